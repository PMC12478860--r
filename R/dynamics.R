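#' Langevin dynamics parameters
#'
#' Settings for the Langevin integrator.  Times are user-facing units:
#' `dt` in femtoseconds, `t_damp` in picoseconds; they are converted to the
#' internal unit system on input.  The published protocol uses 300 K, a
#' 10 fs step and a 1000 ps damping time; short test runs typically lower
#' `t_damp` to 1 ps so velocities decorrelate within the run.
#' `t_damp = Inf` disables the thermostat, leaving plain velocity Verlet.
#'
#' @param temperature Thermostat temperature (K).
#' @param t_damp Damping time (ps); friction on bead i is
#'   `gamma_i = m_i / t_damp`.
#' @param dt Time step (fs).
#' @param n_steps Number of integration steps.
#' @param seed Integer RNG seed.
#' @param sample_every Record a frame every this many steps.
#' @param record_velocities Keep per-frame velocities (needed for kinetic
#'   temperature time series).
#' @return An object of class `langevin_params`.
#' @export
langevin_params <- function(temperature = 300, t_damp = 1000, dt = 10,
                            n_steps = 1000, seed = 1, sample_every = 100,
                            record_velocities = FALSE) {
  stopifnot(dt > 0, t_damp > 0, temperature >= 0, n_steps >= 1,
            sample_every >= 1)
  structure(list(temperature = temperature, t_damp = t_damp, dt = dt,
                 n_steps = n_steps, seed = seed, sample_every = sample_every,
                 record_velocities = record_velocities),
            class = "langevin_params")
}

#' Run Langevin dynamics
#'
#' Integrates the system with a BAOAB-splitting velocity-Verlet Langevin
#' scheme: deterministic half-kicks and half-drifts around an exact
#' Ornstein-Uhlenbeck velocity update, which satisfies fluctuation-
#' dissipation at finite time step.  Friction is `gamma_i = m_i / t_damp`.
#' Nonbonded forces use a cell list when the box admits one (at least three
#' cells per edge at the largest cutoff) and fall back to an all-pairs loop
#' otherwise; the two paths produce identical forces.  Trajectories are
#' reproducible for a given seed.
#'
#' @param sys A [particle_system].
#' @param topo A [cg_topology].
#' @param ff A [ff_params].
#' @param lp A [langevin_params].
#' @return A `cg_trajectory`: list with `times` (fs), `positions` and
#'   `images` (lists of per-frame matrices), `velocities` (internal units;
#'   present when recorded), `energies` (potential, kcal/mol), `box_edge`,
#'   `species`, `masses`, and the parameter objects under `meta`.
#' @export
run_langevin <- function(sys, topo, ff, lp) {
  stopifnot(inherits(sys, "particle_system"), inherits(topo, "cg_topology"),
            inherits(ff, "ff_params"), inherits(lp, "langevin_params"))
  dt <- fs_to_internal(lp$dt)
  td <- if (is.finite(lp$t_damp)) ps_to_internal(lp$t_damp) else Inf
  set.seed(lp$seed)
  res <- cpp_run_langevin(sys$positions, sys$velocities, sys$images,
                          species_code(sys$species), sys$masses,
                          sys$box_edge, unclass(ff),
                          topo$bonds - 1L, topo$angles - 1L,
                          dt, td, kB * lp$temperature,
                          lp$n_steps, lp$sample_every, lp$record_velocities)
  structure(list(times = internal_to_fs(res$times),
                 positions = res$positions,
                 images = res$images,
                 velocities = if (lp$record_velocities) res$velocities,
                 energies = res$energies,
                 box_edge = sys$box_edge,
                 species = sys$species,
                 masses = sys$masses,
                 meta = list(ff = ff, lp = lp, topology = topo)),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d frames x %d beads, box %.6g A, span %.4g ns\n",
              length(x$times), length(x$species), x$box_edge,
              (max(x$times) - min(x$times)) * 1e-6))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `cg_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$times)

#' Frame coordinates
#'
#' @param traj A `cg_trajectory`.
#' @param i Frame index.
#' @param unwrapped Return continuous coordinates (`positions +
#'   images * box_edge`)?
#' @return n x 3 matrix.
#' @export
frame_positions <- function(traj, i, unwrapped = FALSE) {
  p <- traj$positions[[i]]
  if (unwrapped) p <- unwrap_positions(p, traj$images[[i]], traj$box_edge)
  p
}

#' Evaluate forces and potential energy
#'
#' Computes total forces on every bead and the total potential energy of a
#' configuration.  `method = "cell"` uses the cell-list path, `"allpairs"`
#' the direct double loop; both must agree to machine precision.
#'
#' @inheritParams run_langevin
#' @param method `"cell"` or `"allpairs"`.
#' @return `list(forces = n x 3 matrix (kcal/mol/A), energy = kcal/mol)`.
#' @export
compute_forces <- function(sys, topo, ff, method = c("cell", "allpairs")) {
  method <- match.arg(method)
  cpp_compute_forces(sys$positions, species_code(sys$species), sys$box_edge,
                     unclass(ff), topo$bonds - 1L, topo$angles - 1L, method)
}

#' Instantaneous kinetic temperature
#'
#' Equipartition estimate `T = sum(m v^2) / (3 N kB)` with velocities in
#' internal units (A per internal time unit) and masses in g/mol.
#'
#' @param velocities n x 3 matrix.
#' @param masses Per-bead masses (g/mol).
#' @return Temperature in K.
#' @export
kinetic_temperature <- function(velocities, masses) {
  stopifnot(nrow(velocities) >= 1)
  sum(masses * rowSums(velocities^2)) / (3 * nrow(velocities) * kB)
}

#' Maxwell-Boltzmann velocities
#'
#' Draws velocities from the Maxwell-Boltzmann distribution at the given
#' temperature (internal units) and returns the system with them installed.
#'
#' @param sys A [particle_system].
#' @param temperature Kelvin.
#' @param seed Integer RNG seed.
#' @return The modified [particle_system].
#' @export
maxwell_velocities <- function(sys, temperature = 300, seed = 1) {
  set.seed(seed)
  n <- length(sys$masses)
  sd <- sqrt(kB * temperature / sys$masses)
  sys$velocities <- matrix(stats::rnorm(3 * n, sd = rep(sd, 3)), n, 3)
  sys
}

#' Trajectory writers and readers
#'
#' `write_traj_xyz`/`read_traj_xyz` store a trajectory as plain-text
#' extended XYZ (17 significant digits; round-trips exactly).
#' `write_traj_bin`/`read_traj_bin` use a compact binary frame store
#' (IEEE doubles, bit-exact round-trip).
#'
#' @param traj A `cg_trajectory`.
#' @param path Output file.
#' @return Writers return `path` invisibly; readers a `cg_trajectory`
#'   (metadata other than box/species/times is not stored).
#' @export
write_traj_xyz <- function(traj, path) {
  sys <- list(species = traj$species, box_edge = traj$box_edge,
              positions = traj$positions[[1]], images = traj$images[[1]])
  write_xyz(sys, path, frames = traj$positions, images = traj$images,
            times = traj$times)
}

#' @rdname write_traj_xyz
#' @param ff [ff_params] for default masses on read.
#' @export
read_traj_xyz <- function(path, ff = ff_params()) {
  x <- read_xyz(path, ff)
  structure(list(times = x$times, positions = x$frames, images = x$images,
                 velocities = NULL, energies = NULL, box_edge = x$box_edge,
                 species = x$system$species, masses = x$system$masses,
                 meta = list()),
            class = "cg_trajectory")
}

#' @rdname write_traj_xyz
#' @export
write_traj_bin <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(traj$species)
  nf <- n_frames(traj)
  writeBin("cgdropletbin1", con)
  writeBin(c(n, nf), con, size = 4L)
  writeBin(traj$box_edge, con, size = 8L)
  writeBin(as.integer(traj$species == "dna"), con, size = 4L)
  for (f in seq_len(nf)) {
    writeBin(traj$times[f], con, size = 8L)
    writeBin(as.vector(traj$positions[[f]]), con, size = 8L)
    writeBin(as.integer(traj$images[[f]]), con, size = 4L)
  }
  invisible(path)
}

#' @rdname write_traj_xyz
#' @export
read_traj_bin <- function(path, ff = ff_params()) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "character")
  if (!identical(magic, "cgdropletbin1")) stop("not a cgdroplet binary store")
  hd <- readBin(con, "integer", 2, size = 4L)
  n <- hd[1]; nf <- hd[2]
  box <- readBin(con, "double", 1, size = 8L)
  species <- c("protein", "dna")[readBin(con, "integer", n, size = 4L) + 1L]
  times <- numeric(nf)
  positions <- vector("list", nf)
  images <- vector("list", nf)
  for (f in seq_len(nf)) {
    times[f] <- readBin(con, "double", 1, size = 8L)
    positions[[f]] <- matrix(readBin(con, "double", 3 * n, size = 8L), n, 3)
    images[[f]] <- matrix(readBin(con, "integer", 3 * n, size = 4L), n, 3)
  }
  masses <- ifelse(species == "protein", ff$mass_P, ff$mass_D)
  structure(list(times = times, positions = positions, images = images,
                 velocities = NULL, energies = NULL, box_edge = box,
                 species = species, masses = masses, meta = list()),
            class = "cg_trajectory")
}
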
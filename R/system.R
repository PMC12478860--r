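#' Particle system container
#'
#' Holds per-bead positions (wrapped into `[0, box_edge)` on every axis),
#' velocities (internal units, A per internal time unit), species labels,
#' masses, integer periodic-image counts and the box edge.  Unwrapped
#' coordinates are `positions + images * box_edge`.
#'
#' @param positions n x 3 numeric matrix (A).
#' @param species Character vector, `"protein"` or `"dna"` per bead.
#' @param box_edge Cubic box edge (A).
#' @param velocities Optional n x 3 matrix; defaults to zero.
#' @param masses Optional per-bead masses (g/mol); defaults to the
#'   force-field masses for each species.
#' @param images Optional n x 3 integer matrix of periodic image counts.
#' @param ff [ff_params] supplying default masses.
#' @return An object of class `particle_system`.
#' @export
particle_system <- function(positions, species, box_edge, velocities = NULL,
                            masses = NULL, images = NULL, ff = ff_params()) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, length(species) == nrow(positions),
            box_edge > 0)
  species_code(species)  # validates labels
  n <- nrow(positions)
  if (is.null(masses))
    masses <- ifelse(species == "protein", ff$mass_P, ff$mass_D)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (is.null(images)) images <- matrix(0L, n, 3)
  w <- wrap_positions(positions, box_edge)
  structure(list(positions = w$positions, velocities = velocities,
                 species = species, masses = masses, box_edge = box_edge,
                 images = images + w$images),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("particle_system: %d beads (%d protein, %d dna), box %.6g A\n",
              length(x$species), sum(x$species == "protein"),
              sum(x$species == "dna"), x$box_edge))
  invisible(x)
}

#' Molecular topology
#'
#' Chain membership, bonds and angles of a protein-DNA mixture.  Each DNA
#' chain of `N` beads contributes `N - 1` bonds and `N - 2` angles; protein
#' beads are single-bead molecules with no bonded terms.
#'
#' @param molecules List with one entry per molecule:
#'   `list(id =, species =, beads = integer indices)`.
#' @param bonds Integer matrix (n_bonds x 2) of 1-based bead indices.
#' @param angles Integer matrix (n_angles x 3).
#' @param chain_length Beads per DNA chain.
#' @return An object of class `cg_topology`.
#' @export
cg_topology <- function(molecules, bonds, angles, chain_length) {
  beads <- unlist(lapply(molecules, `[[`, "beads"))
  if (anyDuplicated(beads))
    stop("a bead may belong to exactly one molecule")
  structure(list(molecules = molecules, bonds = bonds, angles = angles,
                 chain_length = chain_length),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  nsp <- table(vapply(x$molecules, `[[`, "", "species"))
  cat(sprintf("cg_topology: %d molecules (%s), %d bonds, %d angles\n",
              length(x$molecules),
              paste(sprintf("%d %s", nsp, names(nsp)), collapse = ", "),
              nrow(x$bonds), nrow(x$angles)))
  invisible(x)
}

#' Number of DNA chains for a bead budget
#'
#' The model fixes the total number of DNA beads and distributes them over
#' chains of length `L`; only exact divisors are meaningful.
#'
#' @param dna_bead_budget Total DNA bead count.
#' @param L Beads (base pairs) per chain.
#' @return Integer chain count `dna_bead_budget / L`.
#' @export
#' @examples
#' chain_count(5000, 250)  # 20 chains
chain_count <- function(dna_bead_budget, L) {
  stopifnot(dna_bead_budget > 0, L > 0)
  if (dna_bead_budget %% L != 0)
    stop(sprintf("chain length %d does not divide the DNA bead budget %d",
                 L, dna_bead_budget))
  as.integer(dna_bead_budget / L)
}

make_topology <- function(n_protein, n_chains, chain_len) {
  molecules <- vector("list", n_protein + n_chains)
  for (i in seq_len(n_protein))
    molecules[[i]] <- list(id = i, species = "protein", beads = i)
  bonds <- matrix(0L, max(n_chains * (chain_len - 1), 0), 2)
  angles <- matrix(0L, max(n_chains * max(chain_len - 2, 0), 0), 3)
  bi <- 0L; ai <- 0L
  for (c in seq_len(n_chains)) {
    first <- n_protein + (c - 1L) * chain_len + 1L
    beads <- first:(first + chain_len - 1L)
    molecules[[n_protein + c]] <-
      list(id = n_protein + c, species = "dna", beads = beads)
    if (chain_len >= 2)
      for (k in seq_len(chain_len - 1)) {
        bi <- bi + 1L
        bonds[bi, ] <- c(beads[k], beads[k + 1])
      }
    if (chain_len >= 3)
      for (k in seq_len(chain_len - 2)) {
        ai <- ai + 1L
        angles[ai, ] <- c(beads[k], beads[k + 1], beads[k + 2])
      }
  }
  cg_topology(molecules, bonds[seq_len(bi), , drop = FALSE],
              angles[seq_len(ai), , drop = FALSE], chain_len)
}

#' Build a protein-DNA mixture
#'
#' Places `n_protein` single-bead proteins and `dna_bead_budget / dna_length`
#' DNA chains inside a central sphere of a periodic cubic box, emulating a
#' dense random initial droplet.  Proteins are placed by random sequential
#' addition; DNA chains are grown as mildly perturbed persistent random
#' walks with bonds at exactly `r0`.  Overlaps below `0.8 * sigma_ij` are
#' rejected with bounded retries; infeasible packings raise an error.
#' Output is reproducible for a given `seed`.
#'
#' @param n_protein Number of protein beads.
#' @param dna_length Beads per DNA chain.
#' @param dna_bead_budget Total DNA beads (must be a multiple of
#'   `dna_length`).
#' @param box_edge Cubic box edge (A).
#' @param placement_radius Radius of the central placement sphere (A);
#'   default `box_edge / 4`.
#' @param seed Integer RNG seed.
#' @param ff [ff_params].
#' @param max_retries Placement retries per bead before giving up.
#' @return `list(system = particle_system, topology = cg_topology)`.
#' @export
build_mixture <- function(n_protein, dna_length, dna_bead_budget, box_edge,
                          placement_radius = box_edge / 4, seed = 1,
                          ff = ff_params(), max_retries = 500) {
  stopifnot(n_protein >= 0, box_edge > 0,
            placement_radius > 0, 2 * placement_radius <= box_edge)
  n_chains <- if (dna_bead_budget > 0) chain_count(dna_bead_budget, dna_length)
              else 0L
  set.seed(seed)
  out <- cpp_place_mixture(n_protein, n_chains, dna_length, box_edge,
                           placement_radius, unclass(ff), max_retries)
  species <- c("protein", "dna")[out$species + 1L]
  sys <- particle_system(out$positions, species, box_edge, ff = ff)
  topo <- make_topology(n_protein, n_chains, dna_length)
  list(system = sys, topology = topo)
}

#' Build a single isolated DNA chain
#'
#' One chain of `L` beads in a box at least three times its contour length,
#' so periodic self-images cannot interact.  `conformation = "straight"`
#' places the chain on the z axis with bonds at exactly `r0`;
#' `conformation = "random"` grows a perturbed random walk.
#'
#' @param L Chain length in beads; at least 2.
#' @param conformation `"straight"` or `"random"`.
#' @param seed Integer RNG seed (used for `"random"`).
#' @param ff [ff_params].
#' @return `list(system = particle_system, topology = cg_topology)`.
#' @export
make_single_chain <- function(L, conformation = c("straight", "random"),
                              seed = 1, ff = ff_params()) {
  if (L < 2) stop("a chain needs at least 2 beads")
  conformation <- match.arg(conformation)
  contour <- (L - 1) * ff$r0
  box <- max(3 * contour, 20 * ff$sigma_D)
  if (conformation == "straight") {
    z <- box / 2 + (seq_len(L) - (L + 1) / 2) * ff$r0
    pos <- cbind(box / 2, box / 2, z)
  } else {
    set.seed(seed)
    out <- cpp_place_mixture(0L, 1L, L, box, box / 2 - 1e-9, unclass(ff),
                             1000L)
    pos <- out$positions
  }
  sys <- particle_system(pos, rep("dna", L), box, ff = ff)
  list(system = sys, topology = make_topology(0L, 1L, L))
}

#' Wrap and unwrap periodic coordinates
#'
#' `wrap_positions` folds coordinates into `[0, box_edge)` and returns the
#' integer image shifts removed; `unwrap_positions` restores the original
#' continuous coordinates from wrapped positions plus image counts, so
#' `unwrap(wrap(x)) = x`.
#'
#' @param positions n x 3 matrix (A).
#' @param box_edge Box edge (A).
#' @param images n x 3 integer matrix of image counts.
#' @return `wrap_positions`: `list(positions, images)`;
#'   `unwrap_positions`: an n x 3 matrix.
#' @export
wrap_positions <- function(positions, box_edge) {
  img <- floor(positions / box_edge)
  list(positions = positions - img * box_edge,
       images = matrix(as.integer(img), nrow(positions), 3))
}

#' @rdname wrap_positions
#' @export
unwrap_positions <- function(positions, images, box_edge) {
  positions + images * box_edge
}

#' Export a configuration as extended XYZ
#'
#' Writes one or more frames in extended-XYZ format (species as the element
#' column, positions and image flags as per-atom columns, the box as a
#' `Lattice` field).  Coordinates are printed with 17 significant digits and
#' round-trip exactly through [read_xyz].
#'
#' @param sys A [particle_system], or a list of position matrices via
#'   `frames`.
#' @param path Output file.
#' @param frames Optional list of n x 3 matrices overriding `sys$positions`.
#' @param images Optional list of image matrices matching `frames`.
#' @param times Optional frame times (fs).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(sys, path, frames = NULL, images = NULL, times = NULL) {
  if (is.null(frames)) {
    frames <- list(sys$positions)
    images <- list(sys$images)
  }
  if (is.null(images)) images <- rep(list(matrix(0L, nrow(frames[[1]]), 3)),
                                     length(frames))
  if (is.null(times)) times <- seq_along(frames) - 1
  n <- length(sys$species)
  con <- file(path, "w")
  on.exit(close(con))
  lat <- sprintf("%.17g 0 0 0 %.17g 0 0 0 %.17g",
                 sys$box_edge, sys$box_edge, sys$box_edge)
  for (f in seq_along(frames)) {
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%s" Properties=species:S:1:pos:R:3:image:I:3 Time=%.17g',
      lat, times[f]), con)
    p <- frames[[f]]; im <- images[[f]]
    writeLines(sprintf("%s %.17g %.17g %.17g %d %d %d",
                       sys$species, p[, 1], p[, 2], p[, 3],
                       im[, 1], im[, 2], im[, 3]), con)
  }
  invisible(path)
}

#' Read an extended XYZ file
#'
#' @param path File written by [write_xyz].
#' @param ff [ff_params] for default masses.
#' @return `list(system = particle_system of the first frame, frames = list
#'   of position matrices, images = list of image matrices, times = numeric
#'   vector (fs), box_edge)`.
#' @export
read_xyz <- function(path, ff = ff_params()) {
  lines <- readLines(path)
  frames <- list(); images <- list(); times <- numeric()
  species <- NULL; box <- NA_real_
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1]
    box <- as.numeric(sub('.*Lattice="([^ ]+) .*', "\\1", hdr))
    tm <- if (grepl("Time=", hdr))
      as.numeric(sub(".*Time=([^ ]+).*", "\\1", hdr)) else length(times)
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(body, " +")
    species <- vapply(parts, `[[`, "", 1)
    num <- t(vapply(parts, function(p) as.numeric(p[2:7]), numeric(6)))
    frames[[length(frames) + 1]] <- num[, 1:3, drop = FALSE]
    images[[length(images) + 1]] <-
      matrix(as.integer(num[, 4:6]), n, 3)
    times <- c(times, tm)
    i <- i + 2 + n
  }
  sys <- particle_system(frames[[1]], species, box,
                         images = images[[1]], ff = ff)
  list(system = sys, frames = frames, images = images, times = times,
       box_edge = box)
}
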
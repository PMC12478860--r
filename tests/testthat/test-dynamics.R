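test_that("kinetic temperature inverts equipartition exactly and statistically", {
  # single particle engineered to 300 K
  m <- 5000
  v2 <- 3 * kB * 300 / m
  v <- matrix(c(sqrt(v2), 0, 0), 1, 3)
  expect_equal(kinetic_temperature(v, m), 300)
  expect_equal(kinetic_temperature(matrix(0, 5, 3), rep(500, 5)), 0)
  # Maxwell-Boltzmann sample at 300 K
  set.seed(1)
  n <- 1e5
  vel <- matrix(rnorm(3 * n, sd = sqrt(kB * 300 / 500)), n, 3)
  expect_equal(kinetic_temperature(vel, rep(500, n)), 300, tolerance = 0.01)
})

test_that("cell-list forces equal all-pairs forces on random mixtures", {
  ff <- ff_params(lambda_PP = 2, lambda_PD = 0.8)
  for (k in 1:50) {
    set.seed(k)
    box <- sample(c(350, 500, 900, 1600), 1)
    pos <- matrix(runif(600, 0, box), 200, 3)
    species <- sample(c("protein", "dna"), 200, replace = TRUE)
    sys <- particle_system(pos, species, box, ff = ff)
    # bond a few consecutive dna-labelled beads to exercise exclusions
    dna_idx <- which(species == "dna")
    bonds <- cbind(dna_idx[-length(dna_idx)], dna_idx[-1])[1:10, , drop = FALSE]
    topo <- cg_topology(list(list(id = 1, species = "dna",
                                  beads = seq_len(200))),
                        bonds, matrix(0L, 0, 3), 200)
    a <- compute_forces(sys, topo, ff, "cell")
    b <- compute_forces(sys, topo, ff, "allpairs")
    # random configurations contain deep overlaps with enormous forces, so
    # agreement is relative to the force scale (summation order differs)
    scale <- max(abs(b$forces), 1)
    expect_lt(max(abs(a$forces - b$forces)) / scale, 1e-10)
    expect_equal(a$energy, b$energy, tolerance = 1e-12)
  }
})

test_that("the thermostat holds the target temperature in a bonded mixture", {
  ff <- ff_params(lambda_PP = 1, lambda_PD = 0.5)
  b <- fixture_mixture(ff = ff)
  lp <- langevin_params(temperature = 300, t_damp = 1, dt = 10,
                        n_steps = 20000, seed = 6, sample_every = 200,
                        record_velocities = TRUE)
  traj <- run_langevin(b$system, b$topology, ff, lp)
  skip_frames <- 30   # let velocities thermalise
  Tk <- vapply(skip_frames:n_frames(traj), function(i)
    kinetic_temperature(traj$velocities[[i]], traj$masses), numeric(1))
  expect_equal(mean(Tk), 300, tolerance = 0.03)
})

test_that("free Langevin particles obey the Einstein relation", {
  ff <- ff_params()
  set.seed(1)
  n <- 400
  box <- 20000   # dilute: collisions negligible
  sys <- particle_system(matrix(runif(3 * n, 0, box), n, 3),
                         rep("protein", n), box)
  topo <- cg_topology(lapply(seq_len(n), function(i)
    list(id = i, species = "protein", beads = i)),
    matrix(0L, 0, 2), matrix(0L, 0, 3), 0)
  lp <- langevin_params(temperature = 300, t_damp = 1, dt = 20,
                        n_steps = 25000, seed = 2, sample_every = 500)
  traj <- run_langevin(sys, topo, ff, lp)
  nf <- n_frames(traj)
  i0 <- nf %/% 2
  p0 <- frame_positions(traj, i0, unwrapped = TRUE)
  msd <- vapply((i0 + 1):nf, function(i)
    mean(rowSums((frame_positions(traj, i, unwrapped = TRUE) - p0)^2)),
    numeric(1))
  t_ns <- (traj$times[(i0 + 1):nf] - traj$times[i0]) * 1e-6
  D_fit <- unname(coef(lm(msd ~ t_ns))[2] / 6)
  tau_ns <- time_unit_fs * 1e-6
  D_theory <- kB * 300 * (1000 / time_unit_fs) / 5000 / tau_ns  # t_damp = 1 ps
  expect_equal(D_fit, D_theory, tolerance = 0.05)
})

test_that("with the thermostat off the integrator conserves energy and momentum", {
  ff <- ff_params()
  # harmonic dimer: secular drift of total energy ~ 0 (symplectic)
  pos <- matrix(c(100, 100, 100, 100, 100, 106.2), 2, 3, byrow = TRUE)
  sys <- particle_system(pos, c("dna", "dna"), 200)
  topo <- cg_topology(list(list(id = 1, species = "dna", beads = 1:2)),
                      matrix(1:2, 1, 2), matrix(0L, 0, 3), 2)
  lp <- langevin_params(temperature = 0, t_damp = Inf, dt = 10,
                        n_steps = 10000, seed = 1, sample_every = 10,
                        record_velocities = TRUE)
  traj <- run_langevin(sys, topo, ff, lp)
  E <- vapply(seq_len(n_frames(traj)), function(i)
    traj$energies[i] + 0.5 * sum(traj$masses *
                                   rowSums(traj$velocities[[i]]^2)),
    numeric(1))
  drift <- abs(unname(coef(lm(E ~ traj$times))[2]) * max(traj$times))
  expect_lt(drift / abs(mean(E)), 1e-4)

  # interacting mixture without thermostat conserves total momentum
  ffm <- ff_params(lambda_PP = 1.5, lambda_PD = 0.5)
  b <- fixture_mixture(n_protein = 20, chain_len = 5, n_chains = 4,
                       box = 300, seed = 9, ff = ffm)
  s <- maxwell_velocities(b$system, 300, seed = 4)
  p0 <- colSums(s$masses * s$velocities)
  tr <- run_langevin(s, b$topology, ffm,
                     langevin_params(t_damp = Inf, dt = 5, n_steps = 2000,
                                     seed = 1, sample_every = 2000,
                                     record_velocities = TRUE))
  p1 <- colSums(tr$masses * tr$velocities[[n_frames(tr)]])
  expect_lt(max(abs(p1 - p0)) / max(abs(p0)), 1e-8)
})

test_that("a repulsive pair at the potential minimum stays put", {
  ff <- ff_params()
  pos <- matrix(c(100, 100, 100, 100, 100, 100 + 2^(1/6) * 50), 2, 3,
                byrow = TRUE)
  sys <- particle_system(pos, c("protein", "protein"), 400)
  topo <- cg_topology(lapply(1:2, function(i)
    list(id = i, species = "protein", beads = i)),
    matrix(0L, 0, 2), matrix(0L, 0, 3), 0)
  lp <- langevin_params(temperature = 0, t_damp = Inf, dt = 10,
                        n_steps = 200, seed = 1, sample_every = 20)
  traj <- run_langevin(sys, topo, ff, lp)
  expect_equal(frame_positions(traj, n_frames(traj)), pos,
               ignore_attr = TRUE)
})

test_that("trajectories are reproducible per seed and abort on blow-ups", {
  ff <- ff_params(lambda_PP = 2)
  b <- fixture_mixture(n_protein = 15, chain_len = 5, n_chains = 2,
                       box = 300, seed = 3, ff = ff)
  lp <- langevin_params(n_steps = 500, seed = 42, sample_every = 100,
                        t_damp = 1)
  t1 <- run_langevin(b$system, b$topology, ff, lp)
  t2 <- run_langevin(b$system, b$topology, ff, lp)
  expect_identical(t1$positions, t2$positions)
  # overlapping start with a huge step must abort with a diagnostic
  bad <- b$system
  bad$positions[2, ] <- bad$positions[1, ] + c(0.01, 0, 0)
  expect_error(
    run_langevin(bad, b$topology, ff,
                 langevin_params(n_steps = 100, dt = 1000, t_damp = 1)),
    "half the box")
})

test_that("trajectory stores round-trip bit-exactly in both formats", {
  ff <- ff_params()
  b <- fixture_mixture(n_protein = 10, chain_len = 5, n_chains = 2,
                       box = 300, seed = 7, ff = ff)
  lp <- langevin_params(n_steps = 300, seed = 1, sample_every = 100,
                        t_damp = 1)
  traj <- run_langevin(b$system, b$topology, ff, lp)
  fx <- withr::local_tempfile(fileext = ".xyz")
  fb <- withr::local_tempfile(fileext = ".bin")
  write_traj_xyz(traj, fx)
  write_traj_bin(traj, fb)
  bx <- read_traj_xyz(fx)
  bb <- read_traj_bin(fb)
  for (i in seq_len(n_frames(traj))) {
    expect_identical(bx$positions[[i]], traj$positions[[i]])
    expect_identical(bb$positions[[i]], traj$positions[[i]])
    expect_identical(bb$images[[i]], traj$images[[i]])
  }
  expect_identical(bb$times, traj$times)
})
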
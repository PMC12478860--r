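test_that("the mixture density is a normalised radial propagator", {
  # n = 1: unit mass and maximum at r = 2 sqrt(D t)
  D <- 250; t <- 2
  mass <- integrate(function(r) mixture_pdf(r, t, 1, D), 0, Inf,
                    rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-8)
  ropt <- optimize(function(r) mixture_pdf(r, t, 1, D),
                   c(0, 10 * sqrt(D * t)), maximum = TRUE)$maximum
  expect_equal(ropt, 2 * sqrt(D * t), tolerance = 1e-4)
  # n = 2: second moment is 6 t sum(p D)
  m2 <- integrate(function(r) r^2 * mixture_pdf(r, 1, c(.5, .5), c(100, 10)),
                  0, Inf, rel.tol = 1e-10)$value
  expect_equal(m2, 6 * 1 * (0.5 * 100 + 0.5 * 10), tolerance = 1e-6)
  expect_error(mixture_pdf(1, 1, c(.5, .4), c(1, 1)), "sum to 1")
  expect_error(mixture_pdf(1, 1, 1, -2), "D > 0")
})

test_that("the displacement sampler has the right moments and is deterministic", {
  p <- c(0.3, 0.7); D <- c(500, 50); t <- 2
  a <- sample_displacements(p, D, t, 1e5, seed = 3)
  b <- sample_displacements(p, D, t, 1e5, seed = 3)
  expect_identical(a, b)
  expect_equal(mean(a^2), 6 * t * sum(p * D), tolerance = 0.02)
  one <- sample_displacements(1, 120, 1, 1e5, seed = 4)
  expect_equal(mean(one^2) / 6, 120, tolerance = 0.02)
})

test_that("displacement histograms are normalised and reject bad lags", {
  # static trajectory: all mass in the first bin
  n <- 20
  pos <- matrix(runif(3 * n, 0, 100), n, 3)
  traj <- structure(list(times = (0:4) * 1e6, positions = rep(list(pos), 5),
                         images = rep(list(matrix(0L, n, 3)), 5),
                         box_edge = 100, species = rep("protein", n),
                         masses = rep(5000, n), meta = list()),
                    class = "cg_trajectory")
  d <- displacement_distribution(traj, lag = 1, n_bins = 50)
  expect_equal(d$probability[1], 1)
  expect_equal(sum(d$probability), 1, tolerance = 1e-12)
  expect_error(displacement_distribution(traj, lag = 1.5), "multiple")
  expect_error(displacement_distribution(traj, lag = 9), "span")
})

test_that("free Langevin displacement distributions match the Einstein relation", {
  ff <- ff_params()
  set.seed(2)
  n <- 300
  box <- 30000
  sys <- particle_system(matrix(runif(3 * n, 0, box), n, 3),
                         rep("protein", n), box)
  topo <- cg_topology(lapply(seq_len(n), function(i)
    list(id = i, species = "protein", beads = i)),
    matrix(0L, 0, 2), matrix(0L, 0, 3), 0)
  lp <- langevin_params(temperature = 300, t_damp = 1, dt = 20,
                        n_steps = 20000, seed = 5, sample_every = 1000)
  traj <- run_langevin(sys, topo, ff, lp)
  traj$positions <- traj$positions[-(1:4)]
  traj$images <- traj$images[-(1:4)]
  traj$times <- traj$times[-(1:4)]
  # lag >> t_damp so the inertial part of the MSD is negligible
  lag_ns <- (traj$times[2] - traj$times[1]) * 1e-6 * 3
  d <- displacement_distribution(traj, lag = lag_ns, n_bins = 200)
  msd <- sum(d$probability * d$r^2)
  D_theory <- kB * 300 * (1000 / time_unit_fs) / 5000 /
    (time_unit_fs * 1e-6)
  expect_equal(msd / (6 * lag_ns), D_theory, tolerance = 0.05)
})

test_that("mode fits round-trip known mixtures for n in {1, 2, 3, 5}", {
  cases <- list(
    list(p = 1, D = 100),
    list(p = c(0.5, 0.5), D = c(1e4, 1e3)),
    list(p = c(0.4, 0.35, 0.25), D = c(1e4, 1e3, 1e2)),
    list(p = c(0.3, 0.25, 0.2, 0.15, 0.1), D = c(1e4, 1e3, 1e2, 1e1, 1)))
  for (cs in cases) {
    n <- length(cs$p)
    disp <- sample_displacements(cs$p, cs$D, t = 1,
                                 n_samples = if (n >= 4) 2e5 else 1e5,
                                 seed = 40 + n)
    fit <- fit_diffusion_modes(displacement_histogram(disp, 1, 500), n)
    expect_equal(fit$D, cs$D, tolerance = 0.05)
    expect_equal(fit$p, cs$p, tolerance = 0.02, ignore_attr = TRUE)
    # invariants: simplex, positivity, descending D
    expect_equal(sum(fit$p), 1, tolerance = 1e-9)
    expect_true(all(fit$D > 0))
    expect_true(all(diff(fit$D) < 0) || n == 1)
  }
})

test_that("a superfluous mode collapses when over-fitting single-mode data", {
  disp <- sample_displacements(1, 100, 1, 1e5, seed = 2)
  fit <- fit_diffusion_modes(displacement_histogram(disp, 1, 500), 2)
  expect_lt(min(fit$p), 0.02)
})

test_that("mode-count selection finds the true component number", {
  d1 <- displacement_histogram(sample_displacements(1, 100, 1, 1e5,
                                                    seed = 2), 1, 500)
  expect_identical(select_mode_count(d1, 4), 1L)
  d3 <- displacement_histogram(
    sample_displacements(c(0.4, 0.35, 0.25), c(1e4, 1e3, 1e2), 1, 2e5,
                         seed = 7), 1, 500)
  expect_identical(select_mode_count(d3, 6), 3L)
  d5 <- displacement_histogram(
    sample_displacements(c(0.3, 0.25, 0.2, 0.15, 0.1),
                         c(1e4, 1e3, 1e2, 1e1, 1), 1, 2e5, seed = 5),
    1, 500)
  expect_identical(select_mode_count(d5, 6), 5L)
})

test_that("selection and fitted diffusivities are robust to bin size", {
  p <- c(0.3, 0.25, 0.2, 0.15, 0.1)
  D <- c(1e4, 1e3, 1e2, 1e1, 1)
  disp <- sample_displacements(p, D, 1, 2e5, seed = 5)
  ref <- NULL
  for (nb in c(300, 500, 1000, 2000)) {
    dd <- displacement_histogram(disp, 1, nb)
    expect_identical(select_mode_count(dd, 6), 5L)
    fit <- fit_diffusion_modes(dd, 5)
    if (is.null(ref)) ref <- fit$D
    expect_equal(fit$D / ref, rep(1, 5), tolerance = 0.1,
                 ignore_attr = TRUE)
  }
})

test_that("fitted diffusivities are constant across lags for Brownian data", {
  p <- c(0.6, 0.4); D <- c(2e3, 1e2)
  dists <- lapply(c(0.5, 1, 2), function(t)
    displacement_histogram(sample_displacements(p, D, t, 1e5,
                                                seed = round(t * 100)),
                           t, 400))
  fit <- fit_diffusion_modes(dists, 2)
  for (m in 1:2) {
    Dm <- fit$per_lag$D[fit$per_lag$mode == m]
    expect_lt(max(abs(Dm / mean(Dm) - 1)), 0.1)
  }
})
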
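test_that("radial profiles conserve counts and capture simple geometries", {
  box <- 400
  # single bead at the reference point
  prof1 <- radial_density_profile(matrix(c(200, 200, 200), 1, 3), 1,
                                  c(200, 200, 200), box, bin_width = 10)
  expect_equal(prof1$counts[1], 1)
  expect_equal(sum(prof1$counts), 1)
  # volume normalisation: sum(density * shell volume) = bead count
  set.seed(4)
  n <- 2000
  pos <- matrix(runif(3 * n, 0, box), n, 3)
  prof <- radial_density_profile(pos, seq_len(n), c(123, 45, 320), box, 10)
  expect_equal(sum(prof$concentration / 1000 *
                     4 / 3 * pi * diff(prof$shell_edges^3)), n)
  expect_equal(sum(prof$counts), n)
  expect_error(radial_density_profile(pos, integer(0), c(0, 0, 0), box, 10),
               "empty")
})

test_that("a uniform sphere gives a flat profile that ends at its radius", {
  set.seed(11)
  n <- 10000
  R <- 60
  box <- 1000
  # rejection-sample points uniform in a sphere around the centre
  pts <- matrix(runif(3 * n * 3, -R, R), ncol = 3)
  pts <- pts[rowSums(pts^2) <= R^2, ][seq_len(n), ] +
    matrix(rep(500, 3), n, 3, byrow = TRUE)
  prof <- radial_density_profile(pts, seq_len(n), c(500, 500, 500), box, 5)
  inside <- prof$r < R - 5
  outside <- prof$r > R + 5
  # per-shell counts flat to within Poisson noise (4 sigma)
  expected <- n * diff(prof$shell_edges^3) / R^3
  dev <- abs(prof$counts[inside] - expected[inside])
  expect_true(all(dev <= 4 * sqrt(expected[inside]) + 1))
  expect_true(all(prof$concentration[outside] == 0))
})

test_that("profile + reference are invariant under rigid translation", {
  set.seed(12)
  box <- 300
  n <- 400
  base <- matrix(rnorm(3 * n, 150, 25), n, 3) %% box
  ref <- periodic_com(base, box)
  prof <- radial_density_profile(base, seq_len(n), ref, box, 5)
  shift <- c(211.7, 95.3, 280.9)
  moved <- sweep(base, 2, shift, "+") %% box
  ref2 <- periodic_com(moved, box)
  prof2 <- radial_density_profile(moved, seq_len(n), ref2, box, 5)
  expect_equal(prof2$counts, prof$counts)
})

test_that("double-tanh fits recover noise-free synthetic parameters", {
  truth <- c(rho_dil = 0.002, rho_II = 0.05, rho_I = 0.2,
             R_I = 80, R_II = 200, w_I = 15, w_II = 25)
  fit <- fit_double_tanh(synthetic_profile(truth))
  expect_true(fit$converged)
  expect_true(fit$multiphasic)
  for (p in names(truth))
    expect_equal(fit[[p]], unname(truth[p]), tolerance = 1e-6)
  expect_lt(fit$rms_residual, 1e-8 * truth["rho_I"])
})

test_that("single-step and flat profiles are not declared multiphasic", {
  single <- c(rho_dil = 0.003, rho_II = 0.18, rho_I = 0.18,
              R_I = 150, R_II = 150, w_I = 20, w_II = 20)
  fit <- fit_double_tanh(synthetic_profile(single))
  expect_false(fit$multiphasic)
  expect_lt(abs(fit$rho_I - fit$rho_II), 0.02 * 0.18)
  flat <- synthetic_profile(c(rho_dil = 0.1, rho_II = 0.1, rho_I = 0.1,
                              R_I = 100, R_II = 200, w_I = 10, w_II = 10))
  ffit <- fit_double_tanh(flat)
  expect_false(isTRUE(ffit$multiphasic) && ffit$converged &&
                 (ffit$rho_I - ffit$rho_II) > 0.01)
  expect_error(fit_double_tanh(synthetic_profile(single, r_max = 50,
                                                 bin_width = 5)),
               "20 shells")
})

test_that("interphase radii are recovered within 2 bin widths under noise", {
  set.seed(77)
  miss <- 0
  n_draws <- 60
  for (k in seq_len(n_draws)) {
    truth <- c(rho_dil = runif(1, 0, 0.005),
               rho_II = runif(1, 0.03, 0.08),
               rho_I = runif(1, 0.13, 0.3),
               R_I = runif(1, 50, 120), R_II = runif(1, 180, 280),
               w_I = runif(1, 8, 25), w_II = runif(1, 10, 30))
    prof <- synthetic_profile(truth, noise_sd = 0.05)
    fit <- fit_double_tanh(prof)
    ok <- fit$converged && abs(fit$R_I - truth["R_I"]) <= 10 &&
      abs(fit$R_II - truth["R_II"]) <= 10
    if (!ok) miss <- miss + 1
  }
  expect_lte(miss, ceiling(0.05 * n_draws))
})

test_that("density gradients match analytic expectations", {
  flat <- synthetic_profile(c(rho_dil = 0.1, rho_II = 0.1, rho_I = 0.1,
                              R_I = 100, R_II = 200, w_I = 10, w_II = 10))
  expect_true(all(density_gradient(flat) == 0))
  ramp <- flat
  ramp$concentration <- 0.002 * ramp$r
  expect_equal(density_gradient(ramp), rep(0.002, length(ramp$r)))
  truth <- c(rho_dil = 0.002, rho_II = 0.05, rho_I = 0.2,
             R_I = 80, R_II = 200, w_I = 15, w_II = 25)
  g <- density_gradient(synthetic_profile(truth))
  r <- synthetic_profile(truth)$r
  # two negative troughs near the interphases
  near_RI <- which(abs(r - 80) < 30)
  near_RII <- which(abs(r - 200) < 40)
  expect_lt(g[which.min(g[near_RI]) + near_RI[1] - 1], 0)
  expect_lt(g[which.min(g[near_RII]) + near_RII[1] - 1], 0)
  expect_lt(abs(r[near_RI][which.min(g[near_RI])] - 80), 10)
  expect_lt(abs(r[near_RII][which.min(g[near_RII])] - 200), 10)
})

test_that("coexistence densities are recovered from a sphere-in-gas fixture", {
  set.seed(21)
  box <- 600
  R <- 90
  rho_dense <- 0.05    # beads/A^3-scaled synthetic condensate
  n_dense <- round(4 / 3 * pi * R^3 * 2e-4)
  n_gas <- 400
  centre <- c(300, 300, 300)
  dense <- matrix(rnorm(3 * n_dense * 4), ncol = 3)
  dense <- dense / sqrt(rowSums(dense^2)) *
    runif(nrow(dense))^(1 / 3) * R
  dense <- dense[seq_len(n_dense), ] + matrix(centre, n_dense, 3,
                                              byrow = TRUE)
  gas <- matrix(runif(3 * n_gas * 3, 0, box), ncol = 3)
  far <- sqrt(rowSums(sweep(gas, 2, centre)^2)) > R + 60
  gas <- gas[far, ][seq_len(n_gas), ]
  pos <- rbind(dense, gas)
  n <- nrow(pos)
  species <- rep("protein", n)
  topo <- cgdroplet:::make_topology(n, 0L, 0L)
  frames <- rep(list(pos), 6)
  traj <- structure(list(times = (0:5) * 1e6, positions = frames,
                         images = rep(list(matrix(0L, n, 3)), 6),
                         box_edge = box, species = species,
                         masses = rep(5000, n), meta = list()),
                    class = "cg_trajectory")
  coex <- coexistence_concentrations(traj, topo, block_scheme(5, 1),
                                     bin_width = 10)
  c_dense_true <- n_dense / (4 / 3 * pi * R^3) * 1000
  vol_gas <- box^3 - 4 / 3 * pi * (R + 60)^3
  c_dil_true <- n_gas / vol_gas * 1000
  expect_equal(coex$c_dense$mean, c_dense_true, tolerance = 0.05)
  expect_equal(coex$c_dilute$mean, c_dil_true, tolerance = 0.25)
})

test_that("a fully dilute gas reports no dense branch", {
  set.seed(31)
  box <- 500
  n <- 200
  pos <- matrix(runif(3 * n, 0, box), n, 3)
  topo <- cgdroplet:::make_topology(n, 0L, 0L)
  frames <- rep(list(pos), 5)
  traj <- structure(list(times = (0:4) * 1e6, positions = frames,
                         images = rep(list(matrix(0L, n, 3)), 5),
                         box_edge = box, species = rep("protein", n),
                         masses = rep(5000, n), meta = list()),
                    class = "cg_trajectory")
  coex <- coexistence_concentrations(traj, topo)
  expect_null(coex$c_dense)
  expect_equal(coex$c_dilute$mean, n / (box / 10)^3)
})
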
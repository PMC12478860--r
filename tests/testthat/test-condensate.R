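test_that("two beads link exactly at the published cluster criterion", {
  box <- 500
  near <- rbind(c(100, 100, 100), c(100, 100, 141))     # 41.0 < 41.25
  far <- rbind(c(100, 100, 100), c(100, 100, 142))      # 42.0 > 41.25
  expect_equal(length(cluster_beads(near, box)$sizes), 1L)
  expect_equal(length(cluster_beads(far, box)$sizes), 2L)
  expect_error(cluster_beads(near, 80, cutoff = 41.25), "half the box")
})

test_that("clustering matches the independent graph-components oracle", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    n <- 500
    box <- 400
    pos <- matrix(runif(3 * n, 0, box), n, 3)
    cl <- cluster_beads(pos, box, 41.25)
    oracle <- oracle_cluster_membership(pos, box, 41.25)
    expect_true(same_partition(cl$labels, oracle))
    expect_equal(sum(cl$sizes), n)
  }
})

test_that("clustering is invariant under translation and bead permutation", {
  set.seed(9)
  pos <- matrix(runif(300, 0, 300), 100, 3)
  base <- cluster_beads(pos, 300, 41.25)
  shifted <- (pos + matrix(rep(c(123.4, -77.7, 250.1), each = 100), 100, 3)) %% 300
  expect_true(same_partition(base$labels,
                             cluster_beads(shifted, 300, 41.25)$labels))
  perm <- sample(100)
  permuted <- cluster_beads(pos[perm, ], 300, 41.25)
  expect_true(same_partition(base$labels[perm], permuted$labels))
})

test_that("largest-cluster fractions apply the any-bead rule for DNA chains", {
  # 3 proteins clustered; one of two 5-bead chains touches via one bead
  box <- 1000
  prot <- rbind(c(500, 500, 500), c(530, 500, 500), c(500, 530, 500))
  chainA <- cbind(seq(520, 542, length.out = 5), 520, 500)  # first bead close
  chainB <- cbind(seq(800, 822, length.out = 5), 800, 800)  # far away
  pos <- rbind(prot, chainA, chainB)
  species <- c(rep("protein", 3), rep("dna", 10))
  topo <- cgdroplet:::make_topology(3L, 2L, 5L)
  cl <- cluster_beads(pos, box, 41.25, species = species)
  fr <- largest_cluster_fractions(cl, topo)
  expect_equal(fr$f_P, 1)
  expect_equal(fr$f_D, 0.5)   # whole chain A counted, none of B
  # everything one cluster
  all1 <- cluster_beads(pos[1:3, ], box, 400, species = species[1:3])
  expect_equal(largest_cluster_fractions(all1,
                 cgdroplet:::make_topology(3L, 0L, 0L))$f_P, 1)
  # no contacts at all: largest cluster is a single molecule
  iso <- rbind(c(0, 0, 0), c(200, 200, 200), c(400, 400, 400))
  cli <- cluster_beads(iso, box, 41.25, species = rep("protein", 3))
  fri <- largest_cluster_fractions(cli, cgdroplet:::make_topology(3L, 0L, 0L))
  expect_equal(fri$f_P, 1 / 3)
})

test_that("fractions are non-decreasing in the cluster cutoff", {
  set.seed(5)
  pos <- matrix(runif(360, 0, 400), 120, 3)
  species <- c(rep("protein", 60), rep("dna", 60))
  topo <- cgdroplet:::make_topology(60L, 6L, 10L)
  cuts <- c(20, 41.25, 60, 90)
  fs <- t(vapply(cuts, function(ct) {
    fr <- largest_cluster_fractions(
      cluster_beads(pos, 400, ct, species = species), topo)
    c(fr$f_P, fr$f_D)
  }, numeric(2)))
  expect_true(all(diff(fs[, 1]) >= 0))
  expect_true(all(diff(fs[, 2]) >= 0))
})

test_that("bound-protein fraction applies the sigma_P + sigma_D criterion", {
  box <- 1000
  # single protein 54.9 A from the nearest DNA bead: bound
  pos1 <- rbind(c(500, 500, 500), c(500, 500, 554.9))
  expect_equal(bound_protein_fraction(pos1, c("protein", "dna"), box), 1)
  pos2 <- rbind(c(500, 500, 500), c(500, 500, 555.1))
  expect_equal(bound_protein_fraction(pos2, c("protein", "dna"), box), 0)
  # no DNA at all
  expect_equal(bound_protein_fraction(pos1[1, , drop = FALSE], "protein",
                                      box), 0)
  # mixed configuration equals a brute-force minimum-image check
  set.seed(7)
  n <- 80
  pos <- matrix(runif(3 * n, 0, 300), n, 3)
  species <- sample(c("protein", "dna"), n, replace = TRUE, prob = c(.6, .4))
  got <- bound_protein_fraction(pos, species, 300, cutoff = 55)
  mi <- function(d) pmin(abs(d), 300 - abs(d))
  pidx <- which(species == "protein"); didx <- which(species == "dna")
  bound <- vapply(pidx, function(i) {
    dd <- vapply(didx, function(j)
      sqrt(sum(mi(pos[i, ] - pos[j, ])^2)), numeric(1))
    any(dd <= 55)
  }, logical(1))
  expect_equal(got, mean(bound))
})

test_that("block averaging reproduces hand-computed summaries", {
  # series whose 5 block means are 1..5; first block discarded
  series <- rep(1:5, each = 4)
  ba <- block_average(series, block_scheme(5, 1))
  expect_equal(ba$mean, 3.5)
  expect_equal(ba$stderr, sd(2:5) / 2)
  # constant series
  expect_equal(block_average(rep(7, 25))$stderr, 0)
  expect_equal(block_average(rep(7, 25))$mean, 7)
  # random series vs direct textbook computation with truncation
  set.seed(2)
  x <- rnorm(53)
  ba2 <- block_average(x, block_scheme(5, 1))
  len <- 53 %/% 5
  bm <- vapply(1:5, function(b) mean(x[((b - 1) * len + 1):(b * len)]),
               numeric(1))
  expect_equal(ba2$mean, mean(bm[-1]))
  expect_equal(ba2$stderr, sd(bm[-1]) / 2)
  expect_error(block_average(1:3, block_scheme(5, 1)), "shorter")
})
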
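# Shared fixtures and independent oracles used across test files.

# Boltzmann single-angle quadrature oracle for the persistence length of a
# worm-like bead-spring chain: l_p = -b / ln<cos(phi)> with phi the
# deviation from a straight chain, weighted by exp(-K phi^2 / kT) sin(phi).
oracle_persistence_length <- function(K_theta, b = 5.5, temperature = 300) {
  kT <- kB * temperature
  num <- stats::integrate(function(phi)
    cos(phi) * exp(-K_theta * phi^2 / kT) * sin(phi), 0, pi)$value
  den <- stats::integrate(function(phi)
    exp(-K_theta * phi^2 / kT) * sin(phi), 0, pi)$value
  -b / log(num / den)
}

# All-pairs minimum-image connected components through igraph, independent
# of the package's union-find path.
oracle_cluster_membership <- function(pos, box, cutoff) {
  n <- nrow(pos)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    d <- abs(sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ]))
    d <- pmin(d, box - d)
    hit <- rowSums(d^2) <= cutoff^2
    adj[i, (i + 1):n][hit] <- TRUE
  }
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# Same-partition comparison that ignores label permutations.
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# Noise-free double-tanh profile on a shell grid.
synthetic_profile <- function(pars, r_max = 500, bin_width = 5,
                              noise_sd = 0) {
  edges <- seq(0, r_max, by = bin_width)
  r <- (edges[-1] + edges[-length(edges)]) / 2
  y <- pars["rho_dil"] +
    (pars["rho_II"] - pars["rho_dil"]) / 2 *
      (1 - tanh((r - pars["R_II"]) / pars["w_II"])) +
    (pars["rho_I"] - pars["rho_II"]) / 2 *
      (1 - tanh((r - pars["R_I"]) / pars["w_I"]))
  if (noise_sd > 0) y <- pmax(y * (1 + stats::rnorm(length(y), 0, noise_sd)), 0)
  structure(list(shell_edges = edges, r = r, concentration = y,
                 counts = y * (4 / 3 * pi * diff(edges^3)) / 1000),
            class = "density_profile")
}

# Small bonded + nonbonded mixture reused by several dynamics tests.
fixture_mixture <- function(n_protein = 30, chain_len = 10, n_chains = 6,
                            box = 400, seed = 5, ff = ff_params()) {
  build_mixture(n_protein, chain_len, chain_len * n_chains, box,
                seed = seed, ff = ff)
}
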
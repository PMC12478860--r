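#' Block-averaging scheme
#'
#' The analysis protocol splits a time series into `n_blocks` equal blocks
#' (truncating any remainder), discards the first `n_discard` blocks as
#' equilibration and reports the mean and standard error of the remaining
#' block means.  Defaults: five blocks, first discarded.
#'
#' @param n_blocks Number of equal blocks.
#' @param n_discard Leading blocks discarded.
#' @return An object of class `block_scheme`.
#' @export
block_scheme <- function(n_blocks = 5, n_discard = 1) {
  stopifnot(n_blocks >= 2, n_discard >= 0, n_discard < n_blocks)
  structure(list(n_blocks = n_blocks, n_discard = n_discard),
            class = "block_scheme")
}

#' Block average of a time series
#'
#' @param series Numeric per-frame values; at least `n_blocks` long.
#' @param scheme A [block_scheme].
#' @return `list(mean, stderr, block_means)`; `stderr` is the sample
#'   standard deviation of the kept block means divided by the square root
#'   of their number.
#' @export
#' @examples
#' block_average(1:50)  # blocks of 10, first discarded
block_average <- function(series, scheme = block_scheme()) {
  n <- length(series)
  if (n < scheme$n_blocks)
    stop("series shorter than the number of blocks")
  len <- n %/% scheme$n_blocks
  means <- vapply(seq_len(scheme$n_blocks), function(b)
    mean(series[((b - 1) * len + 1):(b * len)]), numeric(1))
  kept <- means[-seq_len(scheme$n_discard)]
  if (scheme$n_discard == 0) kept <- means
  list(mean = mean(kept),
       stderr = if (length(kept) > 1) stats::sd(kept) / sqrt(length(kept))
                else 0,
       block_means = means)
}

#' Distance-based clustering of beads
#'
#' Single-linkage clusters: connected components of the graph joining any
#' two beads whose minimum-image distance is at most the linking cutoff.
#' The published criterion is a single cutoff for all bead pairs,
#' `1.5 * sigma_PD` (41.25 A with default diameters), which is the default.
#' Because that distance is smaller than the protein diameter, two touching
#' proteins (centres near `2^(1/6) sigma_P` = 56 A) can never link under
#' it; `per_pair = TRUE` switches to per-species-pair cutoffs
#' `cutoff_factor * sigma_ij`, which is required to resolve protein-only
#' condensates.
#'
#' @param positions n x 3 matrix of (wrapped or unwrapped) coordinates.
#' @param box_edge Box edge (A).
#' @param cutoff Linking distance (A) in single-cutoff mode; must be below
#'   half the box for the minimum-image convention to be valid.
#' @param species Optional species labels, stored for composition analyses;
#'   required when `per_pair = TRUE`.
#' @param per_pair Use per-species-pair cutoffs `cutoff_factor * sigma_ij`?
#' @param cutoff_factor Multiple of `sigma_ij` in per-pair mode.
#' @param ff [ff_params] supplying the diameters in per-pair mode.
#' @return A `cluster_result`: list with `labels` (1-based cluster ids),
#'   `sizes` (cluster-size table), `largest_id`.
#' @export
cluster_beads <- function(positions, box_edge,
                          cutoff = 1.5 * pair_sigma("protein", "dna"),
                          species = NULL, per_pair = FALSE,
                          cutoff_factor = 1.5, ff = ff_params()) {
  positions <- as.matrix(positions)
  if (per_pair) {
    stopifnot(!is.null(species))
    sig <- c(ff$sigma_P, ff$sigma_D)
    cuts <- cutoff_factor *
      outer(sig, sig, function(a, b) (a + b) / 2)   # PP PD / DP DD
    if (max(cuts) >= box_edge / 2)
      stop("cutoff must be below half the box edge (minimum image)")
    labels <- cpp_cluster_labels_perpair(positions, species_code(species),
                                         box_edge, as.vector(t(cuts)))
  } else {
    stopifnot(cutoff > 0)
    if (cutoff >= box_edge / 2)
      stop("cutoff must be below half the box edge (minimum image)")
    labels <- cpp_cluster_labels(positions, box_edge, cutoff)
  }
  sizes <- tabulate(labels)
  structure(list(labels = labels, sizes = sizes,
                 largest_id = which.max(sizes), species = species),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters over %d beads; largest has %d\n",
              length(x$sizes), length(x$labels), max(x$sizes)))
  invisible(x)
}

#' Largest-cluster composition fractions
#'
#' Selects the largest cluster by bead count and reports
#' `f_P = N_P^cluster / N_P^total` and `f_D = N_D^cluster / N_D^total`.
#' A DNA chain counts as part of the cluster in full if any of its beads
#' belongs to it; proteins are counted bead-wise.
#'
#' @param cluster A `cluster_result` from [cluster_beads].
#' @param topo A [cg_topology].
#' @param species Per-bead species labels (taken from the cluster result if
#'   stored there).
#' @return `list(f_P, f_D, largest_id, largest_size)`.
#' @export
largest_cluster_fractions <- function(cluster, topo, species = NULL) {
  if (is.null(species)) species <- cluster$species
  stopifnot(!is.null(species))
  lab <- cluster$labels
  lid <- cluster$largest_id
  in_cl <- lab == lid
  n_p_tot <- sum(species == "protein")
  n_d_tot <- sum(species == "dna")
  f_P <- if (n_p_tot) sum(in_cl & species == "protein") / n_p_tot else 0
  n_d_cl <- 0
  for (m in topo$molecules) {
    if (m$species != "dna") next
    if (any(in_cl[m$beads])) n_d_cl <- n_d_cl + length(m$beads)
  }
  f_D <- if (n_d_tot) n_d_cl / n_d_tot else 0
  list(f_P = f_P, f_D = f_D, largest_id = lid,
       largest_size = cluster$sizes[lid])
}

#' Fraction of proteins bound to DNA
#'
#' A protein is bound when its minimum-image distance to the nearest DNA
#' bead is at most `cutoff` (default `sigma_P + sigma_D` = 55 A).
#' Optionally restricted to proteins belonging to a given cluster (the
#' dense phase is operationally the largest cluster).
#'
#' @param positions n x 3 coordinate matrix.
#' @param species Per-bead species labels.
#' @param box_edge Box edge (A).
#' @param cutoff Binding distance (A).
#' @param restrict_to Optional logical/integer index over beads selecting
#'   which proteins to consider (e.g. largest-cluster members).
#' @return Bound fraction in `[0, 1]`; 0 when no DNA beads are present.
#' @export
bound_protein_fraction <- function(positions, species, box_edge,
                                   cutoff = NULL, restrict_to = NULL) {
  positions <- as.matrix(positions)
  if (is.null(cutoff)) cutoff <- 55
  is_p <- species == "protein"
  if (!is.null(restrict_to)) {
    sel <- rep(FALSE, length(species))
    sel[restrict_to] <- TRUE
    is_p <- is_p & sel
  }
  stopifnot(sum(species == "protein") >= 1)
  if (!sum(is_p)) return(0)
  dna <- positions[species == "dna", , drop = FALSE]
  if (!nrow(dna)) return(0)
  d <- cpp_nearest_distance(positions[is_p, , drop = FALSE], dna, box_edge)
  mean(d <= cutoff)
}

#' Per-frame condensate composition over a trajectory
#'
#' Runs [cluster_beads] and [largest_cluster_fractions] (and optionally the
#' DNA-bound protein fraction within the largest cluster) on every frame
#' and block-averages the series.
#'
#' @param traj A `cg_trajectory`.
#' @param topo A [cg_topology].
#' @param cutoff Cluster linking distance (A).
#' @param bound_cutoff DNA-binding distance (A).
#' @param blocks A [block_scheme].
#' @param per_pair Use per-species-pair cluster cutoffs (see
#'   [cluster_beads]).
#' @return List of data frame `per_frame` (f_P, f_D, bound fraction) and
#'   block-averaged summaries `f_P`, `f_D`, `bound` (each `list(mean,
#'   stderr)`).
#' @export
condensate_composition <- function(traj, topo,
                                   cutoff = 1.5 * pair_sigma("protein", "dna"),
                                   bound_cutoff = 55,
                                   blocks = block_scheme(),
                                   per_pair = FALSE) {
  nf <- n_frames(traj)
  fP <- fD <- bnd <- numeric(nf)
  for (f in seq_len(nf)) {
    p <- traj$positions[[f]]
    cl <- cluster_beads(p, traj$box_edge, cutoff, species = traj$species,
                        per_pair = per_pair)
    fr <- largest_cluster_fractions(cl, topo)
    fP[f] <- fr$f_P; fD[f] <- fr$f_D
    bnd[f] <- bound_protein_fraction(p, traj$species, traj$box_edge,
                                     bound_cutoff,
                                     restrict_to = cl$labels == fr$largest_id)
  }
  per_frame <- data.frame(time = traj$times, f_P = fP, f_D = fD,
                          bound = bnd)
  list(per_frame = per_frame,
       f_P = block_average(fP, blocks),
       f_D = block_average(fD, blocks),
       bound = block_average(bnd, blocks))
}
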
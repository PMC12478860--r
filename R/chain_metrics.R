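#' Radius of gyration of one chain
#'
#' Mass-weighted root-mean-square distance of the beads from the chain's
#' centre of mass.  Coordinates must be unwrapped (continuous); a chain with
#' any bond longer than half the box is taken as evidence of wrapped input
#' and rejected.
#'
#' @param coords n x 3 matrix of unwrapped bead coordinates (A).
#' @param masses Optional per-bead masses; equal masses by default (for a
#'   homopolymer the two conventions coincide).
#' @param box_edge Optional box edge used only for the wrapped-input check.
#' @return R_g in A.
#' @export
#' @examples
#' radius_of_gyration(cbind(0, 0, c(0, 5.5, 11)))  # 5.5 * sqrt(2/3)
radius_of_gyration <- function(coords, masses = NULL, box_edge = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n >= 1)
  if (!is.null(box_edge) && n > 1) {
    bl <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                          coords[-n, , drop = FALSE])^2))
    if (any(bl > box_edge / 2))
      stop("bond longer than half the box: coordinates look wrapped; ",
           "unwrap before computing R_g")
  }
  if (is.null(masses)) masses <- rep(1, n)
  com <- colSums(coords * masses) / sum(masses)
  d2 <- rowSums(sweep(coords, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

chain_indices <- function(topo) {
  mols <- Filter(function(m) m$species == "dna", topo$molecules)
  lapply(mols, `[[`, "beads")
}

#' Mean DNA radius of gyration over a trajectory
#'
#' Per frame, averages R_g over all DNA chains (on unwrapped coordinates);
#' the frame series is then summarised with the block-averaging protocol
#' (equal blocks, first discarded).
#'
#' @param traj A `cg_trajectory`.
#' @param topo A [cg_topology].
#' @param blocks A [block_scheme].
#' @return A `chain_observable`: list with `per_chain` (data frame of
#'   molecule id and time-averaged value), `series` (per-frame chain
#'   average), `mean`, `stderr`, `units`.
#' @export
mean_chain_rg <- function(traj, topo, blocks = block_scheme()) {
  nf <- n_frames(traj)
  if (nf < blocks$n_blocks)
    stop("need at least as many frames as blocks")
  chains <- chain_indices(topo)
  if (!length(chains)) stop("topology contains no DNA chains")
  per_frame <- matrix(NA_real_, nf, length(chains))
  for (f in seq_len(nf)) {
    p <- frame_positions(traj, f, unwrapped = TRUE)
    per_frame[f, ] <- vapply(chains, function(idx)
      radius_of_gyration(p[idx, , drop = FALSE],
                         traj$masses[idx], traj$box_edge), numeric(1))
  }
  series <- rowMeans(per_frame)
  ba <- block_average(series, blocks)
  per_chain <- data.frame(
    molecule = vapply(Filter(function(m) m$species == "dna", topo$molecules),
                      `[[`, numeric(1), "id"),
    value = colMeans(per_frame))
  structure(list(per_chain = per_chain, series = series,
                 mean = ba$mean, stderr = ba$stderr, units = "A"),
            class = "chain_observable")
}

#' @export
print.chain_observable <- function(x, ...) {
  cat(sprintf("chain observable: mean %.4g +/- %.3g %s (%d chains)\n",
              x$mean, x$stderr, x$units, nrow(x$per_chain)))
  invisible(x)
}

#' Persistence length from bond-vector correlations
#'
#' Fits the exponential decay of the mean bond-direction correlation
#' \eqn{\langle \hat u_i \cdot \hat u_{i+s} \rangle = e^{-s b / l_p}}
#' over contour separations `s` where the correlation still exceeds
#' `fit_window`, with `b` the mean bond length.  The fit is a linear
#' regression of log-correlation on separation through the origin.
#' If the correlation is already non-positive at `s = 1` there is no decay
#' to fit and the result is flagged sub-bond.
#'
#' @param traj A `cg_trajectory` of a single chain (e.g. from
#'   [sample_chain_mc]).
#' @param fit_window Correlation threshold bounding the fit range
#'   (default 0.2).
#' @return List with `l_p` (A, `NA` when sub-bond), `bond_length`,
#'   `correlation` (mean correlation vs separation), `sub_bond` flag.
#' @export
persistence_length <- function(traj, fit_window = 0.2) {
  nf <- n_frames(traj)
  n <- length(traj$species)
  if (n < 21) stop("persistence length needs a chain with at least 20 bonds")
  nb <- n - 1
  corr_sum <- numeric(nb - 1)
  b_sum <- 0
  for (f in seq_len(nf)) {
    p <- frame_positions(traj, f, unwrapped = TRUE)
    bv <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
    bl <- sqrt(rowSums(bv^2))
    u <- bv / bl
    b_sum <- b_sum + mean(bl)
    for (s in seq_len(nb - 1)) {
      corr_sum[s] <- corr_sum[s] +
        mean(rowSums(u[seq_len(nb - s), , drop = FALSE] *
                       u[seq_len(nb - s) + s, , drop = FALSE]))
    }
  }
  corr <- corr_sum / nf
  b <- b_sum / nf
  if (corr[1] <= 0)
    return(list(l_p = NA_real_, bond_length = b, correlation = corr,
                sub_bond = TRUE))
  keep <- seq_len(max(which(corr > fit_window)))
  keep <- keep[corr[keep] > 0]
  s <- keep
  # exponential decay: regression of log(corr) on s through the origin
  slope <- sum(s * log(corr[keep])) / sum(s^2)
  list(l_p = -b / slope, bond_length = b, correlation = corr,
       sub_bond = FALSE)
}

#' Compaction ratio
#'
#' R_g normalised by a reference R_g, typically the same chains with all
#' attractive interactions switched off (`lambda_PP = lambda_PD = 0`);
#' values below 1 indicate compaction.
#'
#' @param rg_observed Observed R_g (A).
#' @param rg_reference Reference R_g (A); must be positive.
#' @return Dimensionless ratio.
#' @export
compaction_ratio <- function(rg_observed, rg_reference) {
  if (any(rg_reference <= 0)) stop("reference R_g must be positive")
  rg_observed / rg_reference
}

#' Write per-chain observables as delimited text
#'
#' @param obs A `chain_observable`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_chain_observable <- function(obs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mean %.10g stderr %.10g units %s",
                     obs$mean, obs$stderr, obs$units), con)
  utils::write.table(obs$per_chain, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
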
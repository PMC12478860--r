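#' Minimum-image-consistent centre of mass
#'
#' Centre of mass of a subset of beads in a periodic box via the circular
#' (angular) mean: each coordinate is mapped to an angle on `[0, 2*pi)`,
#' the mean resultant angle is mapped back.  Well defined for any compact
#' cluster regardless of how it straddles the boundaries.
#'
#' @param positions n x 3 matrix of wrapped coordinates.
#' @param box_edge Box edge (A).
#' @param masses Optional weights.
#' @return Length-3 coordinate vector in `[0, box_edge)`.
#' @export
periodic_com <- function(positions, box_edge, masses = NULL) {
  positions <- as.matrix(positions)
  if (is.null(masses)) masses <- rep(1, nrow(positions))
  th <- positions / box_edge * 2 * pi
  s <- colSums(masses * sin(th)) / sum(masses)
  c_ <- colSums(masses * cos(th)) / sum(masses)
  ang <- atan2(s, c_) %% (2 * pi)
  ang / (2 * pi) * box_edge
}

#' Radial number-density profile
#'
#' Bins the minimum-image distances of a set of beads from a reference
#' point (typically the centre of mass of the largest-cluster proteins)
#' into spherical shells of width `bin_width` and converts counts to number
#' densities in beads/nm^3.  Shells extend far enough to hold every profiled
#' bead, so the counts always sum to the member count; fits normally use
#' the shells within half the box edge.
#'
#' @param positions n x 3 matrix of wrapped coordinates of the full system.
#' @param member_beads Indices of the beads to profile.
#' @param reference Length-3 reference point (A).
#' @param box_edge Box edge (A).
#' @param bin_width Shell width (A).
#' @return A `density_profile`: list with `shell_edges` (A), `r` (shell
#'   centres), `concentration` (beads/nm^3), `counts`.
#' @export
radial_density_profile <- function(positions, member_beads, reference,
                                   box_edge, bin_width = 10) {
  if (!length(member_beads)) stop("empty member set")
  p <- as.matrix(positions)[member_beads, , drop = FALSE]
  d <- sweep(p, 2, reference)
  d <- d - box_edge * round(d / box_edge)
  r <- sqrt(rowSums(d^2))
  n_shell <- max(ceiling(box_edge / 2 / bin_width),
                 ceiling(max(r) / bin_width) + 1L)
  edges <- seq(0, n_shell * bin_width, by = bin_width)
  counts <- tabulate(pmin(floor(r / bin_width), n_shell - 1L) + 1L, n_shell)
  vol_A3 <- 4 / 3 * pi * diff(edges^3)
  structure(list(shell_edges = edges,
                 r = (edges[-1] + edges[-length(edges)]) / 2,
                 concentration = counts / vol_A3 * 1000,  # beads/nm^3
                 counts = counts),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile: %d shells to %.4g A, %d beads\n",
              length(x$counts), max(x$shell_edges), sum(x$counts)))
  invisible(x)
}

double_tanh <- function(r, rho_dil, rho_II, rho_I, R_I, R_II, w_I, w_II) {
  rho_dil +
    (rho_II - rho_dil) / 2 * (1 - tanh((r - R_II) / w_II)) +
    (rho_I - rho_II) / 2 * (1 - tanh((r - R_I) / w_I))
}

#' Fit a double hyperbolic tangent to a radial density profile
#'
#' Least-squares fit of the two-step profile
#' \deqn{\rho(r) = \rho_{dil}
#'   + \tfrac{\rho_{II}-\rho_{dil}}{2}\left[1-\tanh\frac{r-R_{II}}{w_{II}}\right]
#'   + \tfrac{\rho_I-\rho_{II}}{2}\left[1-\tanh\frac{r-R_I}{w_I}\right]}
#' describing an inner dense phase-I (density `rho_I` out to interphase
#' `R_I`), an intermediate dense phase-II (`rho_II` out to `R_II`) and a
#' dilute background.  The form reduces to a single interface when the
#' inner amplitude vanishes.  Ten deterministic starts seeded from profile
#' quantiles are tried (Levenberg-Marquardt with box constraints); the best
#' residual wins, ties broken towards smaller `R_I`.  The profile is
#' declared multiphasic when the fitted inner step `rho_I - rho_II` exceeds
#' `sig_mult` times the rms residual and a small fraction of the total
#' density drop.
#'
#' @param profile A `density_profile` with at least 20 shells (shells within
#'   `r_max` are used).
#' @param r_max Fit range (A); default the largest shell edge.
#' @param sig_mult Significance multiple for the multiphasic flag.
#' @return A `density_profile_fit`: list with `rho_I`, `rho_II`, `rho_dil`
#'   (beads/nm^3), `R_I`, `R_II`, `w_I`, `w_II` (A), `rms_residual`,
#'   `multiphasic`, `converged`.
#' @export
fit_double_tanh <- function(profile, r_max = NULL, sig_mult = 3) {
  r <- profile$r
  y <- profile$concentration
  if (!is.null(r_max)) {
    keep <- r <= r_max
    r <- r[keep]; y <- y[keep]
  }
  if (length(r) < 20) stop("need at least 20 shells to fit")
  rng <- max(r)
  ymax <- max(y)
  if (ymax <= 0 || stats::sd(y) == 0)
    return(structure(list(rho_I = NA_real_, rho_II = NA_real_,
                          rho_dil = mean(y), R_I = NA_real_, R_II = NA_real_,
                          w_I = NA_real_, w_II = NA_real_,
                          rms_residual = 0, multiphasic = FALSE,
                          converged = FALSE),
                     class = "density_profile_fit"))
  resid_fun <- function(par) {
    y - double_tanh(r, par[1], par[2], par[3], par[4], par[5], par[6], par[7])
  }
  lower <- c(0, 0, 0, 0, 0, 1e-3, 1e-3)
  upper <- c(ymax * 2, ymax * 2, ymax * 2, rng, rng, rng, rng)
  # deterministic multi-starts from profile quantiles
  q <- stats::quantile(r[y > 0.05 * ymax], c(0.2, 0.4, 0.6, 0.8),
                       names = FALSE)
  starts <- list()
  for (fR1 in c(q[1], q[2])) {
    for (fR2 in c(q[3], q[4])) {
      if (fR2 <= fR1) next
      starts[[length(starts) + 1]] <-
        c(min(y), mean(y), ymax, fR1, fR2, rng / 20, rng / 20)
    }
  }
  starts[[length(starts) + 1]] <- c(0, ymax / 2, ymax, rng / 4, rng / 2,
                                    rng / 10, rng / 10)
  starts[[length(starts) + 1]] <- c(0, ymax / 3, ymax, rng / 6, rng / 3,
                                    rng / 30, rng / 30)
  while (length(starts) < 10) {
    k <- length(starts)
    starts[[k + 1]] <- c(0, ymax * k / 12, ymax, rng * k / 20, rng * (k + 4) / 20,
                         rng / 15, rng / 15)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(st, lower), upper), fn = resid_fun,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && fit$par[4] < best$par[4])) {
      best <- list(par = fit$par, rss = rss)
    }
  }
  if (is.null(best))
    return(structure(list(rho_I = NA_real_, rho_II = NA_real_,
                          rho_dil = NA_real_, R_I = NA_real_,
                          R_II = NA_real_, w_I = NA_real_, w_II = NA_real_,
                          rms_residual = NA_real_, multiphasic = FALSE,
                          converged = FALSE),
                     class = "density_profile_fit"))
  par <- best$par
  # order the two steps so R_I <= R_II
  if (par[4] > par[5]) {
    par <- c(par[1], par[3] + par[1] - par[2], par[3],
             par[5], par[4], par[7], par[6])
    # re-fit once from the swapped start to restore exact parameterisation
    fit <- minpack.lm::nls.lm(par = pmin(pmax(par, lower), upper),
                              fn = resid_fun, lower = lower, upper = upper)
    par <- fit$par
    best$rss <- sum(fit$fvec^2)
  }
  rms <- sqrt(best$rss / length(r))
  amp_inner <- par[3] - par[2]
  span <- max(par[3] - par[1], ymax)
  multi <- isTRUE(amp_inner > sig_mult * rms && amp_inner > 0.02 * span &&
                    par[4] < par[5])
  structure(list(rho_I = par[3], rho_II = par[2], rho_dil = par[1],
                 R_I = par[4], R_II = par[5], w_I = par[6], w_II = par[7],
                 rms_residual = rms, multiphasic = multi, converged = TRUE),
            class = "density_profile_fit")
}

#' @export
print.density_profile_fit <- function(x, ...) {
  cat(sprintf(paste0("density profile fit: rho_I %.4g, rho_II %.4g, ",
                     "rho_dil %.4g beads/nm^3\n  R_I %.4g A (w %.3g), ",
                     "R_II %.4g A (w %.3g); rms %.3g; %s\n"),
              x$rho_I, x$rho_II, x$rho_dil, x$R_I, x$w_I, x$R_II, x$w_II,
              x$rms_residual,
              if (isTRUE(x$multiphasic)) "multiphasic" else "single-phase"))
  invisible(x)
}

#' Single hyperbolic tangent fit
#'
#' One-interface counterpart of [fit_double_tanh]:
#' `rho(r) = rho_dil + (rho_den - rho_dil)/2 * [1 - tanh((r - R)/w)]`.
#'
#' @inheritParams fit_double_tanh
#' @return List with `rho_den`, `rho_dil`, `R`, `w`, `rms_residual`,
#'   `converged`.
#' @export
fit_single_tanh <- function(profile, r_max = NULL) {
  r <- profile$r
  y <- profile$concentration
  if (!is.null(r_max)) {
    keep <- r <= r_max
    r <- r[keep]; y <- y[keep]
  }
  ymax <- max(y)
  rng <- max(r)
  resid_fun <- function(par)
    y - (par[1] + (par[2] - par[1]) / 2 * (1 - tanh((r - par[3]) / par[4])))
  lower <- c(0, 0, 0, 1e-3)
  upper <- c(ymax * 2, ymax * 2, rng, rng)
  best <- NULL
  for (R0 in c(rng / 6, rng / 4, rng / 2, rng * 0.75)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(min(y), ymax, R0, rng / 20),
                         fn = resid_fun, lower = lower, upper = upper),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    return(list(rho_den = NA_real_, rho_dil = NA_real_, R = NA_real_,
                w = NA_real_, rms_residual = NA_real_, converged = FALSE))
  list(rho_den = best$par[2], rho_dil = best$par[1], R = best$par[3],
       w = best$par[4], rms_residual = sqrt(best$rss / length(r)),
       converged = TRUE)
}

#' Radial concentration gradient
#'
#' Central finite differences of the shell densities on the shell centres;
#' one-sided at the ends.
#'
#' @param profile A `density_profile` with at least 3 shells.
#' @return Numeric vector, beads/nm^3 per A.
#' @export
density_gradient <- function(profile) {
  y <- profile$concentration
  r <- profile$r
  n <- length(y)
  stopifnot(n >= 3)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (r[2] - r[1])
  g[n] <- (y[n] - y[n - 1]) / (r[n] - r[n - 1])
  for (i in 2:(n - 1)) g[i] <- (y[i + 1] - y[i - 1]) / (r[i + 1] - r[i - 1])
  g
}

#' Coexistence (dilute and dense) protein concentrations
#'
#' Per frame: identify the largest cluster, centre the radial protein
#' density profile on its protein centre of mass, fit a tanh envelope
#' (double if the profile is multiphasic, single otherwise) and average the
#' density inside the innermost plateau (`r < R_inner - 2 w_inner`) and
#' beyond the outermost interface (`r > R_outer + 2 w_outer`).  The frame
#' series are block-averaged.  When no condensate is present (largest
#' cluster holds less than `min_cluster_fraction` of the proteins) the
#' dense branch is reported absent and the dilute concentration is the
#' global protein density.
#'
#' @param traj A `cg_trajectory`.
#' @param topo A [cg_topology].
#' @param blocks A [block_scheme].
#' @param bin_width Shell width (A).
#' @param cutoff Cluster linking distance (A).
#' @param min_cluster_fraction Condensate-present threshold on f_P.
#' @param per_pair Use per-species-pair cluster cutoffs (see
#'   [cluster_beads]).
#' @return List with `c_dilute`, `c_dense` (`list(mean, stderr)`;
#'   `c_dense` is `NULL` when no condensate), `multiphasic` (fraction of
#'   frames flagged multiphasic), `per_frame` data frame.
#' @export
coexistence_concentrations <- function(traj, topo, blocks = block_scheme(),
                                       bin_width = 10,
                                       cutoff = 1.5 * pair_sigma("protein", "dna"),
                                       min_cluster_fraction = 0.2,
                                       per_pair = FALSE) {
  nf <- n_frames(traj)
  is_p <- traj$species == "protein"
  dil <- den <- rep(NA_real_, nf)
  multi <- logical(nf)
  has_cond <- logical(nf)
  vol_nm3 <- (traj$box_edge / 10)^3
  for (f in seq_len(nf)) {
    p <- traj$positions[[f]]
    cl <- cluster_beads(p, traj$box_edge, cutoff, species = traj$species,
                        per_pair = per_pair)
    fr <- largest_cluster_fractions(cl, topo)
    if (fr$f_P < min_cluster_fraction) {
      dil[f] <- sum(is_p) / vol_nm3
      next
    }
    has_cond[f] <- TRUE
    members <- which(cl$labels == fr$largest_id & is_p)
    ref <- periodic_com(p[members, , drop = FALSE], traj$box_edge)
    prof <- radial_density_profile(p, which(is_p), ref, traj$box_edge,
                                   bin_width)
    dfit <- fit_double_tanh(prof, r_max = traj$box_edge / 2)
    if (isTRUE(dfit$multiphasic)) {
      multi[f] <- TRUE
      r_in <- dfit$R_I - 2 * dfit$w_I
      r_out <- dfit$R_II + 2 * dfit$w_II
    } else {
      sfit <- fit_single_tanh(prof, r_max = traj$box_edge / 2)
      r_in <- sfit$R - 2 * sfit$w
      r_out <- sfit$R + 2 * sfit$w
    }
    inside <- prof$r < r_in
    outside <- prof$r > r_out & prof$r <= traj$box_edge / 2
    if (any(inside))
      den[f] <- sum(prof$counts[inside]) /
        sum(4 / 3 * pi * diff(prof$shell_edges^3)[inside]) * 1000
    if (any(outside))
      dil[f] <- sum(prof$counts[outside]) /
        sum(4 / 3 * pi * diff(prof$shell_edges^3)[outside]) * 1000
  }
  out <- list(per_frame = data.frame(time = traj$times, c_dilute = dil,
                                     c_dense = den, multiphasic = multi),
              multiphasic = mean(multi))
  ok_dil <- !is.na(dil)
  out$c_dilute <- if (sum(ok_dil) >= blocks$n_blocks)
    block_average(dil[ok_dil], blocks)
  else list(mean = mean(dil, na.rm = TRUE), stderr = NA_real_)
  if (any(has_cond) && sum(!is.na(den)) >= blocks$n_blocks) {
    out$c_dense <- block_average(den[!is.na(den)], blocks)
  } else if (any(!is.na(den))) {
    out$c_dense <- list(mean = mean(den, na.rm = TRUE), stderr = NA_real_)
  } else {
    out$c_dense <- NULL
  }
  out
}

#' Write a profile and its fit as delimited text
#'
#' @param profile A `density_profile`.
#' @param path Output file.
#' @param fit Optional `density_profile_fit` stored as header key-values.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, fit = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(fit))
    writeLines(sprintf(
      "# rho_I %.10g rho_II %.10g rho_dil %.10g R_I %.10g R_II %.10g w_I %.10g w_II %.10g multiphasic %s",
      fit$rho_I, fit$rho_II, fit$rho_dil, fit$R_I, fit$R_II, fit$w_I,
      fit$w_II, isTRUE(fit$multiphasic)), con)
  utils::write.table(
    data.frame(r = profile$r, concentration = profile$concentration,
               counts = profile$counts),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
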
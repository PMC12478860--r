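#' Radial displacement distribution
#'
#' Histogram of the magnitudes of single-particle displacements over a lag
#' time, pooled over all protein beads and all frame pairs separated by the
#' lag (overlapping time origins).  Displacements are computed on unwrapped
#' coordinates.  Probability mass per bin sums to one.
#'
#' @param traj A `cg_trajectory`.
#' @param lag Lag time in ns; must be a multiple of the frame interval.
#' @param n_bins Number of equal-width bins from 0 to the largest
#'   displacement.
#' @param species Which species to track (default protein).
#' @return A `displacement_distribution`: list with `lag` (ns),
#'   `bin_edges` (A), `r` (bin centres), `probability` (per-bin mass),
#'   `density` (mass / bin width, 1/A), `n_samples`.
#' @export
displacement_distribution <- function(traj, lag, n_bins = 300,
                                      species = "protein") {
  nf <- n_frames(traj)
  stopifnot(nf >= 2)
  dt_frame <- (traj$times[2] - traj$times[1]) * 1e-6  # ns
  steps <- lag / dt_frame
  if (abs(steps - round(steps)) > 1e-6)
    stop("lag must be a multiple of the frame interval")
  steps <- as.integer(round(steps))
  if (steps < 1 || steps >= nf)
    stop("lag outside the trajectory span")
  sel <- traj$species == species
  if (!any(sel)) stop("no beads of the requested species")
  disp <- numeric(0)
  rs <- vector("list", nf - steps)
  for (f in seq_len(nf - steps)) {
    p0 <- frame_positions(traj, f, unwrapped = TRUE)[sel, , drop = FALSE]
    p1 <- frame_positions(traj, f + steps, unwrapped = TRUE)[sel, , drop = FALSE]
    rs[[f]] <- sqrt(rowSums((p1 - p0)^2))
  }
  disp <- unlist(rs)
  displacement_histogram(disp, lag, n_bins)
}

#' Bin radial displacement samples
#'
#' @param disp Radial displacement samples (A).
#' @param lag Lag time (ns) attached to the result.
#' @param n_bins Number of bins.
#' @return A `displacement_distribution` (see
#'   [displacement_distribution]).
#' @export
displacement_histogram <- function(disp, lag, n_bins = 300) {
  rmax <- max(disp) * (1 + 1e-9)
  if (rmax <= 0) rmax <- 1   # static input: all mass lands in the first bin
  edges <- seq(0, rmax, length.out = n_bins + 1)
  counts <- tabulate(pmin(floor(disp / (rmax / n_bins)), n_bins - 1L) + 1L,
                     n_bins)
  prob <- counts / sum(counts)
  structure(list(lag = lag, bin_edges = edges,
                 r = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 probability = prob,
                 density = prob / (rmax / n_bins),
                 n_samples = length(disp)),
            class = "displacement_distribution")
}

#' @export
print.displacement_distribution <- function(x, ...) {
  cat(sprintf(
    "displacement_distribution: lag %.4g ns, %d bins, %d samples\n",
    x$lag, length(x$probability), x$n_samples))
  invisible(x)
}

#' Multi-mode radial propagator density
#'
#' The population-weighted sum of 3-D Gaussian propagators expressed as a
#' radial density:
#' \deqn{P(r,t) = \sum_i p_i \frac{4\pi r^2}{(4\pi D_i t)^{3/2}}
#'   e^{-r^2 / 4 D_i t}, \qquad \sum_i p_i = 1.}
#'
#' @param r Radial displacement(s) (A).
#' @param t Lag time (ns).
#' @param p Mode fractions (must sum to 1).
#' @param D Mode diffusivities (A^2/ns, all positive).
#' @return Probability density (1/A), vectorised over `r`.
#' @export
mixture_pdf <- function(r, t, p, D) {
  stopifnot(length(p) == length(D), t > 0)
  if (abs(sum(p) - 1) > 1e-9) stop("mode fractions must sum to 1")
  if (any(D <= 0) || any(p < 0)) stop("modes need D > 0 and p >= 0")
  out <- 0
  for (i in seq_along(p))
    out <- out + p[i] * 4 * pi * r^2 / (4 * pi * D[i] * t)^1.5 *
      exp(-r^2 / (4 * D[i] * t))
  out
}

#' Sample radial displacements from a multi-mode propagator
#'
#' Draws a mode per `p`, then a radial distance from the 3-D Gaussian
#' propagator with per-axis variance `2 D_i t`.  Deterministic per seed;
#' the known-truth generator for round-trip tests of the mixture fit.
#'
#' @inheritParams mixture_pdf
#' @param n_samples Number of draws.
#' @param seed Integer RNG seed.
#' @return Numeric vector of radial displacements (A).
#' @export
sample_displacements <- function(p, D, t, n_samples, seed = 1) {
  stopifnot(length(p) == length(D), t > 0, all(D > 0), all(p >= 0))
  if (abs(sum(p) - 1) > 1e-9) stop("mode fractions must sum to 1")
  set.seed(seed)
  comp <- sample.int(length(p), n_samples, replace = TRUE, prob = p)
  sd_ax <- sqrt(2 * D[comp] * t)
  sqrt(stats::rnorm(n_samples, sd = sd_ax)^2 +
         stats::rnorm(n_samples, sd = sd_ax)^2 +
         stats::rnorm(n_samples, sd = sd_ax)^2)
}

softmax <- function(a) {
  e <- exp(c(a, 0) - max(a, 0))
  e / sum(e)
}

fit_modes_one <- function(dist, n, weight_floor = 1e-4) {
  r <- dist$r
  y <- dist$density
  w <- 1 / pmax(y, weight_floor * max(y))
  t <- dist$lag
  # data-driven D range: r^2 / 4t spans the candidate diffusivities
  r2 <- (r[y > 0])^2 / (4 * t)
  lo <- log(max(min(r2), 1e-8))
  hi <- log(max(r2))
  resid_fun <- function(par) {
    D <- exp(par[seq_len(n)])
    p <- if (n == 1) 1 else softmax(par[(n + 1):(2 * n - 1)])
    sqrt(w) * (y - mixture_pdf(r, t, p, D))
  }
  starts <- list()
  for (k in 0:9) {
    span <- 0.5 + 0.5 * (k %% 5) / 4          # fraction of the log range
    shift <- (k %/% 5) * 0.25 * (hi - lo)
    ctr <- (lo + hi) / 2 + shift * (if (k %% 2) 1 else -1) * 0.3
    half <- span * (hi - lo) / 2
    logD <- if (n == 1) ctr else seq(ctr + half, ctr - half, length.out = n)
    starts[[k + 1]] <- c(logD, rep(0, n - 1))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) return(NULL)
  D <- exp(best$par[seq_len(n)])
  p <- if (n == 1) 1 else softmax(best$par[(n + 1):(2 * n - 1)])
  ord <- order(D, decreasing = TRUE)
  yhat <- mixture_pdf(r, t, p, D)
  list(p = p[ord], D = D[ord],
       rms_residual = sqrt(mean((y - yhat)^2)),
       weighted_rss = best$rss)
}

#' Fit a multi-mode diffusion model to displacement distributions
#'
#' Weighted least squares of the multi-mode propagator ([mixture_pdf])
#' against one or several binned displacement distributions, one fit per
#' lag.  Fractions are constrained to the simplex (softmax parameterisation)
#' and diffusivities kept positive (log parameterisation); per-bin weights
#' are `1 / max(P, floor)`.  Ten deterministic multi-starts with log-spaced
#' diffusivity ladders spanning the data's `r^2 / 4t` range are tried per
#' lag.  Modes are reported sorted by decreasing diffusivity.
#'
#' @param dists A `displacement_distribution` or a list of them (one per
#'   lag).
#' @param n Number of modes.
#' @return A `diffusion_mode_fit`: list with `n_modes`, `p` and `D`
#'   (averaged over lags, sorted by decreasing D), `per_lag` (data frame of
#'   lag, mode, p, D), `rms_residual` (rms over all lags).
#' @export
fit_diffusion_modes <- function(dists, n) {
  stopifnot(n >= 1)
  if (inherits(dists, "displacement_distribution")) dists <- list(dists)
  fits <- lapply(dists, fit_modes_one, n = n)
  if (any(vapply(fits, is.null, logical(1))))
    stop("mode fit failed to converge for at least one lag")
  per_lag <- do.call(rbind, lapply(seq_along(fits), function(i)
    data.frame(lag = dists[[i]]$lag, mode = seq_len(n),
               p = fits[[i]]$p, D = fits[[i]]$D)))
  D <- colMeans(do.call(rbind, lapply(fits, `[[`, "D")))
  p <- colMeans(do.call(rbind, lapply(fits, `[[`, "p")))
  p <- p / sum(p)
  structure(list(n_modes = n, p = p, D = D, per_lag = per_lag,
                 rms_residual = sqrt(mean(vapply(fits, function(f)
                   f$rms_residual^2, numeric(1))))),
            class = "diffusion_mode_fit")
}

#' @export
print.diffusion_mode_fit <- function(x, ...) {
  cat(sprintf("diffusion_mode_fit: %d mode(s), rms residual %.3g\n",
              x$n_modes, x$rms_residual))
  for (i in seq_len(x$n_modes))
    cat(sprintf("  mode %d: D = %.4g A^2/ns, p = %.3f\n", i, x$D[i], x$p[i]))
  invisible(x)
}

#' Select the number of diffusion modes
#'
#' Fits an increasing number of modes jointly across the supplied lags and
#' returns the smallest `n` for which adding one more mode either improves
#' the rms residual by less than `improvement_threshold` (relative) or
#' introduces a mode with fractional population below `p_min` at every lag
#' - the operational version of increasing the mode count "until the fit
#' achieves minimal residuals".
#'
#' @param dists A `displacement_distribution` or list of them.
#' @param n_max Largest mode count considered.
#' @param improvement_threshold Minimum relative rms improvement that
#'   justifies an extra mode (default 0.2).
#' @param p_min Smallest meaningful mode population (default 0.01).
#' @return Selected mode count (integer).
#' @export
select_mode_count <- function(dists, n_max = 6,
                              improvement_threshold = 0.2, p_min = 0.01) {
  stopifnot(n_max >= 1)
  if (inherits(dists, "displacement_distribution")) dists <- list(dists)
  fits <- vector("list", n_max)
  fit_or_null <- function(n)
    tryCatch(fit_diffusion_modes(dists, n), error = function(e) NULL)
  fits[[1]] <- fit_or_null(1)
  for (n in seq_len(n_max - 1)) {
    cur <- fits[[n]]
    nxt <- fit_or_null(n + 1)
    fits[[n + 1]] <- nxt
    if (is.null(cur)) next
    if (is.null(nxt)) return(n)
    improvement <- (cur$rms_residual - nxt$rms_residual) /
      cur$rms_residual
    if (improvement < improvement_threshold) return(n)
    if (min(nxt$p) < p_min) return(n)
  }
  n_max
}

#' Write displacement distributions and fits as delimited text
#'
#' @param dist A `displacement_distribution`.
#' @param path Output file.
#' @param fit Optional `diffusion_mode_fit` recorded as header key-values.
#' @return `path`, invisibly.
#' @export
write_displacement <- function(dist, path, fit = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lag_ns %.10g n_samples %d", dist$lag,
                     dist$n_samples), con)
  if (!is.null(fit))
    writeLines(sprintf("# modes %d D %s p %s", fit$n_modes,
                       paste(sprintf("%.10g", fit$D), collapse = ","),
                       paste(sprintf("%.10g", fit$p), collapse = ",")), con)
  utils::write.table(
    data.frame(r = dist$r, probability = dist$probability,
               density = dist$density),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
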
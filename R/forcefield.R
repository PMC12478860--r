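#' Force-field parameters for the coarse-grained protein-DNA model
#'
#' Bundles every interaction constant of the model: a single-bead protein
#' species and a bead-spring DNA species interacting through an
#' Ashbaugh-Hatch pair potential, harmonic bonds and harmonic angles.
#' The defaults are the published parameterisation of the model:
#' \eqn{\epsilon = 0.2} kcal/mol, \eqn{\sigma_P = 50} A, \eqn{\sigma_D = 5} A,
#' protein mass 5000 g/mol, DNA bead mass 500 g/mol (one bead per base pair),
#' \eqn{K_b = 20} kcal/mol/A^2 with \eqn{r_0 = 5.5} A, \eqn{\theta_0 = \pi}
#' and \eqn{\lambda_{DD} = -1} (purely repulsive DNA-DNA interactions).
#' Harmonic terms carry no 1/2 prefactor: \eqn{U = K (x - x_0)^2}.
#'
#' The pair potential is truncated (unshifted) at `cutoff_factor * sigma_ij`;
#' the model itself does not prescribe a cutoff, so the factor is
#' configurable with default 3, which retains essentially all of the
#' attractive tail.
#'
#' @param epsilon Interaction strength (kcal/mol).
#' @param sigma_P,sigma_D Bead diameters (A).
#' @param mass_P,mass_D Bead masses (g/mol).
#' @param lambda_PP,lambda_PD,lambda_DD Hydropathy scalings of the attractive
#'   branch for protein-protein, protein-DNA and DNA-DNA pairs.
#' @param K_b Bond spring constant (kcal/mol/A^2).
#' @param r0 Equilibrium bond length (A).
#' @param K_theta Angle spring constant (kcal/mol/rad^2).
#' @param theta0 Equilibrium angle (rad); `pi` means a straight chain.
#' @param cutoff_factor Nonbonded cutoff as a multiple of `sigma_ij`; must
#'   exceed `2^(1/6)` so the attractive branch exists.
#' @return An object of class `ff_params` (a named list).
#' @export
#' @examples
#' ff <- ff_params(lambda_PP = 3, lambda_PD = 0.5)
#' pair_sigma("protein", "dna", ff)
ff_params <- function(epsilon = 0.2, sigma_P = 50, sigma_D = 5,
                      mass_P = 5000, mass_D = 500,
                      lambda_PP = 1, lambda_PD = 1, lambda_DD = -1,
                      K_b = 20, r0 = 5.5, K_theta = 20, theta0 = pi,
                      cutoff_factor = 3) {
  stopifnot(epsilon > 0, sigma_P > 0, sigma_D > 0, mass_P > 0, mass_D > 0,
            K_b > 0, K_theta >= 0, r0 > 0)
  if (cutoff_factor <= 2^(1/6))
    stop("cutoff_factor must exceed 2^(1/6) (the potential minimum)")
  structure(list(epsilon = epsilon, sigma_P = sigma_P, sigma_D = sigma_D,
                 mass_P = mass_P, mass_D = mass_D,
                 lambda_PP = lambda_PP, lambda_PD = lambda_PD,
                 lambda_DD = lambda_DD,
                 K_b = K_b, r0 = r0, K_theta = K_theta, theta0 = theta0,
                 cutoff_factor = cutoff_factor),
            class = "ff_params")
}

#' @export
print.ff_params <- function(x, ...) {
  cat("Coarse-grained protein-DNA force field\n")
  cat(sprintf("  epsilon  %.4g kcal/mol   cutoff %.3g sigma_ij\n",
              x$epsilon, x$cutoff_factor))
  cat(sprintf("  protein: sigma %.4g A, mass %.4g g/mol\n", x$sigma_P, x$mass_P))
  cat(sprintf("  dna    : sigma %.4g A, mass %.4g g/mol\n", x$sigma_D, x$mass_D))
  cat(sprintf("  lambda : PP %.3g  PD %.3g  DD %.3g\n",
              x$lambda_PP, x$lambda_PD, x$lambda_DD))
  cat(sprintf("  bonds  : K_b %.4g kcal/mol/A^2, r0 %.4g A\n", x$K_b, x$r0))
  cat(sprintf("  angles : K_theta %.4g kcal/mol/rad^2, theta0 %.4g rad\n",
              x$K_theta, x$theta0))
  invisible(x)
}

species_code <- function(species) {
  code <- match(species, c("protein", "dna"))
  if (anyNA(code))
    stop("unknown species label(s): ",
         paste(unique(species[is.na(code)]), collapse = ", "),
         " (expected 'protein' or 'dna')")
  code - 1L
}

#' Combined pair diameter
#'
#' Arithmetic-mean (Lorentz) combination rule for the pair diameter,
#' `sigma_ij = (sigma_i + sigma_j) / 2`.
#'
#' @param species_i,species_j Species labels, `"protein"` or `"dna"`.
#' @param ff A [ff_params] object.
#' @return The combined diameter in A.
#' @export
pair_sigma <- function(species_i, species_j, ff = ff_params()) {
  sig <- c(ff$sigma_P, ff$sigma_D)
  (sig[species_code(species_i) + 1L] + sig[species_code(species_j) + 1L]) / 2
}

#' Hydropathy for a species pair
#'
#' @inheritParams pair_sigma
#' @return The dimensionless lambda for the pair.
#' @export
pair_lambda <- function(species_i, species_j, ff = ff_params()) {
  i <- species_code(species_i)
  j <- species_code(species_j)
  lam <- matrix(c(ff$lambda_PP, ff$lambda_PD, ff$lambda_PD, ff$lambda_DD), 2, 2)
  lam[cbind(i + 1L, j + 1L)]
}

lj_energy <- function(r, sigma, epsilon) {
  s6 <- (sigma / r)^6
  4 * epsilon * (s6^2 - s6)
}

#' Ashbaugh-Hatch pair energy
#'
#' The nonbonded potential scales the attractive part of a Lennard-Jones
#' interaction by the hydropathy `lambda_ij` while leaving the short-range
#' repulsion untouched:
#' \deqn{U_{nb}(r) = U_{LJ}(r) + (1-\lambda)\epsilon \quad (r \le 2^{1/6}\sigma)}
#' \deqn{U_{nb}(r) = \lambda\, U_{LJ}(r) \quad (r > 2^{1/6}\sigma)}
#' with the standard \eqn{U_{LJ}(r) = 4\epsilon[(\sigma/r)^{12}-(\sigma/r)^6]}.
#' Both branches equal \eqn{-\lambda\epsilon} at \eqn{r = 2^{1/6}\sigma}, so
#' the potential is continuous there for every lambda.  The potential is
#' truncated to zero at `ff$cutoff_factor * sigma_ij` without shifting.
#'
#' @param r Interbead distance(s) in A; must be positive.
#' @param sigma_ij Combined pair diameter (A).
#' @param lambda_ij Pair hydropathy.
#' @param ff A [ff_params] object (supplies `epsilon` and the cutoff rule).
#' @return Energy in kcal/mol (vectorised over `r`).
#' @export
#' @examples
#' pair_energy(2^(1/6) * 50, 50, 1)   # the full well depth, -epsilon
pair_energy <- function(r, sigma_ij, lambda_ij, ff = ff_params()) {
  if (any(r <= 0)) stop("pair distances must be positive")
  u <- ifelse(r <= 2^(1/6) * sigma_ij,
              lj_energy(r, sigma_ij, ff$epsilon) + (1 - lambda_ij) * ff$epsilon,
              lambda_ij * lj_energy(r, sigma_ij, ff$epsilon))
  u[r >= ff$cutoff_factor * sigma_ij] <- 0
  u
}

#' Ashbaugh-Hatch pair force
#'
#' Radial force `-dU/dr` of [pair_energy], analytic.  Zero at the potential
#' minimum `2^(1/6) sigma_ij` and beyond the cutoff.
#'
#' @inheritParams pair_energy
#' @return Force in kcal/mol/A (positive = repulsive), vectorised over `r`.
#' @export
pair_force <- function(r, sigma_ij, lambda_ij, ff = ff_params()) {
  if (any(r <= 0)) stop("pair distances must be positive")
  s6 <- (sigma_ij / r)^6
  f_lj <- 24 * ff$epsilon * (2 * s6^2 - s6) / r   # -dU_LJ/dr
  f <- ifelse(r <= 2^(1/6) * sigma_ij, f_lj, lambda_ij * f_lj)
  f[r >= ff$cutoff_factor * sigma_ij] <- 0
  f
}

#' Harmonic bond energy
#'
#' `U = K_b (r - r0)^2`, with no 1/2 prefactor (the spring constant is used
#' exactly as printed in the model definition).
#'
#' @param r Bond length(s) in A; must be positive.
#' @param ff A [ff_params] object.
#' @return Energy in kcal/mol.
#' @export
bond_energy <- function(r, ff = ff_params()) {
  if (any(r <= 0)) stop("bond lengths must be positive")
  ff$K_b * (r - ff$r0)^2
}

#' Harmonic angle energy
#'
#' `U = K_theta (theta - theta0)^2` for the interior angle between two
#' successive bonds (no 1/2 prefactor); `theta0 = pi` is a straight chain.
#'
#' @param theta Angle(s) in radians, in `[0, pi]`.
#' @param ff A [ff_params] object.
#' @return Energy in kcal/mol.
#' @export
angle_energy <- function(theta, ff = ff_params()) {
  if (any(theta < 0 | theta > pi))
    stop("angles must lie in [0, pi] radians")
  ff$K_theta * (theta - ff$theta0)^2
}

#' Read / write force-field parameters
#'
#' Serialises a [ff_params] object to a plain-text YAML key-value file and
#' back.  Keys absent from the file take the default values, so a file
#' containing only overrides is valid; unknown keys are rejected.
#'
#' @param ff A [ff_params] object.
#' @param path File path.
#' @return `read_ff` returns a [ff_params] object; `write_ff` returns `path`
#'   invisibly.
#' @export
write_ff <- function(ff, path) {
  yaml::write_yaml(unclass(ff), path)
  invisible(path)
}

#' @rdname write_ff
#' @export
read_ff <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(ff_params))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown force-field keys: ", paste(bad, collapse = ", "))
  do.call(ff_params, vals)
}
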
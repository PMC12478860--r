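## Internal unit system: length in Angstrom, mass in g/mol, energy in
## kcal/mol.  The derived time unit is tau = sqrt(g/mol * A^2 / (kcal/mol));
## user-facing times are fs/ps/ns and are converted on input/output.

#' Physical constants and unit conversions
#'
#' The package works internally in Angstrom / (g/mol) / (kcal/mol) units.
#' `kB` is Boltzmann's constant in kcal/mol/K; `time_unit_fs` is the derived
#' internal time unit expressed in femtoseconds (about 48.89 fs).
#'
#' @format `kB` and `time_unit_fs` are numeric scalars.
#' @name units
NULL

#' @rdname units
#' @export
kB <- 0.0019872

#' @rdname units
#' @export
time_unit_fs <- sqrt(1e-3 * 1e-20 / 4184) * 1e15

fs_to_internal <- function(t_fs) t_fs / time_unit_fs
ps_to_internal <- function(t_ps) t_ps * 1000 / time_unit_fs
internal_to_fs <- function(t) t * time_unit_fs
internal_to_ns <- function(t) t * time_unit_fs * 1e-6
ns_to_internal <- function(t_ns) t_ns * 1e6 / time_unit_fs
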
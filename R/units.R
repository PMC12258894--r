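#' Physical constants and unit conversions
#'
#' Conversion factors used throughout the package. Internally free energies
#' are kept in the units they arrive in and converted to electron-volts for
#' any quantity of the form charge times voltage; electrostatic potentials
#' are computed in Gaussian units of e/Angstrom and exported in millivolts.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kcalmol_to_ev}{1 kcal/mol per particle in eV (0.0433641).}
#'   \item{e_per_ang_to_volt}{Potential of e/Angstrom in volts (14.39964).}
#'   \item{elementary_charge_C}{Elementary charge in coulombs.}
#'   \item{R_kcal}{Gas constant in kcal/(mol K).}
#' }
#' @export
vg_constants <- list(
  kcalmol_to_ev       = 0.0433641,
  e_per_ang_to_volt   = 14.39964,
  elementary_charge_C = 1.602176634e-19,
  R_kcal              = 0.0019872041
)

#' Convert a free energy to electron-volts
#'
#' @param x numeric free energy values.
#' @param units one of \code{"kcal/mol"} or \code{"eV"}.
#' @return numeric, in eV.
#' @export
to_ev <- function(x, units) {
  switch(match.arg(units, c("kcal/mol", "eV")),
         "kcal/mol" = x * vg_constants$kcalmol_to_ev,
         "eV" = x)
}
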
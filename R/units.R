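#' @keywords internal
"_PACKAGE"

## Avogadro constant (molecules per mole), CODATA exact value.
AVOGADRO <- 6.02214076e23

#' Convert molecule counts to molar concentration
#'
#' Copy numbers per cell are converted to concentrations assuming the
#' molecules are dissolved in a well-mixed compartment of volume
#' `volume` litres (default 2e-12 L, a typical mammalian cytoplasmic
#' volume).
#'
#' @param copies molecules per cell (numeric vector).
#' @param volume compartment volume in litres.
#' @return concentration in molar.
#' @export
copies_to_molar <- function(copies, volume = 2e-12) {
  stopifnot(is.numeric(copies), volume > 0)
  copies / (AVOGADRO * volume)
}

#' @rdname copies_to_molar
#' @param conc concentration in molar.
#' @export
molar_to_copies <- function(conc, volume = 2e-12) {
  stopifnot(is.numeric(conc), volume > 0)
  conc * AVOGADRO * volume
}
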
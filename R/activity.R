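#' Davies single-ion activity coefficient
#'
#' log10(gamma) = -A z^2 (sqrt(I)/(1+sqrt(I)) - 0.3 I) with A = 0.509.
#' Appropriate at the low ionic strength of neutralized AMD (~10 mmol/L).
#' Neutral species get gamma = 1; the coefficient is capped at 1.2 where the
#' linear Davies term dominates at high ionic strength.
#'
#' @param charge Integer charge of the ion (elementary units).
#' @param ionic_strength Ionic strength in mol/L, must be >= 0.
#' @param temperature degC; accepted for interface symmetry, the
#'   Debye-Hueckel slope is held at its 25 degC value.
#' @return Dimensionless activity coefficient in (0, 1.2].
#' @export
activity_coefficient <- function(charge, ionic_strength, temperature = 25) {
  if (any(ionic_strength < 0)) {
    stop("ionic_strength must be >= 0", call. = FALSE)
  }
  A <- 0.509
  sq <- sqrt(ionic_strength)
  lg <- -A * charge^2 * (sq / (1 + sq) - 0.3 * ionic_strength)
  pmin(10^lg, 1.2)
}

# log10(gamma) vector for a charge vector at ionic strength I (hot path helper)
.log10_gamma <- function(z, I) {
  sq <- sqrt(I)
  lg <- -0.509 * z^2 * (sq / (1 + sq) - 0.3 * I)
  pmin(lg, log10(1.2))
}
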
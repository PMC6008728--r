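# Physical constants. Gyromagnetic ratios to 6 significant figures
# (CODATA-style values, rad s^-1 T^-1); the 15N ratio is negative but only
# the magnitude enters the ppm -> rad/s conversion.
.GAMMA <- c("1H" = 2.67522e8, "15N" = 2.71262e7)

#' Gas constant, J mol^-1 K^-1
#' @keywords internal
.RGAS <- 8.314

#' Convert a chemical-shift difference from ppm to rad/s
#'
#' \eqn{\delta\omega = \Delta\omega_{ppm} \times 10^{-6} |\gamma| B_0}.
#'
#' @param dwPpm shift difference in ppm.
#' @param nucleus "15N" or "1H".
#' @param fieldT static field in tesla.
#' @return angular frequency difference in rad/s.
#' @examples
#' ppmToRad(2, "15N", 11.7)
#' @export
ppmToRad <- function(dwPpm, nucleus, fieldT) {
    if (!nucleus %in% names(.GAMMA))
        stop("unknown nucleus: ", nucleus)
    dwPpm * 1e-6 * .GAMMA[[nucleus]] * fieldT
}

#' Thermal energy in kJ/mol
#'
#' \eqn{k_B T} expressed per mole, i.e. \eqn{RT} in kJ/mol; used wherever
#' energies are reported in multiples of \eqn{k_B T}.
#'
#' @param tempK temperature in kelvin.
#' @return RT in kJ/mol.
#' @examples
#' kBT(310.15)  # ~2.578 kJ/mol at 37 degC
#' @export
kBT <- function(tempK) .RGAS * tempK / 1000

#' Celsius to kelvin
#'
#' @param tempC temperature in degrees Celsius.
#' @return temperature in kelvin (tempC + 273.15, exactly).
#' @export
celsiusToKelvin <- function(tempC) tempC + 273.15
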
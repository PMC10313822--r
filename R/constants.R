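# CODATA 2018 values; mV/pA/pS/ms/mM unit system is fixed package-wide.
.GAS_R <- 8.314462618   # J mol^-1 K^-1
.FARADAY <- 96485.33212 # C mol^-1
.T_DEFAULT <- 298.15    # K (bilayer recordings at 25 degrees C)

#' Physical constants used by the electrodiffusion calculations
#'
#' Returns the gas constant, Faraday constant and the package default
#' temperature as a read-only list. All potentials in the package are derived
#' from these values; at 298.15 K the thermal voltage `RT/F` is 25.693 mV.
#'
#' @return A list with elements `gas_constant` (J mol^-1 K^-1), `faraday`
#'   (C mol^-1) and `default_temperature` (K).
#' @examples
#' const <- phys_constants()
#' 1000 * const$gas_constant * const$default_temperature / const$faraday
#' @export
phys_constants <- function() {
  list(
    gas_constant = .GAS_R,
    faraday = .FARADAY,
    default_temperature = .T_DEFAULT
  )
}

# Thermal voltage RT/F in mV at the given absolute temperature.
rt_over_f_mv <- function(temperature = .T_DEFAULT) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1000 * .GAS_R * temperature / .FARADAY
}
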
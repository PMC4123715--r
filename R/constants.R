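# Physical constants (SI). Charge z is in elementary-charge units and is
# interpreted per mole, i.e. it always multiplies the Faraday constant.
.R_GAS <- 8.314      # J/(mol K)
.FARADAY <- 96485    # C/mol
.T0_KELVIN <- 273.15

#' Convert Celsius to Kelvin
#'
#' @param temp_c Temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @keywords internal
kelvin <- function(temp_c) {
  if (any(!is.finite(temp_c)) || any(temp_c <= -.T0_KELVIN)) {
    stop("temperature must be finite and above absolute zero", call. = FALSE)
  }
  temp_c + .T0_KELVIN
}

# RT/F in mV at a given temperature (the thermal voltage)
rt_over_f_mv <- function(temp_c) 1000 * .R_GAS * kelvin(temp_c) / .FARADAY

check_finite <- function(..., .names = NULL) {
  vals <- list(...)
  nms <- if (is.null(.names)) {
    vapply(substitute(list(...))[-1], deparse, character(1))
  } else {
    .names
  }
  for (i in seq_along(vals)) {
    if (!all(is.finite(vals[[i]]))) {
      stop(sprintf("'%s' must be finite", nms[[i]]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
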
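# Reference channel parameterizations shipped as YAML configs under
# inst/extdata/presets/.  These are model realizations chosen to reproduce
# published apparent charges, midpoints and the bound-type temperature
# coefficients of the channel classes they are named after; they are not
# fits to any particular recording.

#' List shipped channel presets
#'
#' @return Character vector of preset names accepted by [channel_preset()].
#' @export
list_presets <- function() {
  dir <- system.file("extdata", "presets", package = "thermogate")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

#' Load a shipped channel parameterization
#'
#' Presets:
#' \describe{
#'   \item{trpv1_like}{A two-state, weakly voltage-dependent pore transition
#'     with a very large enthalpy and entropy change: heat-activated over a
#'     broad voltage range.}
#'   \item{shaker_like}{Strongly coupled allosteric model (large D): a steep
#'     voltage sensor obligatorily coupled to a heat-sensitive pore opening.}
#'   \item{ilt_like}{The same channel with coupling weakened (small D) and
#'     the sensor midpoint shifted depolarized: the pore transition is
#'     unmasked and strongly heat-activated.}
#'   \item{v2_like}{As ilt_like but with the pore transition enthalpy and
#'     entropy sign-flipped: heat now deactivates the channel.}
#'   \item{kv21_like, kv43_like}{Partially decoupled channels carrying a
#'     closed-state-inactivation availability curve.}
#' }
#'
#' @param name Preset name (see [list_presets()]).
#' @return The loaded model: an `allosteric_params` or `thermo_transition`,
#'   with attributes `channel_name` and (if configured) `csi` (a list with
#'   `v_half`, `q` in mV and e0).
#' @examples
#' m <- channel_preset("trpv1_like")
#' open_probability(m, v = 0, temp = c(30, 40, 50))
#' @export
channel_preset <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "thermogate")
  if (!nzchar(path)) {
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(list_presets(), collapse = ", ")), call. = FALSE)
  }
  load_channel_config(path)
}
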
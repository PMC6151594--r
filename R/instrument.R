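# Instrument response parameters for the simulator.

#' Default instrument parameters
#'
#' Per-channel sensitivities (counts per ug/L of element-equivalent
#' concentration), internal-standard sensitivities, background counts, and
#' the smooth acquisition drift model (a bounded multiplicative random walk
#' shared by analyte and internal-standard channels, so it cancels under
#' internal-standard normalization).
#'
#' Sensitivities are equal across the isotopes of one element; together with
#' the mole-resolved signal model this makes the 63Cu:65Cu response ratio an
#' atom ratio, i.e. the instrument is simulated without mass bias, matching
#' the quantitation model (which carries an identity mass-bias hook).
#'
#' @param channels analyte channel registry.
#' @param is_channels internal-standard registry.
#' @return list with elements `sensitivity` (data frame `element`, `mass`,
#'   `sens`), `is_sensitivity` (data frame `element`, `mass`, `sens`),
#'   `background` (mean background counts), `background_sd` (SD of additive
#'   background noise, counts), `baseline_cv` (relative noise of standards,
#'   QC and calibration blanks, which undergo no sample preparation),
#'   `drift_step` (log-scale SD of the per-solution drift step) and
#'   `drift_range` (clamp bounds of the drift multiplier).
#' @export
default_instrument_params <- function(channels = default_channels(),
                                      is_channels = internal_standard_channels()) {
  list(
    sensitivity = data.frame(element = channels$element,
                             mass = channels$mass,
                             sens = 1000,
                             stringsAsFactors = FALSE),
    is_sensitivity = data.frame(element = is_channels$element,
                                mass = is_channels$mass,
                                sens = 5000,
                                stringsAsFactors = FALSE),
    background = 5,
    background_sd = 1,
    baseline_cv = 0.01,
    drift_step = 0.01,
    drift_range = c(0.8, 1.2)
  )
}

#' Strip all stochastic and nuisance components from instrument parameters
#'
#' Sets background, background noise, baseline noise and drift to zero so
#' that simulated responses are an exact linear function of concentration.
#'
#' @param instrument instrument parameter list.
#' @return modified instrument parameter list.
#' @export
noise_free_instrument <- function(instrument = default_instrument_params()) {
  instrument$background <- 0
  instrument$background_sd <- 0
  instrument$baseline_cv <- 0
  instrument$drift_step <- 0
  instrument
}

#' Strip all stochastic effects from a method-effect structure
#'
#' Sets every method's noise CV and contamination to zero and retention to 1,
#' leaving only the deterministic dilution step, so that the
#' simulate-calibrate-quantify round trip is the identity on the truth table.
#'
#' @param effects effect structure.
#' @return modified effect structure.
#' @export
noise_free_effects <- function(effects = default_method_effects()) {
  lapply(effects, function(e) {
    e$cv <- 0
    e$contamination <- e$contamination[0, , drop = FALSE]
    e$contamination_cv <- 0
    e$retention <- e$retention[0, , drop = FALSE]
    e$matrix_factor <- 1
    e
  })
}
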
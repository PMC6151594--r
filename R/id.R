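# Isotope-dilution quantitation of copper from the 63Cu:65Cu response ratio.

#' Isotope-dilution parameters
#'
#' Bundles the constants of the two-source isotope-mixing equation for
#' copper: the spike solution concentration and the gravimetric masses, the
#' spike isotopic abundances, the natural abundances (0.6915 / 0.3085 for
#' 63Cu / 65Cu by default), and the atomic weights of natural and spike
#' copper (computed from the abundance vectors and exact isotope masses
#' unless supplied).
#'
#' @param c_spike concentration of the enriched-Cu spike solution (ug/L).
#' @param m_spike mass of spike solution added (g).
#' @param m_sample mass of the sample aliquot (g).
#' @param a63,a65 isotopic abundances of the spike (fractions summing to 1).
#' @param b63,b65 natural isotopic abundances (fractions summing to 1).
#' @param w_nat atomic weight of natural Cu (g/mol); computed from `b` if
#'   `NULL`.
#' @param w_spk atomic weight of Cu in the spike (g/mol); computed from `a`
#'   if `NULL`.
#' @return list of validated parameters.
#' @export
id_params <- function(c_spike, m_spike, m_sample, a63, a65,
                      b63 = 0.6915, b65 = 0.3085,
                      w_nat = NULL, w_spk = NULL) {
  if (abs(a63 + a65 - 1) > 1e-6) stop("spike abundances must sum to 1")
  if (abs(b63 + b65 - 1) > 1e-6) stop("natural abundances must sum to 1")
  if (any(c(a63, a65, b63, b65) <= 0) || any(c(a63, a65, b63, b65) >= 1)) {
    stop("abundances must lie strictly between 0 and 1")
  }
  if (any(c(c_spike, m_spike, m_sample) <= 0)) {
    stop("spike concentration and masses must be positive")
  }
  masses <- isotope_masses("Cu")
  if (is.null(w_nat)) {
    w_nat <- atomic_weight_from_abundance(c(`63` = b63, `65` = b65), masses)
  }
  if (is.null(w_spk)) {
    w_spk <- atomic_weight_from_abundance(c(`63` = a63, `65` = a65), masses)
  }
  list(c_spike = c_spike, m_spike = m_spike, m_sample = m_sample,
       a63 = a63, a65 = a65, b63 = b63, b65 = b65,
       w_nat = w_nat, w_spk = w_spk)
}

#' Isotope-dilution copper concentration
#'
#' Inverts the two-source isotope-mixing balance for the measured 63Cu:65Cu
#' instrument response ratio `R`:
#'
#' `conc = c_spike * (m_spike / m_sample) * (w_nat / w_spk) *
#'         (R * a65 - a63) / (b63 - R * b65)`
#'
#' which returns the natural-copper concentration of the original sample.
#' Because the spike and the sample analyte share every preparation step,
#' proportional analyte losses cancel in the ratio and the result is
#' self-correcting for (non-fractionating) loss. For a physically consistent
#' ratio - between the pure-spike ratio `a63/a65` and the natural ratio
#' `b63/b65` - the result is nonnegative and strictly increasing in `R`. A
#' ratio at the natural value is a singularity (the spike contribution
#' vanishes relative to the sample and the estimate diverges); ratios outside
#' the two-source interval are inconsistent with the mixing model and raise a
#' warning.
#'
#' @param R measured 63Cu:65Cu response ratio (> 0); may be a vector.
#' @param params parameter list from [id_params()].
#' @return natural-Cu concentration of the sample (ug/L), same length as `R`.
#' @examples
#' p <- id_params(c_spike = 10000, m_spike = 0.1, m_sample = 10,
#'                a63 = 0.01, a65 = 0.99)
#' isotope_dilution_cu(p$a63 / p$a65, p)  # 0: pure spike, no sample Cu
#' @export
isotope_dilution_cu <- function(R, params) {
  if (any(!is.finite(R)) || any(R <= 0)) {
    stop("response ratio must be positive and finite")
  }
  r_spike <- params$a63 / params$a65
  r_nat <- params$b63 / params$b65
  denom <- params$b63 - R * params$b65
  if (any(abs(denom) < 1e-12 * params$b63)) {
    stop("singular response ratio: sample indistinguishable from natural Cu")
  }
  lo <- min(r_spike, r_nat)
  hi <- max(r_spike, r_nat)
  if (any(R < lo | R > hi)) {
    warning("response ratio outside the two-source mixing interval [",
            signif(lo, 4), ", ", signif(hi, 4),
            "]; measurement inconsistent with spike + natural mixing")
  }
  params$c_spike * (params$m_spike / params$m_sample) *
    (params$w_nat / params$w_spk) *
    (R * params$a65 - params$a63) / denom
}

#' Isotope-dilution results for the spiked samples of a batch
#'
#' Computes the 63Cu:65Cu raw response ratio of every spiked solution and
#' inverts the isotope-mixing equation using the gravimetric masses recorded
#' with each aliquot. The ratio of two channels of the same element acquired
#' in the same solution cancels drift, common-mode noise, and any
#' proportional preparation loss.
#'
#' @param records raw measurement records containing `spiked_sample` rows
#'   with both Cu channels.
#' @param spikes spike parameters (spike solution concentration and
#'   abundances).
#' @param include_blanks also invert the spiked method blanks (their ratio
#'   sits at the pure-spike boundary, where small noise triggers the
#'   consistency warning); off by default.
#' @return data frame `wine`, `method`, `replicate`, `ratio`, `conc_id`
#'   (ug/L natural Cu in the original sample).
#' @export
id_table <- function(records, spikes = default_spike_params(),
                     include_blanks = FALSE) {
  spk <- records[records$role == "spiked_sample" & records$element == "Cu", ,
                 drop = FALSE]
  if (!include_blanks) spk <- spk[spk$wine != "BLANK", , drop = FALSE]
  if (nrow(spk) == 0) stop("no spiked Cu measurements in input")
  ab <- spikes$Cu$abundance
  keys <- unique(spk[, c("wine", "method", "replicate")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- spk$wine == k$wine & spk$method == k$method &
      spk$replicate == k$replicate
    r63 <- spk$response[sel & spk$mass == 63]
    r65 <- spk$response[sel & spk$mass == 65]
    if (length(r63) != 1 || length(r65) != 1) {
      stop("spiked solution missing a Cu channel")
    }
    p <- id_params(c_spike = spikes$Cu$conc,
                   m_spike = spk$spike_mass[sel][1],
                   m_sample = spk$mass_sample[sel][1],
                   a63 = ab[["63"]], a65 = ab[["65"]])
    data.frame(wine = k$wine, method = k$method, replicate = k$replicate,
               ratio = r63 / r65,
               conc_id = isotope_dilution_cu(r63 / r65, p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
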
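# Forward simulation of instrument responses for a full analytical batch.

# lognormal multiplier with unit mean: exp(z * sdlog - sdlog^2 / 2)
.ln_mult <- function(z, sdlog) exp(z * sdlog - sdlog^2 / 2)

.sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

#' Simulate instrument responses for a batch design
#'
#' Generates one raw measurement record per (solution, channel). The signal
#' model is mole-resolved: each solution's element content is split over the
#' element's isotopes (natural abundances for wine-derived analyte and
#' contamination; the enriched abundance vector for gravimetric spikes), and
#' the channel response is
#'
#' `response = sensitivity x signal x matrix x drift x noise + background`
#'
#' where `signal` is the element-equivalent concentration at the monitored
#' mass, `drift` is a bounded multiplicative random walk shared with the
#' internal-standard channels (so it cancels under normalization), and
#' `noise` is a unit-mean lognormal multiplier whose log-variance is split
#' between a common-mode per-solution component and a channel-specific
#' component. Method blanks, samples and spiked samples receive their
#' preparation method's noise CV, per-replicate contamination draw and
#' filtration retention; standards, QC solutions and calibration blanks see
#' only the instrument baseline CV. Additive Gaussian background noise (in
#' counts) gives calibration blanks a nonzero spread, which is what the
#' blank-based detection limits measure.
#'
#' @param design batch design from [batch_design()].
#' @param truth truth table from [generate_truth()].
#' @param effects per-method effect structure, as from
#'   [default_method_effects()].
#' @param instrument instrument parameters, as from
#'   [default_instrument_params()].
#' @param channels analyte channel registry with internal-standard
#'   assignment, as from [assign_internal_standard()].
#' @param spikes spike parameters, as from [default_spike_params()].
#' @param seed integer seed; mandatory (reproducibility contract).
#' @return data frame of measurement records: the design columns plus
#'   `element`, `mass`, `mode`, `is_element`, `is_mass`, `response`,
#'   `is_response`.
#' @export
simulate_batch <- function(design, truth, effects,
                           instrument = default_instrument_params(),
                           channels = assign_internal_standard(),
                           spikes = default_spike_params(),
                           seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required to simulate a batch")
  }
  if (is.null(channels$is_element)) {
    channels <- assign_internal_standard(channels)
  }
  set.seed(seed)
  n_sol <- nrow(design)
  n_ch <- nrow(channels)

  key <- paste(channels$element, channels$mass)
  sens <- instrument$sensitivity$sens[
    match(key, paste(instrument$sensitivity$element,
                     instrument$sensitivity$mass))]
  is_key <- paste(channels$is_element, channels$is_mass)
  is_sens <- instrument$is_sensitivity$sens[
    match(is_key, paste(instrument$is_sensitivity$element,
                        instrument$is_sensitivity$mass))]
  if (any(is.na(sens)) || any(is.na(is_sens))) {
    stop("instrument sensitivities missing for some channels")
  }

  # per-channel natural mole fraction at the monitored mass, and the
  # enriched-spike conversion factor (element-equivalent per ug/L of spike
  # material)
  f_nat <- numeric(n_ch)
  w_nat <- numeric(n_ch)
  spk_factor <- numeric(n_ch)
  for (i in seq_len(n_ch)) {
    e <- channels$element[i]
    m <- as.character(channels$mass[i])
    ab <- natural_abundance(e, channels$mass[i])
    f_nat[i] <- if (m %in% names(ab)) ab[[m]] else 0
    w_nat[i] <- atomic_weight(e, channels$mass[i])
    sp <- spikes[[e]]
    if (!is.null(sp) && m %in% names(sp$abundance)) {
      w_spk <- atomic_weight_from_abundance(sp$abundance, isotope_masses(e))
      spk_factor[i] <- (w_nat[i] / w_spk) * sp$abundance[[m]]
    }
  }

  # acquisition drift: bounded multiplicative random walk
  steps <- stats::rnorm(n_sol, 0, instrument$drift_step)
  drift <- numeric(n_sol)
  d <- 1
  for (i in seq_len(n_sol)) {
    d <- d * exp(steps[i])
    d <- min(max(d, instrument$drift_range[1]), instrument$drift_range[2])
    drift[i] <- d
  }

  prep_roles <- c("method_blank", "sample", "spiked_sample")
  records <- vector("list", n_sol)
  for (i in seq_len(n_sol)) {
    row <- design[i, , drop = FALSE]
    is_prep <- row$role %in% prep_roles
    effect <- if (is_prep) effects[[row$method]] else NULL
    if (is_prep && is.null(effect)) {
      stop("no effect parameters for method ", row$method)
    }
    dfac <- if (is_prep) dilution_factor(row$method) else 1

    ret <- if (is_prep) retention_vector(effect, channels) else rep(1, n_ch)
    contam_mean <- if (is_prep) contamination_vector(effect, channels) else
      numeric(n_ch)

    c_nat_elem <- stats::setNames(numeric(0), character(0))
    c_spk <- stats::setNames(numeric(0), character(0))
    if (row$role %in% c("calibration_standard", "qc_standard")) {
      c_nat_elem <- stats::setNames(rep(row$nominal, n_ch), channels$element)
    } else if (row$role == "spike_calibration_standard") {
      c_spk <- stats::setNames(
        rep(row$nominal, length(spikes)), names(spikes))
    } else if (row$role == "sample") {
      tw <- truth[truth$wine == row$wine, , drop = FALSE]
      c_nat_elem <- stats::setNames(tw$truth / dfac, tw$element)
    } else if (row$role == "spiked_sample") {
      basis <- row$mass_sample / (row$mass_sample + row$spike_mass)
      if (row$wine != "BLANK") {
        tw <- truth[truth$wine == row$wine, , drop = FALSE]
        c_nat_elem <- stats::setNames(tw$truth * basis / dfac, tw$element)
      }
      spike_basis <- row$spike_mass / (row$mass_sample + row$spike_mass)
      c_spk <- stats::setNames(
        vapply(spikes, function(s) s$conc, numeric(1)) * spike_basis / dfac,
        names(spikes))
    }

    c_nat_ch <- c_nat_elem[channels$element]
    c_nat_ch[is.na(c_nat_ch)] <- 0
    c_spk_ch <- c_spk[channels$element]
    c_spk_ch[is.na(c_spk_ch)] <- 0

    # per-replicate contamination draw (reagent variability)
    z_con <- stats::rnorm(n_ch)
    sd_con <- .sdlog_from_cv(if (is_prep) effect$contamination_cv else 0)
    contam <- contam_mean * .ln_mult(z_con, sd_con)

    signal <- unname(c_nat_ch) * f_nat * ret +
      unname(c_spk_ch) * spk_factor + contam

    cv <- if (is_prep) effect$cv else instrument$baseline_cv
    share <- if (is_prep) effect$cv_common_share else 0
    sd_tot <- .sdlog_from_cv(cv)
    sd_common <- sd_tot * sqrt(share)
    sd_chan <- sd_tot * sqrt(1 - share)
    z_common <- stats::rnorm(1)
    z_chan <- stats::rnorm(n_ch)
    noise <- .ln_mult(z_common, sd_common) * .ln_mult(z_chan, sd_chan)

    mfac <- if (is_prep) effect$matrix_factor else 1
    bg <- instrument$background +
      stats::rnorm(n_ch, 0, instrument$background_sd)
    response <- pmax(sens * signal * mfac * drift[i] * noise + bg, 0)
    is_response <- is_sens * drift[i]

    rec <- row[rep(1L, n_ch), , drop = FALSE]
    rec$element <- channels$element
    rec$mass <- channels$mass
    rec$mode <- channels$mode
    rec$is_element <- channels$is_element
    rec$is_mass <- channels$is_mass
    rec$response <- response
    rec$is_response <- is_response
    records[[i]] <- rec
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Simulate quantified concentrations directly
#'
#' Concentration-level shortcut for Monte Carlo calibration studies: applies
#' the preparation effect model and replicate noise to the truth table and
#' returns what an exact calibration layer would report (dilution-corrected
#' concentrations), bypassing response synthesis and curve fitting. The
#' instrument/calibration layer itself is exact under the round-trip
#' identity, so statistical properties of the method-comparison tests can be
#' studied on this model at a fraction of the cost.
#'
#' @param truth truth table.
#' @param effects per-method effect structure.
#' @param methods preparation methods.
#' @param replicates replicates per (wine, method).
#' @param seed integer seed; mandatory.
#' @param channels analyte channel registry.
#' @param include_blanks also emit triplicate method blanks (wine `"BLANK"`).
#' @return long data frame `wine`, `method`, `replicate`, `element`, `mass`,
#'   `conc` (ug/L, reported scale).
#' @export
simulate_concentrations <- function(truth, effects,
                                    methods = prep_methods(),
                                    replicates = 3, seed,
                                    channels = default_channels(),
                                    include_blanks = FALSE) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  set.seed(seed)
  wines <- unique(truth$wine)
  n_ch <- nrow(channels)
  out <- list()
  for (m in methods) {
    effect <- effects[[m]]
    if (is.null(effect)) stop("no effect parameters for method ", m)
    dfac <- dilution_factor(m)
    ret <- retention_vector(effect, channels)
    contam_mean <- contamination_vector(effect, channels)
    sd_tot <- .sdlog_from_cv(effect$cv)
    sd_con <- .sdlog_from_cv(effect$contamination_cv)
    sources <- if (include_blanks) c(wines, "BLANK") else wines
    for (w in sources) {
      if (w == "BLANK") {
        base <- numeric(n_ch)
      } else {
        tw <- truth[truth$wine == w, , drop = FALSE]
        elem_truth <- stats::setNames(tw$truth, tw$element)
        base <- elem_truth[channels$element]
        base[is.na(base)] <- 0
        base <- unname(base) * ret
      }
      for (r in seq_len(replicates)) {
        contam <- contam_mean * .ln_mult(stats::rnorm(n_ch), sd_con)
        noise <- .ln_mult(stats::rnorm(n_ch), sd_tot)
        conc <- (base + contam * dfac) * noise
        out[[length(out) + 1L]] <- data.frame(
          wine = w, method = m, replicate = r,
          element = channels$element, mass = channels$mass, conc = conc,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
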
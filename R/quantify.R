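# Quantitation: internal-standard normalization, external calibration,
# detection limits, censoring, QC, spike recovery, isotope dilution.

#' Internal-standard normalization
#'
#' Divides the raw channel response by the simultaneously acquired response
#' of the assigned internal-standard channel, cancelling sample-transport
#' and plasma drift common to both.
#'
#' @param response raw counts (>= 0).
#' @param is_response internal-standard counts (> 0).
#' @return normalized response (dimensionless).
#' @examples
#' normalize_response(1000, 100)  # 10
#' @export
normalize_response <- function(response, is_response) {
  if (any(!is.finite(is_response)) || any(is_response <= 0)) {
    stop("instrument fault: non-positive internal-standard response")
  }
  response / is_response
}

#' Fit external calibration curves
#'
#' Ordinary (unweighted) least-squares line of internal-standard-normalized
#' response against the gravimetric standard concentration, fitted per
#' channel, per matrix group, and per calibration material (natural-abundance
#' multi-element standards and the separate enriched-isotope series).
#'
#' @param records measurement records containing calibration rows (roles
#'   `calibration_standard` and/or `spike_calibration_standard` with a
#'   `nominal` column).
#' @return data frame of curves: `method` (matrix group), `material`,
#'   `element`, `mass`, `slope`, `intercept`, `r_squared`, `n_levels`.
#' @export
fit_calibration <- function(records) {
  std <- records[records$role %in%
                   c("calibration_standard", "spike_calibration_standard"), ,
                 drop = FALSE]
  if (nrow(std) == 0) stop("no calibration standards in input")
  std$y <- normalize_response(std$response, std$is_response)
  keys <- unique(std[, c("method", "material", "element", "mass")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- std$method == k$method & std$material == k$material &
      std$element == k$element & std$mass == k$mass
    x <- std$nominal[sel]
    y <- std$y[sel]
    if (length(unique(x)) < 2) {
      stop("degenerate calibration design: all levels identical for ",
           k$element, k$mass)
    }
    fit <- stats::lm(y ~ x)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
    data.frame(method = k$method, material = k$material,
               element = k$element, mass = k$mass,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2, n_levels = length(unique(x)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.curve_lookup <- function(curves, group, material, element, mass) {
  sel <- curves$method == group & curves$material == material &
    curves$element == element & curves$mass == mass
  if (!any(sel)) return(NULL)
  curves[which(sel)[1L], ]
}

#' Quantify records against external calibration curves
#'
#' Converts normalized responses to concentrations via the matching curve
#' (matrix group and natural material), then scales to the original-sample
#' basis: prepared solutions (samples, spiked samples, method blanks) are
#' multiplied by the method's dilution factor, and spiked aliquots
#' additionally by `(mass_sample + spike_mass) / mass_sample` so that the
#' wine-derived analyte is reported on the same undiluted-wine scale as the
#' unspiked samples. Standards, QC solutions and calibration blanks are
#' reported at solution scale. Negative instrument-side values pass through
#' unchanged; they are handled later by censoring. A mass-bias correction
#' hook exists but defaults to the identity.
#'
#' @param records measurement records (any roles).
#' @param curves curve table from [fit_calibration()].
#' @param material calibration material to quantify against.
#' @param mass_bias per-channel multiplicative correction of the normalized
#'   response; default 1 (no correction).
#' @return `records` with added columns `conc_solution` (ug/L in the measured
#'   solution) and `conc` (ug/L on the reported, dilution-corrected scale).
#' @export
quantify_external <- function(records, curves, material = "natural",
                              mass_bias = 1) {
  unk <- records
  unk$y <- normalize_response(unk$response, unk$is_response) * mass_bias
  group <- matrix_group(unk$method)
  key <- paste(group, material, unk$element, unk$mass)
  ckey <- paste(curves$method, curves$material, curves$element, curves$mass)
  idx <- match(key, ckey)
  if (any(is.na(idx))) {
    stop("no calibration curve for some channels (material '", material, "')")
  }
  slope <- curves$slope[idx]
  if (any(slope <= 0)) stop("unusable calibration curve: slope <= 0")
  unk$conc_solution <- (unk$y - curves$intercept[idx]) / slope
  prep <- unk$role %in% c("method_blank", "sample", "spiked_sample")
  scale <- rep(1, nrow(unk))
  scale[prep] <- dilution_factor(unk$method[prep])
  spiked <- unk$role == "spiked_sample"
  scale[spiked] <- scale[spiked] *
    (unk$mass_sample[spiked] + unk$spike_mass[spiked]) /
    unk$mass_sample[spiked]
  unk$conc <- unk$conc_solution * scale
  unk$y <- NULL
  unk
}

#' Detection-limit t multiplier
#'
#' Student-t upper-tail quantile used in the blank-SD detection-limit
#' formula, at `n - 1` degrees of freedom. The default confidence level of
#' 0.99 (one-tailed) reproduces the conventional multipliers 3.365 for six
#' and 2.998 for eight blank measurements.
#'
#' @param n_blanks number of blank measurements (>= 2).
#' @param conf one-tailed confidence level.
#' @return the t multiplier.
#' @examples
#' t_critical(6)  # 3.365
#' t_critical(8)  # 2.998
#' @export
t_critical <- function(n_blanks, conf = 0.99) {
  if (any(n_blanks < 2)) stop("at least two blank measurements are required")
  stats::qt(conf, df = n_blanks - 1)
}

#' Detection and quantitation limits from blank measurements
#'
#' `lod = t_critical(n) x SD(blanks)`; `loq = 10 x SD(blanks)` (sample
#' standard deviation). With the default t convention, `lod / loq = t / 10`
#' exactly, so `loq >= lod` whenever `t <= 10`.
#'
#' @param blanks numeric vector of blank concentrations for one channel.
#' @param conf one-tailed confidence level for the t multiplier.
#' @return list with `lod`, `loq`, `sd`, `n_blanks`, `t_value`.
#' @examples
#' compute_lod_loq(c(0, 1, 2, 3, 4, 5))  # lod 6.295, loq 18.708
#' @export
compute_lod_loq <- function(blanks, conf = 0.99) {
  n <- length(blanks)
  if (n < 2) stop("at least two blank measurements are required")
  s <- stats::sd(blanks)
  t <- t_critical(n, conf)
  list(lod = t * s, loq = 10 * s, sd = s, n_blanks = n, t_value = t)
}

#' Per-channel detection limits from continuing calibration blanks
#'
#' Computes LOD/LOQ per channel and matrix group from the quantified
#' continuing-calibration-blank concentrations: one LOD per analytical run
#' from that run's blank SD, then averaged across the group's runs (the
#' direct-method limits are the mean of two runs by default).
#'
#' @param quant quantified records (from [quantify_external()]) containing
#'   `continuing_calibration_blank` rows.
#' @param conf one-tailed confidence level.
#' @return data frame `method` (matrix group), `element`, `mass`, `n_blanks`
#'   (per run), `n_runs`, `t_value`, `lod`, `loq`.
#' @export
detection_limits <- function(quant, conf = 0.99) {
  ccb <- quant[quant$role == "continuing_calibration_blank", , drop = FALSE]
  if (nrow(ccb) == 0) stop("no continuing calibration blanks in input")
  keys <- unique(ccb[, c("method", "element", "mass")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- ccb$method == k$method & ccb$element == k$element &
      ccb$mass == k$mass
    runs <- sort(unique(ccb$run[sel]))
    per_run <- lapply(runs, function(r) {
      compute_lod_loq(ccb$conc[sel & ccb$run == r], conf)
    })
    data.frame(method = k$method, element = k$element, mass = k$mass,
               n_blanks = per_run[[1]]$n_blanks, n_runs = length(runs),
               t_value = per_run[[1]]$t_value,
               lod = mean(vapply(per_run, `[[`, numeric(1), "lod")),
               loq = mean(vapply(per_run, `[[`, numeric(1), "loq")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Left-censor concentrations below the detection limit
#'
#' Replaces every concentration below its detection limit with one-half the
#' detection limit and flags it, so downstream statistics operate on a
#' complete table. The flag guards idempotence: an already-censored value
#' (lod/2, which is itself below the lod) is never re-censored.
#'
#' @param results data frame with columns `conc` and `lod` (and optionally a
#'   logical `censored` from a previous pass).
#' @return `results` with `conc` substituted where censored and a logical
#'   `censored` column.
#' @export
censor_below_lod <- function(results) {
  if (is.null(results$lod) || any(is.na(results$lod))) {
    stop("missing detection limit (lod column) for censoring")
  }
  if (is.null(results$censored)) results$censored <- FALSE
  hit <- !results$censored & results$conc < results$lod
  results$conc[hit] <- results$lod[hit] / 2
  results$censored[hit] <- TRUE
  results
}

#' Quality-control check of repeated QC standard measurements
#'
#' The QC standard passes for a channel when its mean is accurate within
#' `accuracy_tol` of the nominal concentration and precise with a relative
#' standard deviation below `rsd_tol`.
#'
#' @param values numeric vector of quantified QC concentrations (>= 2).
#' @param nominal nominal QC concentration (ug/L).
#' @param accuracy_tol allowed relative bias (fraction).
#' @param rsd_tol allowed RSD (percent).
#' @return list with `mean`, `bias` (fraction), `rsd` (percent), `pass`.
#' @examples
#' qc_check(c(10, 10, 10))$pass   # TRUE
#' qc_check(c(8, 12))$pass        # FALSE (RSD 28.3%)
#' @export
qc_check <- function(values, nominal = 10, accuracy_tol = 0.20,
                     rsd_tol = 20) {
  if (length(values) < 2) stop("at least two QC replicates are required")
  m <- mean(values)
  bias <- abs(m - nominal) / nominal
  r <- rsd(values)
  list(mean = m, bias = bias, rsd = r,
       pass = bias <= accuracy_tol && r <= rsd_tol)
}

#' QC summary per channel
#'
#' @param quant quantified records containing `qc_standard` rows.
#' @param nominal nominal QC concentration.
#' @inheritParams qc_check
#' @return data frame `method`, `element`, `mass`, `mean`, `bias`, `rsd`,
#'   `pass`.
#' @export
qc_table <- function(quant, nominal = 10, accuracy_tol = 0.20, rsd_tol = 20) {
  qc <- quant[quant$role == "qc_standard", , drop = FALSE]
  if (nrow(qc) == 0) stop("no QC standards in input")
  keys <- unique(qc[, c("method", "element", "mass")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sel <- qc$method == k$method & qc$element == k$element &
      qc$mass == k$mass
    chk <- qc_check(qc$conc[sel], nominal, accuracy_tol, rsd_tol)
    data.frame(method = k$method, element = k$element, mass = k$mass,
               mean = chk$mean, bias = chk$bias, rsd = chk$rsd,
               pass = chk$pass, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Percent spike recovery
#'
#' The difference between the concentration measured in the spiked sample
#' and the mean concentration of the unspiked sample, divided by the spike
#' level, expressed as a percentage.
#'
#' @param spiked concentration in the spiked sample.
#' @param unspiked_mean mean unspiked concentration.
#' @param level spike level (> 0), same units.
#' @return recovery in percent.
#' @examples
#' spike_recovery(105, 5, 100)  # 100
#' @export
spike_recovery <- function(spiked, unspiked_mean, level) {
  if (any(level <= 0)) stop("spike level must be positive")
  100 * (spiked - unspiked_mean) / level
}

#' Spike-recovery table for the enriched-isotope spike channels
#'
#' Quantifies the spiked and unspiked solutions of each (wine, method) group
#' on the enriched-material calibration curve of the spike channel (65Cu,
#' 206Pb), then computes per-replicate recoveries against the group's mean
#' unspiked concentration. Using the enriched curve makes the natural
#' contribution cancel exactly in the difference, so a lossless preparation
#' recovers 100%.
#'
#' @param records raw measurement records (spiked and unspiked).
#' @param curves curve table from [fit_calibration()].
#' @param spikes spike parameters (for the per-element spike level).
#' @param recovery_channels data frame `element`, `mass` of the spike
#'   channels.
#' @return data frame `wine`, `method`, `replicate`, `element`, `mass`,
#'   `level`, `recovery_pct`.
#' @export
recovery_table <- function(records, curves, spikes = default_spike_params(),
                           recovery_channels = data.frame(
                             element = c("Cu", "Pb"), mass = c(65L, 206L))) {
  rec_rows <- records[records$element %in% recovery_channels$element &
                        paste(records$element, records$mass) %in%
                        paste(recovery_channels$element,
                              recovery_channels$mass) &
                        records$role %in% c("sample", "spiked_sample",
                                            "method_blank"), , drop = FALSE]
  if (nrow(rec_rows) == 0) stop("no recovery channels in input")
  q <- quantify_external(rec_rows, curves, material = "enriched")
  out <- list()
  spiked <- q[q$role == "spiked_sample", , drop = FALSE]
  for (i in seq_len(nrow(spiked))) {
    row <- spiked[i, ]
    unsp_role <- if (row$wine == "BLANK") "method_blank" else "sample"
    base <- q$conc[q$role == unsp_role & q$wine == row$wine &
                     q$method == row$method & q$element == row$element &
                     q$mass == row$mass]
    if (length(base) == 0) next
    level <- spikes[[row$element]]$conc * row$spike_mass / row$mass_sample
    out[[length(out) + 1L]] <- data.frame(
      wine = row$wine, method = row$method, replicate = row$replicate,
      element = row$element, mass = row$mass, level = level,
      recovery_pct = spike_recovery(row$conc, mean(base), level),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Relative standard deviation
#'
#' @param values numeric vector (>= 2 values, nonzero mean).
#' @return RSD in percent (sample SD over mean).
#' @examples
#' rsd(c(8, 12))  # 28.28
#' @export
rsd <- function(values) {
  if (length(values) < 2) stop("at least two values are required")
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean")
  100 * stats::sd(values) / m
}
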
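# Stage drivers tying simulation, quantitation and comparison into the full
# workflow, with CSV interchange and manifests.

.write_stage_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

.stage_log <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
}

#' Simulate a batch and write the canonical long-format CSV
#'
#' Generates the truth table and the full measurement batch from the
#' configuration and writes one CSV row per (solution, channel), plus a JSON
#' manifest carrying the seed, the configuration hash, record counts, the
#' file checksum and the truth table (for downstream round-trip
#' cross-checks). Rerunning with the same configuration produces a
#' byte-identical file.
#'
#' @param config run configuration with a seed.
#' @param out_csv output CSV path.
#' @param manifest_path manifest path; default `<out_csv>.manifest.json`.
#' @param verbose log record counts at the stage boundary.
#' @return invisibly, a list with `records`, `truth`, `design`, `manifest`.
#' @export
run_simulate <- function(config, out_csv,
                         manifest_path = paste0(out_csv, ".manifest.json"),
                         verbose = TRUE) {
  validate_config(config, require_seed = TRUE)
  truth <- generate_truth(config$seed, config$wines, config$truth_ranges)
  design <- batch_design(
    wines = config$wines, methods = config$methods,
    replicates = config$replicates, cal_levels = config$cal_levels,
    qc_every = config$qc_every, qc_nominal = config$qc_nominal,
    n_ccb = config$n_ccb, n_runs = config$n_runs,
    mass_sample = config$mass_sample, spike_mass = config$spike_mass)
  records <- simulate_batch(design, truth, config$effects,
                            instrument = config$instrument,
                            channels = config$channels,
                            spikes = config$spikes,
                            seed = config$seed + 1L)
  utils::write.csv(records, out_csv, row.names = FALSE)
  manifest <- list(stage = "simulate", seed = config$seed,
                   config_hash = config_hash(config),
                   n_solutions = nrow(design), n_records = nrow(records),
                   csv_md5 = unname(tools::md5sum(out_csv)),
                   truth = truth)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .stage_log(verbose, "simulate: %d solutions -> %d records -> %s",
             nrow(design), nrow(records), out_csv)
  invisible(list(records = records, truth = truth, design = design,
                 manifest = manifest))
}

#' Quantify a batch: calibration, detection limits, censoring, QC, recovery
#' and isotope dilution
#'
#' Runs the full quantitation workflow on a simulated (or imported) batch:
#' fits the external calibration curves per matrix group and material,
#' derives blank-based detection limits per run, quantifies all unknowns
#' with dilution correction, censors prepared-sample concentrations at half
#' the (sample-scale) detection limit, checks the QC standards, and computes
#' spike recoveries and isotope-dilution copper concentrations for the
#' spiked aliquots.
#'
#' @param batch measurement records data frame, or path to the batch CSV.
#' @param config run configuration.
#' @param out_dir optional directory for the stage's CSV exports.
#' @param strict stop (instead of flagging) when a QC channel fails.
#' @param verbose log record counts at the stage boundary.
#' @return list with `quant` (censored prepared-sample concentrations),
#'   `curves`, `lod` (detection-limit table), `qc`, `recovery`, `id`,
#'   `qc_failed` (logical).
#' @export
run_quantify <- function(batch, config = default_config(), out_dir = NULL,
                         strict = FALSE, verbose = TRUE) {
  records <- if (is.character(batch)) utils::read.csv(batch) else batch
  if (!any(records$role == "calibration_standard")) {
    stop("batch carries no calibration series")
  }
  if (!any(records$role == "continuing_calibration_blank")) {
    stop("batch carries no calibration blanks; detection limits undefined")
  }
  have_levels <- sort(unique(
    records$nominal[records$role == "calibration_standard"]))
  missing_levels <- setdiff(config$cal_levels, have_levels)
  if (length(missing_levels) > 0) {
    stop("missing calibration level(s): ",
         paste(missing_levels, collapse = ", "))
  }
  curves <- fit_calibration(records)
  quant_all <- quantify_external(records, curves)
  lod <- detection_limits(quant_all, conf = config$lod_conf)

  prep <- quant_all[quant_all$role %in%
                      c("sample", "spiked_sample", "method_blank"), ,
                    drop = FALSE]
  lkey <- paste(matrix_group(prep$method), prep$element, prep$mass)
  lidx <- match(lkey, paste(lod$method, lod$element, lod$mass))
  prep$lod <- lod$lod[lidx] * dilution_factor(prep$method)
  prep$loq <- lod$loq[lidx] * dilution_factor(prep$method)
  quant <- censor_below_lod(prep)

  qc <- qc_table(quant_all, nominal = config$qc_nominal)
  qc_failed <- any(!qc$pass)
  if (qc_failed && strict) {
    stop("QC failure: ", sum(!qc$pass), " channel(s) outside tolerance")
  }
  recovery <- recovery_table(records, curves, config$spikes)
  id <- id_table(records, config$spikes)

  out <- list(quant = quant, curves = curves, lod = lod, qc = qc,
              recovery = recovery, id = id, qc_failed = qc_failed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_stage_csv(quant, out_dir, "quantified.csv")
    .write_stage_csv(curves, out_dir, "calibration_curves.csv")
    .write_stage_csv(lod, out_dir, "detection_limits.csv")
    .write_stage_csv(qc, out_dir, "qc_report.csv")
    .write_stage_csv(recovery, out_dir, "spike_recovery.csv")
    .write_stage_csv(id, out_dir, "isotope_dilution.csv")
    manifest <- list(stage = "quantify", config_hash = config_hash(config),
                     n_records_in = nrow(records), n_quantified = nrow(quant),
                     qc_failed = qc_failed)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  .stage_log(verbose,
             "quantify: %d records -> %d quantified (%d censored), QC %s",
             nrow(records), nrow(quant), sum(quant$censored),
             if (qc_failed) "FAILED" else "passed")
  out
}

#' MANOVA gate on principal-component scores
#'
#' With more channels than residual degrees of freedom the full multivariate
#' test is singular, so the pipeline's default gate standardizes the
#' replicate-level channel matrix, projects onto its leading principal
#' components (enough to cover `var_target` of the variance, capped below
#' the residual degrees of freedom), and runs the Pillai-trace method test
#' on the scores.
#'
#' @param df long concentration table (wines only).
#' @param var_target variance fraction the retained components must cover.
#' @return list as from [manova_method_effect()], plus `k` (components
#'   used).
#' @export
manova_pc_gate <- function(df, var_target = 0.95) {
  .check_long(df)
  df <- df[df$wine != "BLANK", , drop = FALSE]
  key <- paste0(df$element, df$mass)
  obs <- paste(df$wine, df$method, df$replicate, sep = "|")
  wide <- stats::reshape(
    data.frame(obs = obs, key = key, conc = df$conc,
               stringsAsFactors = FALSE),
    idvar = "obs", timevar = "key", direction = "wide")
  x <- as.matrix(wide[, -1, drop = FALSE])
  x <- x[, apply(x, 2, stats::sd) > 0, drop = FALSE]
  parts <- strsplit(wide$obs, "|", fixed = TRUE)
  sample_f <- factor(vapply(parts, `[[`, character(1), 1))
  method_f <- factor(vapply(parts, `[[`, character(1), 2))
  rep_f <- factor(vapply(parts, `[[`, character(1), 3))
  df_resid <- nrow(x) - (nlevels(sample_f) + nlevels(method_f) +
                           nlevels(rep_f) - 2)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  varfrac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- min(which(varfrac >= var_target)[1], df_resid - 1,
           ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  fit <- stats::manova(scores ~ sample_f + rep_f + method_f)
  st <- summary(fit, test = "Pillai")$stats
  row <- st["method_f", ]
  list(statistic = unname(row["Pillai"]),
       approx_f = unname(row["approx F"]),
       df = unname(c(row["num Df"], row["den Df"])),
       p_value = unname(row["Pr(>F)"]),
       k = k)
}

#' Compare preparation methods on a quantified batch
#'
#' Runs the statistical stage: blank-compromise exclusion (method blanks as
#' an extra sample level), the MANOVA gate on principal-component scores,
#' per-isotope main-effects ANOVA with Tukey letter displays of the method
#' means, correlation-matrix PCA of the sample-mean profiles of retained
#' channels, and the per-method replicate-RSD summary. Deterministic given
#' its input.
#'
#' @param quant censored prepared-sample concentrations (from
#'   [run_quantify()]'s `quant`), or a path to the exported CSV.
#' @param config run configuration.
#' @param out_dir optional directory for the stage's CSV exports.
#' @param verbose log counts at the stage boundary.
#' @return list with `manova`, `anova`, `letters`, `exclusions`, `pca`,
#'   `rsd`, `profile`, `n_method_significant`.
#' @export
run_compare <- function(quant, config = default_config(), out_dir = NULL,
                        verbose = TRUE) {
  if (is.character(quant)) quant <- utils::read.csv(quant)
  long <- quant[quant$role %in% c("sample", "method_blank"),
                c("wine", "method", "replicate", "element", "mass", "conc",
                  "censored")]
  wines_long <- long[long$wine != "BLANK", , drop = FALSE]
  if (nrow(wines_long) == 0) stop("no quantified wine samples in input")

  exclusions <- blank_compromise_filter(long, alpha = config$alpha)
  anova <- anova_per_isotope(wines_long)
  letters <- tukey_method_table(wines_long, alpha = config$alpha)
  manova <- manova_pc_gate(wines_long)

  keep <- exclusions[!exclusions$excluded, c("element", "mass")]
  retained <- wines_long[paste(wines_long$element, wines_long$mass) %in%
                           paste(keep$element, keep$mass), , drop = FALSE]
  pm <- profile_matrix(retained)
  pca <- withCallingHandlers(
    pca_profiles(pm),
    warning = function(w) invokeRestart("muffleWarning"))
  rsd_summary <- summarize_rsd(wines_long)

  method_p <- anova[anova$effect == "method" & !anova$degenerate, ]
  n_sig <- sum(method_p$p_value <= config$alpha, na.rm = TRUE)

  out <- list(manova = manova, anova = anova, letters = letters,
              exclusions = exclusions, pca = pca, rsd = rsd_summary,
              profile = pm, n_method_significant = n_sig)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_stage_csv(anova, out_dir, "anova_per_isotope.csv")
    .write_stage_csv(letters, out_dir, "tukey_letters.csv")
    .write_stage_csv(exclusions, out_dir, "exclusions.csv")
    scores <- data.frame(sample = rownames(pca$scores), pca$scores,
                         stringsAsFactors = FALSE)
    .write_stage_csv(scores, out_dir, "pca_scores.csv")
    loads <- data.frame(channel = rownames(pca$loadings), pca$loadings,
                        stringsAsFactors = FALSE)
    .write_stage_csv(loads, out_dir, "pca_loadings.csv")
    .write_stage_csv(data.frame(component = seq_along(pca$variance_fraction),
                                variance_fraction = pca$variance_fraction),
                     out_dir, "pca_variance.csv")
    .write_stage_csv(rsd_summary, out_dir, "rsd_summary.csv")
    manova_df <- data.frame(statistic = manova$statistic,
                            approx_f = manova$approx_f,
                            num_df = manova$df[1], den_df = manova$df[2],
                            p_value = manova$p_value, k = manova$k)
    .write_stage_csv(manova_df, out_dir, "manova.csv")
    manifest <- list(stage = "compare", config_hash = config_hash(config),
                     n_observations = nrow(wines_long),
                     n_channels = nrow(unique(wines_long[, c("element",
                                                             "mass")])),
                     n_excluded = sum(exclusions$excluded),
                     n_method_significant = n_sig)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  .stage_log(verbose,
             "compare: %d observations, %d channels excluded, %d with a significant method effect",
             nrow(wines_long), sum(exclusions$excluded), n_sig)
  out
}

#' Scatter the first principal-component dimensions of a profile PCA
#'
#' Minimal base-graphics biplot: sample scores labelled by row name, with
#' the variance fraction of each displayed dimension in the axis label.
#'
#' @param pca result of [pca_profiles()].
#' @param dims two component indices.
#' @export
plot_pca_scores <- function(pca, dims = c(1, 2)) {
  s <- pca$scores[, dims, drop = FALSE]
  vf <- pca$variance_fraction[dims] * 100
  plot(s, type = "n",
       xlab = sprintf("PC%d (%.1f%%)", dims[1], vf[1]),
       ylab = sprintf("PC%d (%.1f%%)", dims[2], vf[2]))
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::text(s, labels = rownames(s), cex = 0.7)
  invisible(NULL)
}
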
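# Batch design: the ordered list of solutions measured in one simulated
# analytical campaign.

#' Default gravimetric spike parameters
#'
#' The enriched-isotope spike mix added gravimetrically to aliquots of each
#' wine and method blank: enriched 65Cu and enriched 206Pb in one solution,
#' with concentrations chosen so that the default spike mass (0.1 g into a
#' 10 g aliquot) delivers spike levels of 100 ug/L Cu and 5 ug/L Pb in the
#' spiked sample.
#'
#' The isotopic abundance vectors are documented placeholders for a highly
#' enriched material (not a certificate value); real analyses must supply the
#' manufacturer's certified abundances through the configuration.
#'
#' @return named list per spiked element with `conc` (ug/L in the spike
#'   solution) and `abundance` (named mole fractions by mass number).
#' @export
default_spike_params <- function() {
  list(
    Cu = list(conc = 10000,
              abundance = c(`63` = 0.01, `65` = 0.99)),
    Pb = list(conc = 500,
              abundance = c(`204` = 0, `206` = 0.990, `207` = 0.006,
                            `208` = 0.004))
  )
}

.design_row <- function(sample_id, wine, role, method, replicate = 1L,
                        run = 1L, nominal = NA_real_, mass_sample = NA_real_,
                        spike_mass = 0, material = NA_character_) {
  data.frame(sample_id = sample_id, wine = wine, role = role, method = method,
             replicate = as.integer(replicate), run = as.integer(run),
             nominal = nominal, mass_sample = mass_sample,
             spike_mass = spike_mass, material = material,
             stringsAsFactors = FALSE)
}

#' Build the batch design
#'
#' Assembles the ordered solution list of one simulated campaign: for each
#' matrix group (the shared 4% ethanol / 5% nitric acid matrix of the three
#' direct methods, and the 5% nitric acid matrix of microwave digestion) a
#' six-point natural-abundance calibration series, a six-point
#' enriched-material calibration series, continuing calibration blanks (six
#' per run for the direct group, measured in two runs; eight for microwave),
#' then the prepared solutions of every method in the group - triplicate
#' method blanks, triplicate wines, and triplicate spiked counterparts of
#' each wine and of the method blank - with a 10 ug/L QC standard inserted
#' every `qc_every` solutions.
#'
#' @param wines wine codes.
#' @param methods preparation methods.
#' @param replicates replicates per sample.
#' @param cal_levels calibration concentrations (ug/L), at least two distinct.
#' @param qc_every insert a QC standard after every this many solutions.
#' @param qc_nominal QC standard concentration (ug/L).
#' @param n_ccb named list of continuing-calibration-blank counts per run for
#'   the `direct` and `MW` groups.
#' @param n_runs named list of run counts for the two groups (detection
#'   limits of the direct methods are averaged across runs).
#' @param mass_sample sample aliquot mass (g).
#' @param spike_mass spike solution mass added to spiked aliquots (g).
#' @return data frame, one row per solution, in acquisition order. Columns:
#'   `sample_id`, `wine`, `role`, `method`, `replicate`, `run`, `nominal`,
#'   `mass_sample`, `spike_mass`, `material`.
#' @export
batch_design <- function(wines = c("C", "PN", "S", "T"),
                         methods = prep_methods(),
                         replicates = 3,
                         cal_levels = c(0, 1, 10, 50, 100, 500),
                         qc_every = 15,
                         qc_nominal = 10,
                         n_ccb = list(direct = 6, MW = 8),
                         n_runs = list(direct = 2, MW = 1),
                         mass_sample = 10,
                         spike_mass = 0.1) {
  if (length(unique(cal_levels)) < 2) {
    stop("calibration design needs at least two distinct levels")
  }
  groups <- unique(matrix_group(methods))
  qc_counter <- new.env()
  out <- list()
  for (g in groups) {
    g_methods <- methods[matrix_group(methods) == g]
    cal <- do.call(rbind, lapply(seq_along(cal_levels), function(i) {
      .design_row(sprintf("cal_%s_L%d", g, i), "BLANK",
                  "calibration_standard", g, replicate = 1L,
                  nominal = cal_levels[i], material = "natural")
    }))
    enr <- do.call(rbind, lapply(seq_along(cal_levels), function(i) {
      .design_row(sprintf("enrcal_%s_L%d", g, i), "BLANK",
                  "spike_calibration_standard", g, replicate = 1L,
                  nominal = cal_levels[i], material = "enriched")
    }))
    ccb1 <- do.call(rbind, lapply(seq_len(n_ccb[[g]]), function(i) {
      .design_row(sprintf("ccb_%s_r1_%d", g, i), "BLANK",
                  "continuing_calibration_blank", g, replicate = i, run = 1L)
    }))
    samples <- list()
    for (m in g_methods) {
      for (r in seq_len(replicates)) {
        samples[[length(samples) + 1L]] <-
          .design_row(sprintf("%s_blank_r%d", m, r), "BLANK", "method_blank",
                      m, replicate = r, mass_sample = mass_sample)
      }
      for (w in wines) {
        for (r in seq_len(replicates)) {
          samples[[length(samples) + 1L]] <-
            .design_row(sprintf("%s_%s_r%d", m, w, r), w, "sample", m,
                        replicate = r, mass_sample = mass_sample)
        }
      }
      for (r in seq_len(replicates)) {
        samples[[length(samples) + 1L]] <-
          .design_row(sprintf("%s_blank_spk_r%d", m, r), "BLANK",
                      "spiked_sample", m, replicate = r,
                      mass_sample = mass_sample, spike_mass = spike_mass)
      }
      for (w in wines) {
        for (r in seq_len(replicates)) {
          samples[[length(samples) + 1L]] <-
            .design_row(sprintf("%s_%s_spk_r%d", m, w, r), w, "spiked_sample",
                        m, replicate = r, mass_sample = mass_sample,
                        spike_mass = spike_mass)
        }
      }
    }
    samples <- do.call(rbind, samples)
    # interleave QC standards every qc_every solutions
    qc_n <- 0L
    seq_rows <- list()
    for (i in seq_len(nrow(samples))) {
      seq_rows[[length(seq_rows) + 1L]] <- samples[i, , drop = FALSE]
      if (i %% qc_every == 0) {
        qc_n <- qc_n + 1L
        seq_rows[[length(seq_rows) + 1L]] <-
          .design_row(sprintf("qc_%s_%d", g, qc_n), "BLANK", "qc_standard", g,
                      replicate = qc_n, nominal = qc_nominal)
      }
    }
    seq_rows <- do.call(rbind, seq_rows)
    extra_runs <- list()
    if (n_runs[[g]] > 1) {
      for (rr in seq(2L, n_runs[[g]])) {
        extra_runs[[length(extra_runs) + 1L]] <-
          do.call(rbind, lapply(seq_len(n_ccb[[g]]), function(i) {
            .design_row(sprintf("ccb_%s_r%d_%d", g, rr, i), "BLANK",
                        "continuing_calibration_blank", g, replicate = i,
                        run = rr)
          }))
      }
    }
    out[[g]] <- do.call(rbind, c(list(cal, enr, ccb1, seq_rows), extra_runs))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
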
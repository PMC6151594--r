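# Preparation-method effect structure: contamination, filtration losses,
# noise levels.

# Channels with lowered results in both filtration treatments (retention of
# organically complexed analytes on the 0.45 um PTFE filter).
.FILTRATION_RETENTION <- data.frame(
  element = c("Li", "Co", "Cu", "Cu", "Rb", "Sr", "Nb", "Cs", "W", "Tl",
              "Pb", "Pb"),
  mass = c(7L, 59L, 63L, 65L, 85L, 88L, 93L, 133L, 182L, 205L, 206L, 208L),
  retention = c(0.90, 0.90, 0.85, 0.85, 0.92, 0.92, 0.88, 0.90, 0.85, 0.90,
                0.88, 0.88),
  stringsAsFactors = FALSE
)

# Channels additionally lowered in AF relative to FA.
.AF_EXTRA_RETENTION <- data.frame(
  element = c("Al", "Mn", "Ni", "Zn", "As", "Se", "Ru"),
  mass = c(27L, 55L, 60L, 66L, 75L, 78L, 101L),
  retention = c(0.90, 0.90, 0.90, 0.90, 0.90, 0.90, 0.90),
  stringsAsFactors = FALSE
)

#' Default preparation-method effect parameters
#'
#' One effect structure per method, comprising:
#' \describe{
#'   \item{cv}{total relative standard deviation of replicate preparations
#'     (fraction). Microwave digestion 0.295; direct methods 0.13--0.18.}
#'   \item{cv_common_share}{fraction of the log-scale noise variance that is
#'     common to all analyte channels of one solution (sample transport /
#'     matrix fluctuation). Common-mode noise cancels in an isotope ratio but
#'     not in internal-standard normalization.}
#'   \item{contamination}{data frame (`element`, `mass`, `mean`) of additive
#'     contamination at the instrument (ug/L in the measured solution). The
#'     defaults divide the reference method-blank concentrations by the
#'     method's dilution factor so that quantified, dilution-corrected blank
#'     concentrations reproduce the reference blank profile.}
#'   \item{contamination_cv}{relative spread of the per-replicate lognormal
#'     contamination draw (reagent contamination varies between replicates).}
#'   \item{retention}{data frame (`element`, `mass`, `retention`) of
#'     multiplicative retention fractions in (0, 1] applied to the
#'     wine-derived analyte; channels absent from the table retain 1.
#'     Non-filtration methods (DD, MW) lose nothing.}
#'   \item{matrix_factor}{multiplicative response factor near 1; identical
#'     factors apply to samples and their matrix-matched standards, so the
#'     default is exactly 1.}
#' }
#'
#' @param dilution named dilution factors used to place contamination on the
#'   at-instrument scale.
#' @param blank_profile reference blank table, as from
#'   [default_blank_profile()].
#' @return named list of per-method effect parameter lists.
#' @export
default_method_effects <- function(dilution = c(DD = 3, FA = 3, AF = 3, MW = 10),
                                   blank_profile = default_blank_profile()) {
  contamination_for <- function(method) {
    col <- paste0("blank_", method)
    mean <- blank_profile[[col]] / dilution[[method]]
    keep <- !is.na(mean) & mean > 0
    data.frame(element = blank_profile$element[keep],
               mass = blank_profile$mass[keep],
               mean = mean[keep], stringsAsFactors = FALSE)
  }
  retention_for <- function(method) {
    if (method %in% c("DD", "MW")) {
      return(data.frame(element = character(), mass = integer(),
                        retention = numeric(), stringsAsFactors = FALSE))
    }
    ret <- .FILTRATION_RETENTION
    if (method == "AF") ret <- rbind(ret, .AF_EXTRA_RETENTION)
    ret
  }
  cvs <- c(DD = 0.13, FA = 0.155, AF = 0.18, MW = 0.295)
  out <- lapply(names(cvs), function(m) {
    list(code = m,
         cv = unname(cvs[[m]]),
         cv_common_share = 0.8,
         contamination = contamination_for(m),
         contamination_cv = 0.5,
         retention = retention_for(m),
         matrix_factor = 1)
  })
  names(out) <- names(cvs)
  out
}

#' Effect parameters for a null (no method difference) simulation
#'
#' All four methods share one noise level; no contamination, no filtration
#' loss. Used for type-I-error calibration of the method-effect tests.
#'
#' @param cv shared noise CV (fraction).
#' @param cv_common_share common-mode share of the log-variance.
#' @return named list of per-method effect parameter lists.
#' @export
null_method_effects <- function(cv = 0.15, cv_common_share = 0.8) {
  empty_c <- data.frame(element = character(), mass = integer(),
                        mean = numeric(), stringsAsFactors = FALSE)
  empty_r <- data.frame(element = character(), mass = integer(),
                        retention = numeric(), stringsAsFactors = FALSE)
  out <- lapply(prep_methods(), function(m) {
    list(code = m, cv = cv, cv_common_share = cv_common_share,
         contamination = empty_c, contamination_cv = 0,
         retention = empty_r, matrix_factor = 1)
  })
  names(out) <- prep_methods()
  out
}

#' Per-channel retention vector for a method
#' @keywords internal
retention_vector <- function(effect, channels) {
  ret <- rep(1, nrow(channels))
  tab <- effect$retention
  if (!is.null(tab) && nrow(tab) > 0) {
    if (any(tab$retention <= 0 | tab$retention > 1)) {
      stop("retention fractions must lie in (0, 1]")
    }
    idx <- match(paste(channels$element, channels$mass),
                 paste(tab$element, tab$mass))
    hit <- !is.na(idx)
    ret[hit] <- tab$retention[idx[hit]]
  }
  ret
}

#' Per-channel mean contamination vector for a method
#' @keywords internal
contamination_vector <- function(effect, channels) {
  con <- rep(0, nrow(channels))
  tab <- effect$contamination
  if (!is.null(tab) && nrow(tab) > 0) {
    idx <- match(paste(channels$element, channels$mass),
                 paste(tab$element, tab$mass))
    hit <- !is.na(idx)
    con[hit] <- tab$mean[idx[hit]]
  }
  con
}

#' Expected at-instrument concentration after sample preparation
#'
#' Deterministic forward model of one preparation method: the true
#' concentration in the undiluted wine is divided by the method's dilution
#' factor, multiplied by the per-channel retention fraction (filtration
#' loss), and the method's mean additive contamination (at-instrument scale)
#' is added. No measurement noise is applied.
#'
#' @param truth truth table from [generate_truth()].
#' @param method preparation method code.
#' @param effects effect structure, as from [default_method_effects()].
#' @param channels channel registry.
#' @param dilution dilution factor; defaults to [dilution_factor()] of the
#'   method.
#' @return data frame `wine`, `element`, `mass`, `conc_instrument` (ug/L in
#'   the measured solution, element-equivalent scale).
#' @examples
#' tt <- data.frame(wine = "C", element = "Cu", truth = 300)
#' eff <- null_method_effects()
#' ch <- subset(default_channels(), element == "Cu" & mass == 63)
#' apply_prep_effects(tt, "DD", eff, ch)$conc_instrument  # 100
#' @export
apply_prep_effects <- function(truth, method, effects,
                               channels = default_channels(),
                               dilution = dilution_factor(method)) {
  effect <- effects[[method]]
  if (is.null(effect)) stop("no effect parameters defined for ", method)
  ret <- retention_vector(effect, channels)
  con <- contamination_vector(effect, channels)
  wines <- unique(truth$wine)
  out <- do.call(rbind, lapply(wines, function(w) {
    tw <- truth[truth$wine == w, , drop = FALSE]
    elem_truth <- stats::setNames(tw$truth, tw$element)
    base <- elem_truth[channels$element]
    base[is.na(base)] <- 0
    data.frame(wine = w, element = channels$element, mass = channels$mass,
               conc_instrument = unname(base) / dilution * ret + con,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
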
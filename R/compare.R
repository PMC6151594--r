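# Statistical comparison of preparation methods: MANOVA gate, per-isotope
# ANOVA with Tukey letter displays, blank-compromise exclusion, RSD
# summaries, correlation-matrix PCA.

.check_long <- function(df) {
  need <- c("wine", "method", "replicate", "element", "mass", "conc")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
}

.check_balanced <- function(df) {
  counts <- table(df$wine, df$method)
  if (length(unique(as.vector(counts))) != 1) {
    stop("unbalanced design: every (sample, method) cell must hold the same ",
         "number of replicates")
  }
}

#' Multivariate test of the preparation-method effect
#'
#' Fits a MANOVA of the per-channel concentrations on the main effects
#' sample, replicate and method, and reports the Pillai-trace test of the
#' method effect. The multivariate residual covariance is singular when the
#' number of response channels reaches the residual degrees of freedom; in
#' that case the function stops and asks for a channel subset (or use
#' principal-component scores, as the pipeline default does).
#'
#' @param df long concentration table (`wine`, `method`, `replicate`,
#'   `element`, `mass`, `conc`).
#' @param channels optional data frame `element`, `mass` restricting the
#'   response set.
#' @return list with `statistic` (Pillai trace), `approx_f`, `df`, `p_value`,
#'   `channels` (the channel keys used).
#' @export
manova_method_effect <- function(df, channels = NULL) {
  .check_long(df)
  df <- df[df$wine != "BLANK", , drop = FALSE]
  if (!is.null(channels)) {
    keep <- paste(df$element, df$mass) %in%
      paste(channels$element, channels$mass)
    df <- df[keep, , drop = FALSE]
  }
  if (length(unique(df$method)) < 2) stop("need at least two methods")
  .check_balanced(df)
  key <- paste0(df$element, df$mass)
  obs <- paste(df$wine, df$method, df$replicate, sep = "|")
  wide <- stats::reshape(
    data.frame(obs = obs, key = key, conc = df$conc,
               stringsAsFactors = FALSE),
    idvar = "obs", timevar = "key", direction = "wide")
  y <- as.matrix(wide[, -1, drop = FALSE])
  parts <- strsplit(wide$obs, "|", fixed = TRUE)
  sample_f <- factor(vapply(parts, `[[`, character(1), 1))
  method_f <- factor(vapply(parts, `[[`, character(1), 2))
  rep_f <- factor(vapply(parts, `[[`, character(1), 3))
  df_model <- (nlevels(sample_f) - 1) + (nlevels(method_f) - 1) +
    (nlevels(rep_f) - 1) + 1
  df_resid <- nrow(y) - df_model
  if (ncol(y) >= df_resid) {
    stop("singular residual covariance: ", ncol(y), " response channels but ",
         "only ", df_resid, " residual degrees of freedom; supply a channel ",
         "subset via `channels` or test principal-component scores")
  }
  fit <- stats::manova(y ~ sample_f + rep_f + method_f)
  st <- summary(fit, test = "Pillai")$stats
  row <- st["method_f", ]
  list(statistic = unname(row["Pillai"]),
       approx_f = unname(row["approx F"]),
       df = unname(c(row["num Df"], row["den Df"])),
       p_value = unname(row["Pr(>F)"]),
       channels = unique(paste0(df$element, df$mass)))
}

#' Per-isotope analysis of variance
#'
#' Univariate ANOVA of each channel's concentrations on the main effects
#' sample, replicate and method (no interactions), on a balanced design. On
#' such designs the sums of squares decompose exactly:
#' `SS_sample + SS_replicate + SS_method + SS_residual = SS_total`.
#' Channels whose observations are all equal are flagged degenerate (zero
#' residual variance; no F statistic).
#'
#' @param df long concentration table; wines only (no blanks) unless blanks
#'   are deliberately included as an extra sample level.
#' @return data frame with one row per (channel, effect): `element`, `mass`,
#'   `effect` in sample/replicate/method/Residuals, `df`, `sumsq`,
#'   `statistic` (F), `p_value`, `degenerate`.
#' @export
anova_per_isotope <- function(df) {
  .check_long(df)
  .check_balanced(df)
  keys <- unique(df[, c("element", "mass")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    d <- df[df$element == k$element & df$mass == k$mass, , drop = FALSE]
    degenerate <- stats::var(d$conc) == 0
    fit <- stats::aov(conc ~ factor(wine) + factor(replicate) +
                        factor(method), data = d)
    tab <- summary(fit)[[1]]
    effect <- c("sample", "replicate", "method", "Residuals")
    data.frame(element = k$element, mass = k$mass, effect = effect,
               df = tab[["Df"]], sumsq = tab[["Sum Sq"]],
               statistic = if (degenerate) rep(NA_real_, 4) else
                 c(tab[["F value"]][1:3], NA),
               p_value = if (degenerate) rep(NA_real_, 4) else
                 c(tab[["Pr(>F)"]][1:3], NA),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Tukey honestly-significant-difference letter display
#'
#' Compact letter display for equal-sized groups: two groups differ exactly
#' when their means differ by more than
#' `HSD = qtukey(1 - alpha, k, df) * sqrt(MSE / n)`. Because the
#' not-different relation on means sorted by value is an interval relation,
#' letters are the maximal runs of mutually not-different groups, and two
#' groups share a letter if and only if they are not significantly
#' different.
#'
#' @param means named numeric vector of group means.
#' @param mse residual mean square from the ANOVA.
#' @param df_resid residual degrees of freedom.
#' @param n observations per group.
#' @param alpha significance level.
#' @return character vector of letters, named and ordered like `means`.
#' @examples
#' tukey_letters(c(A = 1, B = 1, C = 10), mse = 0.01, df_resid = 6, n = 3)
#' @export
tukey_letters <- function(means, mse, df_resid, n, alpha = 0.05) {
  if (length(means) < 2) stop("at least two groups are required")
  if (mse <= 0) stop("mean squared error must be positive")
  hsd <- stats::qtukey(1 - alpha, length(means), df_resid) * sqrt(mse / n)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  intervals <- list()
  prev_end <- 0L
  for (i in seq_len(k)) {
    j <- i
    while (j < k && (m[i] - m[j + 1L]) <= hsd) j <- j + 1L
    if (j > prev_end) {
      intervals[[length(intervals) + 1L]] <- c(i, j)
      prev_end <- j
    }
  }
  letters_sorted <- character(k)
  for (li in seq_along(intervals)) {
    span <- intervals[[li]]
    idx <- span[1]:span[2]
    letters_sorted[idx] <- paste0(letters_sorted[idx], letters[li])
  }
  out <- character(k)
  out[ord] <- letters_sorted
  names(out) <- names(means)
  out
}

#' Method-mean letter displays per channel
#'
#' Computes, for every channel, the per-method means and a Tukey letter
#' display using the residual mean square of the channel's main-effects
#' ANOVA.
#'
#' @param df long concentration table (wines only).
#' @param alpha significance level.
#' @return data frame `element`, `mass`, `method`, `mean`, `letter`.
#' @export
tukey_method_table <- function(df, alpha = 0.05) {
  .check_long(df)
  .check_balanced(df)
  keys <- unique(df[, c("element", "mass")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    d <- df[df$element == k$element & df$mass == k$mass, , drop = FALSE]
    fit <- stats::aov(conc ~ factor(wine) + factor(replicate) +
                        factor(method), data = d)
    tab <- summary(fit)[[1]]
    mse <- tab[["Mean Sq"]][nrow(tab)]
    df_resid <- tab[["Df"]][nrow(tab)]
    means <- tapply(d$conc, d$method, mean)
    n <- nrow(d) / length(means)
    letter <- if (mse > 0) {
      tukey_letters(means, mse, df_resid, n, alpha)
    } else {
      stats::setNames(rep("a", length(means)), names(means))
    }
    data.frame(element = k$element, mass = k$mass, method = names(means),
               mean = as.vector(means), letter = unname(letter[names(means)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Blank-compromise channel exclusion
#'
#' Flags channels whose signal is compromised by the method blanks, by the
#' union of two rules evaluated on the long table with the method blanks
#' included as an extra sample level:
#' \describe{
#'   \item{no-sample-effect}{the sample main effect of the ANOVA (samples =
#'     wines plus blank) is not significant at `alpha`: the channel does not
#'     distinguish wines from analyte-free blanks.}
#'   \item{blank-exceeds-sample}{for at least one method, the mean blank
#'     concentration reaches or exceeds the mean concentration measured in
#'     the wines prepared by that method.}
#' }
#'
#' @param df long concentration table including `wine == "BLANK"` rows
#'   (method blanks).
#' @param alpha significance level for the sample effect.
#' @return data frame `element`, `mass`, `excluded`, `reason`
#'   (comma-separated), `p_sample`.
#' @export
blank_compromise_filter <- function(df, alpha = 0.05) {
  .check_long(df)
  if (!any(df$wine == "BLANK")) {
    stop("method blanks (wine == 'BLANK') are required")
  }
  keys <- unique(df[, c("element", "mass")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    d <- df[df$element == k$element & df$mass == k$mass, , drop = FALSE]
    reasons <- character(0)
    p_sample <- NA_real_
    if (stats::var(d$conc) == 0) {
      reasons <- "no-sample-effect"
    } else {
      fit <- stats::aov(conc ~ factor(wine) + factor(replicate) +
                          factor(method), data = d)
      tab <- summary(fit)[[1]]
      p_sample <- tab[["Pr(>F)"]][1]
      if (is.na(p_sample) || p_sample > alpha) {
        reasons <- c(reasons, "no-sample-effect")
      }
    }
    for (m in unique(d$method)) {
      blank_mean <- mean(d$conc[d$method == m & d$wine == "BLANK"])
      wine_mean <- mean(d$conc[d$method == m & d$wine != "BLANK"])
      if (is.finite(blank_mean) && is.finite(wine_mean) &&
          blank_mean >= wine_mean) {
        reasons <- c(reasons, "blank-exceeds-sample")
        break
      }
    }
    data.frame(element = k$element, mass = k$mass,
               excluded = length(reasons) > 0,
               reason = paste(unique(reasons), collapse = ","),
               p_sample = p_sample, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Profile matrix of sample means
#'
#' Averages the censored concentrations over replicates into a (wine x
#' method) by channel matrix for multivariate display.
#'
#' @param df long concentration table (wines only).
#' @return numeric matrix; rows named `wine_method`, columns
#'   `elementMass`.
#' @export
profile_matrix <- function(df) {
  .check_long(df)
  df <- df[df$wine != "BLANK", , drop = FALSE]
  row_key <- paste(df$wine, df$method, sep = "_")
  col_key <- paste0(df$element, df$mass)
  agg <- stats::aggregate(df$conc, list(row = row_key, col = col_key), mean)
  rows <- unique(row_key)
  cols <- unique(col_key)
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(agg$row, rows), match(agg$col, cols))] <- agg$x
  if (any(is.na(m))) stop("profile matrix has missing cells")
  m
}

#' Correlation-matrix principal component analysis of elemental profiles
#'
#' Standardizes every channel to zero mean and unit variance (the
#' correlation-matrix convention, so channels spanning nanograms to
#' milligrams per litre contribute comparably) and eigendecomposes. Columns
#' with zero variance (e.g. fully censored channels) are dropped with a
#' warning. The sign of each component is fixed so that its
#' largest-magnitude loading is positive. Eigenvalues sum to the number of
#' retained columns and the variance fractions to 1.
#'
#' @param x profile matrix (rows = samples, columns = channels).
#' @return list with `scores` (rows x components), `loadings` (channels x
#'   components), `variance_fraction`, `dropped` (names of zero-variance
#'   columns).
#' @export
pca_profiles <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least 2 rows and 2 columns")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped) > 0) {
    warning("dropping zero-variance columns: ",
            paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < 2) stop("fewer than 2 columns with variance remain")
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(fit$x, 2, flip, `*`)
  loadings <- sweep(fit$rotation, 2, flip, `*`)
  ev <- fit$sdev^2
  list(scores = scores, loadings = loadings,
       variance_fraction = ev / sum(ev), dropped = dropped)
}

#' Mean replicate RSD per preparation method
#'
#' Computes the relative standard deviation over replicates for every
#' (wine, method, channel) group in which all replicates are uncensored
#' (detected), then averages per method. Censored groups sit at the
#' substituted half-LOD constant and carry no precision information.
#'
#' @param df long concentration table with a logical `censored` column.
#' @return data frame `method`, `mean_rsd` (percent), `n_groups`.
#' @export
summarize_rsd <- function(df) {
  .check_long(df)
  if (is.null(df$censored)) df$censored <- FALSE
  df <- df[df$wine != "BLANK", , drop = FALSE]
  key <- paste(df$wine, df$method, df$element, df$mass, sep = "|")
  groups <- split(df, key)
  vals <- lapply(groups, function(g) {
    if (nrow(g) < 2 || any(g$censored) || mean(g$conc) == 0) return(NULL)
    data.frame(method = g$method[1], rsd = rsd(g$conc),
               stringsAsFactors = FALSE)
  })
  vals <- do.call(rbind, vals)
  if (is.null(vals) || nrow(vals) == 0) {
    stop("no uncensored replicate groups available")
  }
  agg <- stats::aggregate(vals$rsd, list(method = vals$method), mean)
  cnt <- stats::aggregate(vals$rsd, list(method = vals$method), length)
  out <- data.frame(method = agg$method, mean_rsd = agg$x,
                    n_groups = cnt$x, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
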
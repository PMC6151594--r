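test_that("per-isotope ANOVA matches brute-force sums of squares on a
          balanced design", {
  d <- toy_long(means_by_method = c(DD = 10, FA = 12, AF = 9, MW = 20),
                sd = 1, seed = 31)
  res <- anova_per_isotope(d)
  oracle <- balanced_ss(d)
  get_ss <- function(e) res$sumsq[res$effect == e]
  expect_equal(get_ss("sample"), oracle$sample)
  expect_equal(get_ss("replicate"), oracle$replicate)
  expect_equal(get_ss("method"), oracle$method)
  expect_equal(get_ss("Residuals"), oracle$residual)
  # exact decomposition
  expect_equal(sum(res$sumsq), oracle$total)
})

test_that("ANOVA flags degenerate channels and rejects unbalanced input", {
  d <- toy_long()
  d$conc <- 5
  res <- anova_per_isotope(d)
  expect_true(all(res$degenerate))
  expect_true(all(is.na(res$statistic)))

  d2 <- toy_long()
  expect_error(anova_per_isotope(d2[-1, ]), "unbalanced")
})

test_that("an injected microwave shift is detected as a method effect", {
  d <- toy_long(means_by_method = c(DD = 10, FA = 10, AF = 10, MW = 16),
                sd = 1, seed = 32)
  res <- anova_per_isotope(d)
  p <- res$p_value[res$effect == "method"]
  expect_lt(p, 0.05)
})

test_that("Tukey letters agree with exhaustive pairwise comparisons", {
  expect_equal(unname(tukey_letters(c(a = 5, b = 5, c = 5), mse = 1,
                                    df_resid = 8, n = 3)),
               c("a", "a", "a"))
  expect_equal(sort(unname(tukey_letters(c(lo = 0, hi = 100), mse = 1,
                                         df_resid = 6, n = 3))),
               c("a", "b"))
  set.seed(33)
  for (i in 1:25) {
    k <- sample(3:6, 1)
    means <- setNames(rnorm(k, 10, 2), paste0("g", seq_len(k)))
    mse <- runif(1, 0.1, 4)
    df_resid <- 3 * k - k - 2
    lt <- tukey_letters(means, mse, df_resid, n = 3)
    hsd <- qtukey(0.95, k, df_resid) * sqrt(mse / 3)
    share <- function(i, j) {
      length(intersect(strsplit(lt[i], "")[[1]],
                       strsplit(lt[j], "")[[1]])) > 0
    }
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      expect_identical(share(a, b),
                       unname(abs(means[a] - means[b]) <= hsd))
    }
  }
  expect_error(tukey_letters(c(a = 1, b = 2), mse = 0, df_resid = 3, n = 3),
               "positive")
})

test_that("method letter table labels groups with their means", {
  d <- toy_long(means_by_method = c(DD = 10, FA = 10, AF = 10, MW = 50),
                sd = 0.5, seed = 34)
  tab <- tukey_method_table(d)
  expect_equal(nrow(tab), 4)
  mw <- tab$letter[tab$method == "MW"]
  others <- tab$letter[tab$method != "MW"]
  expect_false(any(vapply(others, function(x)
    grepl(mw, x, fixed = TRUE), logical(1))))
  expect_equal(length(unique(others)), 1L)
})

test_that("the MANOVA gate detects an injected method effect and errors on
          singular input", {
  tt <- generate_truth(seed = 40)
  ch <- default_channels()
  mw_ch <- ch[paste(ch$element, ch$mass) %in%
                c("Mn 55", "Co 59", "Ta 181", "W 182", "Nb 93"), ]
  eff <- default_method_effects()
  d <- simulate_concentrations(tt, eff, replicates = 3, seed = 41,
                               channels = mw_ch)
  res <- manova_method_effect(d)
  expect_lt(res$p_value, 0.05)
  expect_true(res$statistic > 0 && res$statistic <= length(unique(d$method)))

  # permuting the method labels (within wine x replicate strata, preserving
  # balance) destroys the effect
  set.seed(42)
  d_perm <- d
  methods <- unique(d$method)
  for (w in unique(d$wine)) {
    for (r in unique(d$replicate)) {
      sel <- d$wine == w & d$replicate == r
      perm <- sample(methods)
      d_perm$method[sel] <- perm[match(d$method[sel], methods)]
    }
  }
  res_perm <- manova_method_effect(d_perm)
  expect_gt(res_perm$p_value, 0.05)

  # 43 channels on 48 observations: singular, with an instructive message
  d_all <- simulate_concentrations(tt, eff, replicates = 3, seed = 43)
  expect_error(manova_method_effect(d_all), "channel subset")
})

test_that("blank-compromise filter excludes for the right reasons", {
  mk <- function(wine_levels, blank_level, seed = 50) {
    set.seed(seed)
    g <- expand.grid(wine = c(names(wine_levels), "BLANK"),
                     method = c("DD", "FA", "AF", "MW"),
                     replicate = 1:3, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
    base <- c(wine_levels, BLANK = blank_level)
    g$element <- "X"; g$mass <- 1L
    g$conc <- base[g$wine] + rnorm(nrow(g), 0, 0.05)
    g
  }
  # blank at wine levels: excluded as blank-exceeds-sample
  d1 <- mk(c(C = 1, PN = 2, S = 3, T = 4), blank_level = 3)
  r1 <- blank_compromise_filter(d1)
  expect_true(r1$excluded)
  expect_match(r1$reason, "blank-exceeds-sample")

  # identical across wines and blanks: no sample effect
  d2 <- mk(c(C = 2, PN = 2, S = 2, T = 2), blank_level = 2)
  r2 <- blank_compromise_filter(d2)
  expect_true(r2$excluded)
  expect_match(r2$reason, "no-sample-effect")

  # clean high-signal channel: retained
  d3 <- mk(c(C = 10, PN = 20, S = 30, T = 40), blank_level = 0.1)
  r3 <- blank_compromise_filter(d3)
  expect_false(r3$excluded)
  expect_error(blank_compromise_filter(d3[d3$wine != "BLANK", ]), "blanks")
})

test_that("correlation-matrix PCA has the expected algebra", {
  # two perfectly correlated columns: one component carries everything
  x <- cbind(a = c(1, 2, 3, 4), b = 2 * c(1, 2, 3, 4) + 5)
  p <- pca_profiles(x)
  expect_equal(p$variance_fraction[1], 1)

  # eigenvalues sum to the number of retained columns
  set.seed(60)
  y <- matrix(rnorm(40), 8, 5)
  colnames(y) <- letters[1:5]
  p2 <- pca_profiles(y)
  ev <- p2$variance_fraction * 5
  expect_equal(sum(ev), 5)

  # 3x2 toy: eigenvalues of a 2x2 correlation matrix are 1 +/- r
  z <- cbind(u = c(1, 2, 4), v = c(1, 3, 3))
  r <- cor(z)[1, 2]
  p3 <- pca_profiles(z)
  expect_equal(unname(p3$variance_fraction * 2), c(1 + r, 1 - r))

  # affine per-column rescaling leaves the scores unchanged
  y2 <- sweep(sweep(y, 2, c(2, 3, 0.5, 10, 7), `*`), 2, 1:5, `+`)
  p4 <- pca_profiles(y2)
  expect_equal(p4$scores, p2$scores, tolerance = 1e-10)

  # zero-variance columns are dropped with a warning
  y3 <- cbind(y, const = 1)
  expect_warning(p5 <- pca_profiles(y3), "zero-variance")
  expect_equal(p5$dropped, "const")
})

test_that("RSD summary averages only detected replicate groups", {
  d <- toy_long(sd = 0)
  d$censored <- FALSE
  s0 <- summarize_rsd(d)
  expect_equal(s0$mean_rsd, rep(0, 4))

  # configured noise comes back out as the mean RSD, up to the small-sample
  # attenuation of the n = 3 standard deviation (E[s] = c4 * sigma,
  # c4(3) = 0.8862)
  tt <- generate_truth(seed = 61)
  eff <- null_method_effects(cv = 0.295)
  sim <- simulate_concentrations(tt, eff, methods = "MW", replicates = 3,
                                 seed = 62)
  sim$censored <- FALSE
  s1 <- summarize_rsd(sim)
  expect_equal(s1$mean_rsd / 0.8862, 29.5, tolerance = 0.1 * 29.5)

  # censored groups are excluded from the average
  d2 <- toy_long()
  d2$censored <- d2$element == "Mn" & d2$wine == "C" & d2$method == "DD" &
    d2$replicate == 1
  s2 <- summarize_rsd(d2)
  expect_equal(s2$n_groups[s2$method == "DD"], 3)
  expect_equal(s2$n_groups[s2$method == "FA"], 4)
})
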
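test_that("internal-standard normalization is a guarded ratio", {
  expect_equal(normalize_response(1000, 100), 10)
  expect_equal(normalize_response(0, 100), 0)
  expect_error(normalize_response(10, 0), "instrument fault")
  expect_error(normalize_response(10, -5), "instrument fault")
})

test_that("drift cancels under internal-standard normalization", {
  cfg <- default_config(seed = 1)
  cfg$instrument <- noise_free_instrument(cfg$instrument)
  cfg$instrument$drift_step <- 0.05   # strong drift, no other noise
  tt <- generate_truth(seed = 2)
  ch <- tiny_channels("Mn")
  d <- batch_design(wines = "C", methods = "DD", replicates = 1)
  rec <- simulate_batch(d, tt, noise_free_effects(cfg$effects),
                        cfg$instrument, ch, cfg$spikes, seed = 11)
  std <- rec[rec$role == "calibration_standard", ]
  expect_gt(diff(range(std$is_response)), 0)  # drift really moved
  norm <- std$response / std$is_response
  fit <- lm(norm ~ std$nominal)
  expect_lt(max(abs(residuals(fit))), 1e-12)
})

test_that("calibration fitting recovers exact and least-squares lines", {
  mk_std <- function(x, y) {
    data.frame(sample_id = paste0("s", seq_along(x)), wine = "BLANK",
               role = "calibration_standard", method = "direct",
               replicate = 1L, run = 1L, nominal = x, mass_sample = NA,
               spike_mass = 0, material = "natural", element = "X",
               mass = 1L, mode = "helium", is_element = "Y", is_mass = 2L,
               response = y, is_response = 1, stringsAsFactors = FALSE)
  }
  # exact line y = 2x + 1
  cur <- fit_calibration(mk_std(c(0, 1, 2, 5), 2 * c(0, 1, 2, 5) + 1))
  expect_equal(cur$slope, 2)
  expect_equal(cur$intercept, 1)
  expect_equal(cur$r_squared, 1)

  # duplicate x with differing y: normal-equation oracle
  x <- c(0, 1, 1, 2)
  y <- c(1, 2, 4, 5)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  cur2 <- fit_calibration(mk_std(x, y))
  expect_equal(cur2$slope, sxy / sxx)
  expect_equal(cur2$intercept, mean(y) - cur2$slope * mean(x))

  # degenerate design
  expect_error(fit_calibration(mk_std(c(5, 5), c(1, 2))), "degenerate")
})

test_that("external quantitation applies curve and dilution factor", {
  rec <- data.frame(sample_id = "s1", wine = "C", role = "sample",
                    method = "DD", replicate = 1L, run = 1L, nominal = NA,
                    mass_sample = 10, spike_mass = 0, material = NA,
                    element = "X", mass = 1L, mode = "helium",
                    is_element = "Y", is_mass = 2L,
                    response = 21, is_response = 1, stringsAsFactors = FALSE)
  cur <- data.frame(method = "direct", material = "natural", element = "X",
                    mass = 1L, slope = 2, intercept = 1, r_squared = 1,
                    n_levels = 6, stringsAsFactors = FALSE)
  q <- quantify_external(rec, cur)
  expect_equal(q$conc, (21 - 1) / 2 * 3)   # 30 ug/L
  rec$response <- 1                        # normalized equals intercept
  expect_equal(quantify_external(rec, cur)$conc, 0)
  cur$slope <- -1
  expect_error(quantify_external(rec, cur), "slope")
})

test_that("the detection-limit t multiplier follows the one-tailed convention", {
  expect_equal(t_critical(6), 3.365, tolerance = 5e-4)
  expect_equal(t_critical(8), 2.998, tolerance = 5e-4)
  expect_equal(t_critical(2), 31.821, tolerance = 5e-4)
  expect_equal(t_critical(6), qt(0.99, 5))
  expect_error(t_critical(1), "at least two")
})

test_that("LOD/LOQ come from the blank SD with the t and 10x rules", {
  expect_equal(compute_lod_loq(c(1, 1, 1))$lod, 0)
  expect_equal(compute_lod_loq(c(1, 1, 1))$loq, 0)

  res <- compute_lod_loq(0:5)
  s <- sd(0:5)
  expect_equal(res$lod, qt(0.99, 5) * s)
  expect_equal(res$lod, 6.295, tolerance = 1e-3)
  expect_equal(res$loq, 18.708, tolerance = 1e-3)
  # lod/loq ratio is exactly t/10, and both scale linearly with the SD
  expect_equal(res$lod / res$loq, res$t_value / 10)
  res2 <- compute_lod_loq(3 * (0:5))
  expect_equal(res2$lod, 3 * res$lod)
  expect_error(compute_lod_loq(1), "at least two")
})

test_that("direct-method limits average across analytical runs", {
  q <- data.frame(role = "continuing_calibration_blank", method = "direct",
                  element = "X", mass = 1L,
                  run = rep(1:2, each = 6),
                  conc = c(0:5, 2 * (0:5)), stringsAsFactors = FALSE)
  dl <- detection_limits(q)
  one <- compute_lod_loq(0:5)
  expect_equal(dl$lod, mean(c(one$lod, 2 * one$lod)))
  expect_equal(dl$n_runs, 2)
})

test_that("censoring substitutes half the detection limit exactly once", {
  d <- data.frame(conc = c(0.3, 2.0, 0.9), lod = c(1, 1, 1))
  c1 <- censor_below_lod(d)
  expect_equal(c1$conc, c(0.5, 2.0, 0.5))
  expect_equal(c1$censored, c(TRUE, FALSE, TRUE))
  # idempotent: the substituted lod/2 is itself below lod but stays put
  c2 <- censor_below_lod(c1)
  expect_identical(c1, c2)
  expect_error(censor_below_lod(data.frame(conc = 1)), "lod")
})

test_that("QC acceptance combines accuracy and precision", {
  expect_true(qc_check(c(10, 10, 10))$pass)
  chk <- qc_check(c(13, 13, 13))
  expect_false(chk$pass)           # 30% bias
  expect_equal(chk$bias, 0.3)
  chk2 <- qc_check(c(8, 12))
  expect_equal(chk2$mean, 10)
  expect_equal(chk2$rsd, 28.28, tolerance = 1e-3)
  expect_false(chk2$pass)          # accurate but imprecise
  expect_error(qc_check(numeric(0)), "at least two")
})

test_that("spike recovery follows the difference-over-level formula", {
  expect_equal(spike_recovery(105, 5, 100), 100)
  expect_equal(spike_recovery(85, 5, 100), 80)
  expect_error(spike_recovery(85, 5, 0), "positive")
})

test_that("relative standard deviation behaves and scales", {
  expect_equal(rsd(c(1, 1, 1)), 0)
  expect_equal(rsd(c(8, 12)), 28.28, tolerance = 1e-3)
  x <- c(3, 5, 9)
  expect_equal(rsd(10 * x), rsd(x))
  expect_error(rsd(5), "at least two")
  expect_error(rsd(c(-1, 1)), "zero mean")
})

test_that("noise-free simulated wines quantify back to the truth", {
  cfg <- noise_free_config(seed = 1)
  tt <- generate_truth(seed = 1)
  ch <- tiny_channels(c("Mn", "Cu", "Pb"))
  cfg$channels <- ch
  d <- batch_design(methods = c("DD", "MW"))
  rec <- simulate_batch(d, tt, cfg$effects, cfg$instrument, ch, cfg$spikes,
                        seed = 12)
  q <- run_quantify(rec, cfg, verbose = FALSE)
  s <- q$quant[q$quant$role == "sample", ]
  s$truth <- tt$truth[match(paste(s$wine, s$element),
                            paste(tt$wine, tt$element))]
  expect_lt(max(abs(s$conc - s$truth) / s$truth), 1e-9)
})

test_that("noise-free spike recoveries are exactly 100 percent", {
  cfg <- noise_free_config(seed = 1)
  tt <- generate_truth(seed = 1)
  ch <- tiny_channels(c("Cu", "Pb"))
  cfg$channels <- ch
  d <- batch_design()
  rec <- simulate_batch(d, tt, cfg$effects, cfg$instrument, ch, cfg$spikes,
                        seed = 13)
  cur <- fit_calibration(rec)
  recov <- recovery_table(rec, cur, cfg$spikes)
  expect_equal(recov$recovery_pct, rep(100, nrow(recov)), tolerance = 1e-9)
})
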
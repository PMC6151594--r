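cfg0 <- noise_free_config(seed = 1)
truth0 <- generate_truth(seed = 1)

test_that("a batch is reproducible under its seed and refuses to run without one", {
  ch <- tiny_channels("Mn")
  d <- batch_design(wines = "C", methods = "DD", replicates = 1)
  cfg <- default_config(seed = 1)
  r1 <- simulate_batch(d, truth0, cfg$effects, cfg$instrument, ch,
                       cfg$spikes, seed = 9)
  r2 <- simulate_batch(d, truth0, cfg$effects, cfg$instrument, ch,
                       cfg$spikes, seed = 9)
  expect_identical(r1, r2)
  r3 <- simulate_batch(d, truth0, cfg$effects, cfg$instrument, ch,
                       cfg$spikes, seed = 10)
  expect_false(isTRUE(all.equal(r1$response, r3$response)))
  expect_error(simulate_batch(d, truth0, cfg$effects, cfg$instrument, ch,
                              cfg$spikes),
               "seed")
})

test_that("record count equals design cardinality (no silent drops)", {
  d <- batch_design()
  cfg <- default_config(seed = 1)
  rec <- simulate_batch(d, truth0, cfg$effects, cfg$instrument,
                        cfg$channels, cfg$spikes, seed = 2)
  expect_equal(nrow(rec), nrow(d) * nrow(cfg$channels))
  expect_true(all(rec$response >= 0))
  expect_true(all(rec$is_response > 0))
})

test_that("noise-free calibration responses are exactly linear", {
  ch <- tiny_channels("Mn")
  d <- batch_design(wines = "C", methods = "DD", replicates = 1)
  rec <- simulate_batch(d, truth0, cfg0$effects, cfg0$instrument, ch,
                        cfg0$spikes, seed = 3)
  std <- rec[rec$role == "calibration_standard", ]
  norm <- std$response / std$is_response
  fit <- lm(norm ~ std$nominal)
  expect_lt(max(abs(residuals(fit))), 1e-12)
})

test_that("a noise-free spiked blank reproduces the spike isotope ratio", {
  ch <- tiny_channels("Cu")
  d <- batch_design(wines = "C", methods = "DD", replicates = 1)
  rec <- simulate_batch(d, truth0, cfg0$effects, cfg0$instrument, ch,
                        cfg0$spikes, seed = 4)
  spk <- rec[rec$role == "spiked_sample" & rec$wine == "BLANK", ]
  ab <- default_spike_params()$Cu$abundance
  expect_equal(spk$response[spk$mass == 65] / spk$response[spk$mass == 63],
               unname(ab["65"] / ab["63"]), tolerance = 1e-12)
})

test_that("isotope amounts are conserved across a multi-isotope element", {
  # for a natural standard the two Cu channels carry mole fractions that sum
  # to the element amount
  ch <- tiny_channels("Cu")
  d <- batch_design(wines = "C", methods = "DD", replicates = 1)
  rec <- simulate_batch(d, truth0, cfg0$effects, cfg0$instrument, ch,
                        cfg0$spikes, seed = 4)
  std <- rec[rec$role == "calibration_standard" & rec$nominal == 100, ]
  sens <- cfg0$instrument$sensitivity$sens[1]
  drift <- std$is_response[1] / cfg0$instrument$is_sensitivity$sens[1]
  total <- sum(std$response) / (sens * drift)
  expect_equal(total, 100, tolerance = 1e-9)
})

test_that("spiked and unspiked blanks differ only at spiked masses", {
  cfg <- noise_free_config(seed = 1)
  d <- batch_design(wines = "C", methods = "DD", replicates = 1)
  rec <- simulate_batch(d, truth0, cfg$effects, cfg$instrument,
                        cfg$channels, cfg$spikes, seed = 5)
  blank <- rec[rec$role == "method_blank", ]
  spiked <- rec[rec$role == "spiked_sample" & rec$wine == "BLANK", ]
  key <- paste(blank$element, blank$mass)
  stopifnot(identical(key, paste(spiked$element, spiked$mass)))
  delta <- abs(spiked$response - blank$response)
  spiked_masses <- key %in% c("Cu 63", "Cu 65", "Pb 206", "Pb 208")
  expect_true(all(delta[spiked_masses] > 0))
  expect_true(all(delta[!spiked_masses] == 0))
})

test_that("concentration-level shortcut matches the effect model in expectation", {
  ch <- tiny_channels("Mn")
  eff <- null_method_effects(cv = 0)
  d <- simulate_concentrations(truth0, eff, methods = "DD", replicates = 2,
                               seed = 6, channels = ch)
  expected <- truth0$truth[match(paste(d$wine, "Mn"),
                                 paste(truth0$wine, truth0$element))]
  expect_equal(d$conc, expected)
  expect_error(simulate_concentrations(truth0, eff, channels = ch), "seed")
})
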
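test_that("isotope-dilution parameters are validated and derive atomic weights", {
  p <- id_params(c_spike = 10000, m_spike = 0.1, m_sample = 10,
                 a63 = 0.01, a65 = 0.99)
  expect_equal(p$b63, 0.6915)
  expect_equal(p$b65, 0.3085)
  expect_equal(p$w_nat, 63.546, tolerance = 1e-4)
  expect_gt(p$w_spk, p$w_nat)  # enriched in the heavy isotope
  expect_error(id_params(1, 1, 1, a63 = 0.1, a65 = 0.8), "sum to 1")
  expect_error(id_params(1, 1, 1, a63 = 0.01, a65 = 0.99, b63 = 0.5,
                         b65 = 0.4), "sum to 1")
  expect_error(id_params(-1, 1, 1, a63 = 0.01, a65 = 0.99), "positive")
})

test_that("the mixing-equation boundary cases behave", {
  p <- id_params(c_spike = 10000, m_spike = 0.1, m_sample = 10,
                 a63 = 0.01, a65 = 0.99)
  # pure spike: no sample copper
  expect_equal(isotope_dilution_cu(p$a63 / p$a65, p), 0)
  # natural ratio: singular (sample indistinguishable from natural Cu)
  expect_error(isotope_dilution_cu(p$b63 / p$b65, p), "singular")
  expect_error(isotope_dilution_cu(-1, p), "positive")
  # outside the two-source interval: inconsistent measurement
  expect_warning(isotope_dilution_cu(3, p), "inconsistent")
  expect_warning(isotope_dilution_cu(1e-4, p), "inconsistent")
})

test_that("inversion recovers the sample content of the mole-balance oracle", {
  set.seed(101)
  for (i in 1:100) {
    c_sample <- 10^runif(1, 0, 3)
    c_spike <- 10^runif(1, 3, 5)
    m_sample <- runif(1, 5, 20)
    m_spike <- runif(1, 0.05, 0.5)
    a65 <- runif(1, 0.9, 0.999)
    a63 <- 1 - a65
    b63 <- runif(1, 0.6, 0.75)
    b65 <- 1 - b63
    R <- id_forward_ratio(c_sample, c_spike, m_sample, m_spike,
                          a63, a65, b63, b65)
    p <- id_params(c_spike, m_spike, m_sample, a63, a65, b63, b65)
    est <- isotope_dilution_cu(R, p)
    expect_lt(abs(est - c_sample) / c_sample, 1e-9)
  }
})

test_that("the estimate is strictly increasing in the response ratio", {
  p <- id_params(c_spike = 10000, m_spike = 0.1, m_sample = 10,
                 a63 = 0.01, a65 = 0.99)
  r <- seq(p$a63 / p$a65 + 1e-4, p$b63 / p$b65 - 1e-4, length.out = 200)
  est <- isotope_dilution_cu(r, p)
  expect_true(all(diff(est) > 0))
  expect_true(all(est >= 0))
})

test_that("isotope dilution agrees with external calibration when lossless", {
  cfg <- noise_free_config(seed = 1)
  tt <- generate_truth(seed = 1)
  ch <- tiny_channels("Cu")
  d <- batch_design(methods = c("DD", "MW"))
  rec <- simulate_batch(d, tt, cfg$effects, cfg$instrument, ch, cfg$spikes,
                        seed = 20)
  cur <- fit_calibration(rec)
  q <- quantify_external(rec, cur)
  ext <- q[q$role == "sample" & q$mass == 63, ]
  idt <- id_table(rec, cfg$spikes)
  m <- merge(idt, ext[, c("wine", "method", "replicate", "conc")],
             by = c("wine", "method", "replicate"))
  expect_lt(max(abs(m$conc_id - m$conc) / m$conc), 1e-3)
  expect_lt(max(abs(m$conc_id - m$conc) / m$conc), 1e-9)  # in fact exact
})

test_that("isotope dilution self-corrects a proportional filtration loss", {
  cfg <- noise_free_config(seed = 1)
  # retention 0.8 on both Cu isotopes of the wine-derived analyte
  cfg$effects$FA$retention <- data.frame(element = c("Cu", "Cu"),
                                         mass = c(63L, 65L),
                                         retention = c(0.8, 0.8))
  tt <- generate_truth(seed = 1)
  ch <- tiny_channels("Cu")
  d <- batch_design(methods = "FA")
  rec <- simulate_batch(d, tt, cfg$effects, cfg$instrument, ch, cfg$spikes,
                        seed = 21)
  idt <- id_table(rec, cfg$spikes)
  truth_cu <- tt$truth[match(paste(idt$wine, "Cu"),
                             paste(tt$wine, tt$element))]
  # the spike passes the filter, the wine analyte is retained at 0.8: the
  # ratio sees the retained fraction of the natural copper
  expect_equal(idt$conc_id, 0.8 * truth_cu, tolerance = 1e-9)
})

test_that("isotope dilution is more precise than external calibration under
          common-mode (drift-like) noise", {
  cfg <- default_config(seed = 1)
  tr <- data.frame(wine = "C", element = "Cu", truth = 200,
                   stringsAsFactors = FALSE)
  eff <- null_method_effects(cv = 0.15, cv_common_share = 0.95)
  d <- batch_design(wines = "C", methods = "DD", replicates = 12,
                    qc_every = 1000)
  ch <- tiny_channels("Cu")
  rec <- simulate_batch(d, tr, eff, cfg$instrument, ch, cfg$spikes, seed = 5)
  cur <- fit_calibration(rec)
  q <- quantify_external(rec, cur)
  ext <- q$conc[q$role == "sample" & q$mass == 63]
  idt <- id_table(rec, cfg$spikes)
  expect_lt(rsd(idt$conc_id), rsd(ext))
})
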
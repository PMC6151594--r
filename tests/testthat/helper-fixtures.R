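# Shared fixtures and independent oracles.

# channel subset with internal standards assigned
tiny_channels <- function(elements = c("Mn", "Cu")) {
  ch <- default_channels()
  assign_internal_standard(ch[ch$element %in% elements, , drop = FALSE])
}

# configuration with every stochastic component switched off
noise_free_config <- function(seed = 1) {
  cfg <- default_config(seed)
  cfg$effects <- noise_free_effects(cfg$effects)
  cfg$instrument <- noise_free_instrument(cfg$instrument)
  cfg
}

# independent mole-balance forward model: the 63/65 atom ratio of a spiked
# sample, computed from first principles (amounts in moles), never through
# the package's inversion formula
id_forward_ratio <- function(c_sample, c_spike, m_sample, m_spike,
                             a63, a65, b63, b65) {
  m63 <- 62.92960
  m65 <- 64.92779
  w_nat <- b63 * m63 + b65 * m65
  w_spk <- a63 * m63 + a65 * m65
  u_nat <- c_sample * m_sample / w_nat
  u_spk <- c_spike * m_spike / w_spk
  (u_nat * b63 + u_spk * a63) / (u_nat * b65 + u_spk * a65)
}

# brute-force main-effects sums of squares on a balanced design
balanced_ss <- function(d) {
  g <- mean(d$conc)
  ss_level <- function(f) {
    sum(tapply(d$conc, d[[f]], function(v) length(v) * (mean(v) - g)^2))
  }
  ss_tot <- sum((d$conc - g)^2)
  ss_s <- ss_level("wine")
  ss_r <- ss_level("replicate")
  ss_m <- ss_level("method")
  list(sample = ss_s, replicate = ss_r, method = ss_m,
       residual = ss_tot - ss_s - ss_r - ss_m, total = ss_tot)
}

# a small quantified long table: 4 wines x 4 methods x n reps, one channel,
# built from explicit cell means plus reproducible noise
toy_long <- function(means_by_method = c(DD = 10, FA = 10, AF = 10, MW = 10),
                     wine_shift = c(C = 0, PN = 2, S = 4, T = 6),
                     sd = 0.5, n_rep = 3, seed = 42,
                     element = "Mn", mass = 55L) {
  set.seed(seed)
  grid <- expand.grid(wine = names(wine_shift),
                      method = names(means_by_method),
                      replicate = seq_len(n_rep),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$element <- element
  grid$mass <- mass
  grid$conc <- means_by_method[grid$method] + wine_shift[grid$wine] +
    rnorm(nrow(grid), 0, sd)
  grid
}
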
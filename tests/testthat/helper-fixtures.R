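# Shared fixtures, built in code.

# Noiseless square wave alternating closed_level / open_level.
square_trace <- function(closed = 0, open = 10, dwell_s = 0.1, n_cycles = 5,
                         fs = 5000, noise_sd = 0, filter_hz = NA, seed = 1) {
  n_dwell <- round(dwell_s * fs)
  x <- rep(rep(c(closed, open), n_cycles), each = n_dwell)
  if (noise_sd > 0) {
    set.seed(seed)
    x <- x + rnorm(length(x), sd = noise_sd)
  }
  sc_trace(x, fs = fs, voltage = 100, genotype = "fixture",
           filter_hz = filter_hz)
}

known_baseline <- function(closed = 0, noise_sd = 0)
  baseline_estimate(closed, noise_sd)

# Simulate one trace plus generator truth for a slow two-state gate with a
# pinned-open flicker gate (unambiguous truth conducting fraction).
sim_slow_trace <- function(po, mean_open_s = 0.01, g = 174, voltage = 100,
                           duration = 20, noise_sd = 0.25, seed = 1) {
  kc <- 1 / mean_open_s
  ko <- kc * po / (1 - po)
  m <- gating_model("sim", g_true = g, slow_open_rate0 = ko,
                    slow_close_rate0 = kc)
  acq <- acquisition_config(noise_sd = noise_sd, duration = duration)
  dw <- sample_dwells(m, voltage, duration, seed = child_seed(seed, 1))
  tr <- render_trace(dw, m, voltage, acq, seed = child_seed(seed, 2))
  list(model = m, dwells = dw, trace = tr)
}
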
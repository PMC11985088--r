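test_that("baseline estimation is robust to open events", {
  set.seed(101)
  tr_noise <- sc_trace(rnorm(20000, 0, 1), fs = 5000, filter_hz = NA)
  b <- estimate_baseline(tr_noise)
  expect_lt(abs(b$closed_level), 0.05)
  expect_lt(abs(b$noise_sd - 1) / 1, 0.05)

  tr_const <- sc_trace(rep(0, 500), fs = 5000)
  b0 <- estimate_baseline(tr_const)
  expect_identical(b0$closed_level, 0)
  expect_identical(b0$noise_sd, 0)

  # 3% open time at +17.4 pA must not drag the mode off the baseline
  set.seed(102)
  x <- rnorm(20000, 0, 0.5)
  open_idx <- 1:600
  x[open_idx] <- x[open_idx] + 17.4
  b3 <- estimate_baseline(sc_trace(x, fs = 5000))
  expect_lt(abs(b3$closed_level), 0.1)

  expect_error(estimate_baseline(sc_trace(rnorm(50), fs = 5000)), "100 samples")
})

test_that("noiseless square waves are idealized exactly", {
  tr <- square_trace(dwell_s = 0.1, n_cycles = 5)      # 0 <-> 10 pA, fs 5 kHz
  ev <- hinkley_detect(tr, known_baseline(), detector_config())
  expect_identical(nrow(ev), 10L)
  expect_true(all(ev$state == rep(c("closed", "open"), 5)))
  # boundaries within one sample of the construction
  expect_true(all(abs(ev$start_s - seq(0, 0.9, by = 0.1)) <= 1 / tr$fs))
  expect_equal(open_probability(ev), 0.5)
  # conservation and alternation
  expect_equal(sum(ev$duration_s), attr(ev, "t_total"), tolerance = 1e-12)
  expect_true(all(rle(ev$state)$lengths == 1L))
})

test_that("a flat trace yields one closed event spanning the record", {
  tr <- sc_trace(rep(0, 5000), fs = 5000, filter_hz = 1000)
  expect_warning(ev <- hinkley_detect(tr), "detectability")
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$state, "closed")
  expect_equal(ev$duration_s, 1)
  expect_true(attr(ev, "undetectable"))
  expect_equal(open_probability(ev), 0)
})

test_that("traces shorter than the dead time are rejected", {
  tr <- sc_trace(c(0, 1), fs = 5000, filter_hz = 1000)
  expect_error(hinkley_detect(tr, known_baseline(),
                              detector_config(dead_time = 0.01)), "dead time")
})

test_that("open probability follows t_open / t_total", {
  tr <- square_trace(dwell_s = 0.05, n_cycles = 10)
  ev <- hinkley_detect(tr, known_baseline())
  expect_equal(open_probability(ev), 0.5)
  # manual table: 3.4 s open of 100 s
  ev2 <- structure(data.frame(state = c("closed", "open", "closed"),
                              start_s = c(0, 50, 53.4),
                              duration_s = c(50, 3.4, 46.6),
                              amplitude_pA = c(0, 10, 0)),
                   class = c("event_table", "data.frame"), t_total = 100)
  expect_equal(open_probability(ev2), 0.034)
  ev_empty <- structure(data.frame(), class = c("event_table", "data.frame"),
                        t_total = 10)
  expect_error(open_probability(ev_empty), "empty")
})

test_that("amplitudes come from edge-trimmed open plateaus", {
  tr <- square_trace(dwell_s = 0.1, n_cycles = 5)
  b <- known_baseline()
  ev <- hinkley_detect(tr, b)
  expect_equal(estimate_amplitude(tr, ev, b, detector_config(edge_margin = 0)), 10)
  expect_equal(estimate_amplitude(tr, ev, b, detector_config(edge_margin = 2)), 10)
  # no qualifying open events -> NA with warning, not zero
  ev_closed <- ev[ev$state == "closed", , drop = FALSE]
  attr(ev_closed, "t_total") <- attr(ev, "t_total")
  class(ev_closed) <- c("event_table", "data.frame")
  expect_warning(a <- estimate_amplitude(tr, ev_closed, b), "no open event")
  expect_true(is.na(a))
})

test_that("detected P_O tracks generator truth on a low-P_O simulated trace", {
  sim <- sim_slow_trace(po = 0.01, mean_open_s = 0.01, voltage = 100,
                        duration = 60, noise_sd = 1.74, seed = 7)  # SNR 10
  res <- idealize_trace(sim$trace)
  expect_lt(abs(res$po - sim$dwells$conducting_fraction) /
              sim$dwells$conducting_fraction, 0.15)
  expect_equal(res$i_meas, true_current(sim$model, 100), tolerance = 0.05)
})

test_that("P_O recovery holds across open probabilities and SNR (median of 10 seeds)", {
  cases <- expand.grid(po = c(0.005, 0.03, 0.1, 0.4), snr = c(5, 10))
  durations <- c(`0.005` = 60, `0.03` = 40, `0.1` = 20, `0.4` = 20)
  for (i in seq_len(nrow(cases))) {
    po <- cases$po[i]; snr <- cases$snr[i]
    rel_err <- vapply(1:10, function(s) {
      sim <- sim_slow_trace(po = po, mean_open_s = 0.01, voltage = 100,
                            duration = durations[[as.character(po)]],
                            noise_sd = 17.4 / snr, seed = 1000 * i + s)
      truth <- sim$dwells$conducting_fraction
      res <- suppressWarnings(idealize_trace(sim$trace))
      abs(res$po - truth) / truth
    }, numeric(1))
    expect_lt(median(rel_err), 0.15,
              label = sprintf("median P_O error at po=%g snr=%g", po, snr))
  }
})

test_that("raising the detection threshold never adds events", {
  sim <- sim_slow_trace(po = 0.1, mean_open_s = 0.01, duration = 20,
                        noise_sd = 2.2, seed = 42)
  b <- estimate_baseline(sim$trace)
  counts <- vapply(c(4, 6, 9, 12), function(lam) {
    ev <- suppressWarnings(
      hinkley_detect(sim$trace, b, detector_config(threshold_lambda = lam)))
    nrow(ev)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("flickery traces report the filtered (apparent) amplitude", {
  # slow bursts with flicker far above the cutoff: i_meas ~ i_true * p_fast
  m <- gating_model("flk", g_true = 174,
                    slow_open_rate0 = 3, slow_close_rate0 = 7,
                    fast_open_rate0 = 50000, fast_close_rate0 = 25000)
  acq <- acquisition_config(noise_sd = 0.25, duration = 30)
  dw <- sample_dwells(m, -160, 30, seed = 31)
  tr <- render_trace(dw, m, -160, acq, seed = 32)
  res <- idealize_trace(tr)
  expected <- true_current(m, -160) * 2 / 3
  expect_lt(abs(res$i_meas - expected) / abs(expected), 0.07)
})

test_that("idealized events conserve time and alternate on noisy traces", {
  sim <- sim_slow_trace(po = 0.1, mean_open_s = 0.02, duration = 10,
                        noise_sd = 1, seed = 5)
  ev <- suppressWarnings(hinkley_detect(sim$trace))
  expect_equal(sum(ev$duration_s), attr(ev, "t_total"), tolerance = 1e-9)
  expect_true(all(rle(ev$state)$lengths == 1L))
  expect_true(all(ev$duration_s > 0))
  po <- open_probability(ev)
  expect_gte(po, 0); expect_lte(po, 1)
})
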
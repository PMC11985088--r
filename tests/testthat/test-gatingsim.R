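test_that("dwell sampling reproduces stationary occupancies", {
  # symmetric slow gate: stationary conducting fraction 1/2
  m_sym <- gating_model("sym", g_true = 100,
                        slow_open_rate0 = 2, slow_close_rate0 = 2)
  cf <- vapply(1:20, function(s)
    sample_dwells(m_sym, 0, 100, seed = s)$conducting_fraction, numeric(1))
  se <- sd(cf) / sqrt(length(cf))
  expect_lt(abs(mean(cf) - 0.5), 3 * se)

  # asymmetric gate: k_open/(k_open + k_close) = 0.1
  m_asym <- gating_model("asym", g_true = 100,
                         slow_open_rate0 = 1, slow_close_rate0 = 9)
  cf <- vapply(1:50, function(s)
    sample_dwells(m_asym, 0, 500, seed = s)$conducting_fraction, numeric(1))
  se <- sd(cf) / sqrt(length(cf))
  expect_lt(abs(mean(cf) - 0.1), 3 * se)
})

test_that("absorbing gates give a single full-duration conducting interval", {
  m <- gating_model("pinned", g_true = 100,
                    slow_open_rate0 = 5, slow_close_rate0 = 0,
                    fast_open_rate0 = 5, fast_close_rate0 = 0)
  dw <- sample_dwells(m, 0, 12.5, seed = 3)
  expect_identical(length(dw$durations), 1L)
  expect_true(dw$conducting[1])
  expect_equal(dw$total_duration, 12.5)
  expect_equal(dw$conducting_fraction, 1)
})

test_that("dwell sequences conserve time, alternate, and are seed-deterministic", {
  m <- preset_wt()
  for (case in list(c(v = -160, seed = 11), c(v = 0, seed = 12),
                    c(v = 120, seed = 13))) {
    dw <- sample_dwells(m, case["v"], 5, seed = case["seed"])
    expect_equal(sum(dw$durations), 5, tolerance = 1e-9)
    expect_true(all(dw$durations > 0))
    # merged same-flag neighbours: flags strictly alternate
    expect_true(all(rle(dw$conducting)$lengths == 1L))
    dw2 <- sample_dwells(m, case["v"], 5, seed = case["seed"])
    expect_identical(dw, dw2)
  }
})

test_that("dwell sampling rejects bad durations and overflowing rates", {
  m <- preset_wt()
  expect_error(sample_dwells(m, 0, 0, seed = 1), "duration")
  hot <- gating_model("hot", g_true = 100, slow_open_rate0 = 1,
                      slow_close_rate0 = 1, slow_z_open = 5)
  expect_error(sample_dwells(hot, 200, 1, seed = 1), "slow_open_rate")
})

test_that("rendered traces carry the Ohmic open level and respect e_rev", {
  m <- gating_model("const", g_true = 174, slow_open_rate0 = 1,
                    slow_close_rate0 = 0)
  acq <- acquisition_config(noise_sd = 0, duration = 0.5)
  dw <- sample_dwells(m, 100, 0.5, seed = 1)
  tr <- render_trace(dw, m, 100, acq, seed = 1)
  # after filter settling, a permanently conducting channel sits at g*V/1000
  expect_equal(unique(round(tail(tr$current, 2000), 6)), 17.4)
  expect_identical(length(tr$current), 2500L)

  tr0 <- render_trace(dw, m, m$e_rev, acq, seed = 1)
  expect_true(all(tr0$current == 0))
})

test_that("sub-bandwidth flicker reduces the apparent level to its open fraction", {
  # flicker at 50 kHz rates against a 1 kHz filter: apparent plateau is
  # i_true * k_open / (k_open + k_close)
  m <- gating_model("flk", g_true = 174,
                    slow_open_rate0 = 1, slow_close_rate0 = 0,
                    fast_open_rate0 = 50000, fast_close_rate0 = 50000)
  acq <- acquisition_config(noise_sd = 0, duration = 2)
  dw <- sample_dwells(m, -160, 2, seed = 5)
  tr <- render_trace(dw, m, -160, acq, seed = 5)
  i_true <- true_current(m, -160)
  apparent <- mean(tail(tr$current, 9000))
  expect_lt(abs(apparent - 0.5 * i_true) / abs(0.5 * i_true), 0.05)
})

test_that("recordings produce one deterministic trace per protocol voltage", {
  m <- preset_wt()
  proto <- voltage_protocol(per_voltage_duration = 0.05)
  rec <- simulate_recording(m, proto, acquisition_config(), seed = 9)
  expect_identical(length(rec$traces), 17L)
  expect_identical(length(rec$dwells), 17L)
  expect_identical(names(rec$traces), as.character(seq(160, -160, by = -20)))
  rec2 <- simulate_recording(m, proto, acquisition_config(), seed = 9)
  expect_identical(rec$traces, rec2$traces)
})

test_that("slow-gate occupancy ratio between voltage extremes matches the configured 6.8-fold", {
  m <- preset_wt(flicker = FALSE)
  target <- stationary_slow_po(m, -160) / stationary_slow_po(m, 160)
  expect_equal(target, 6.8, tolerance = 0.01)
  ratios <- vapply(1:20, function(s) {
    lo <- sample_dwells(m, -160, 120, seed = child_seed(s, 1))$conducting_fraction
    hi <- sample_dwells(m, 160, 120, seed = child_seed(s, 2))$conducting_fraction
    lo / hi
  }, numeric(1))
  expect_lt(abs(mean(ratios) - target) / target, 0.20)
})

test_that("growth model: zero activity means no growth, activity raises fold change monotonically", {
  gm <- growth_model(baseline_rate = 0, noise_sd = 0)
  g0 <- simulate_growth(0, gm, genotype = "ev")
  expect_true(all(abs(g0$od600 / g0$od600[g0$time_h == 0][1] - 1) < 1e-12))

  folds <- vapply(c(0.05, 0.2, 1, 5, 50), function(a) {
    g <- simulate_growth(a, gm, genotype = "x", replicates = 1)
    g$od600[g$time_h == 48] / g$od600[g$time_h == 0]
  }, numeric(1))
  expect_true(all(diff(folds) > 0))
  # saturating activity approaches the carrying capacity at late times
  g_hi <- simulate_growth(1e4, gm, genotype = "hi", replicates = 1)
  expect_gt(g_hi$od600[g_hi$time_h == 72], 0.95 * gm$carrying_capacity)
})

test_that("noiseless growth equals the closed-form logistic", {
  gm <- growth_model(max_rate = 0.2, half_sat_activity = 1,
                     carrying_capacity = 2, od0 = 0.05, noise_sd = 0)
  a <- 3
  g <- simulate_growth(a, gm, genotype = "x", replicates = 1)
  # independent closed form: r from the Michaelis term, logistic in t
  r <- 0.2 * a / (a + 1)
  expected <- 2 / (1 + (2 / 0.05 - 1) * exp(-r * gm$sample_times))
  expect_equal(g$od600, expected, tolerance = 1e-12)
})

test_that("panels require a unique WT flag and rank growth by activity", {
  entries <- preset_panel()
  expect_identical(length(entries), 20L)
  no_wt <- lapply(entries, function(e) { e$wt <- FALSE; e })
  expect_error(make_panel(no_wt, render_traces = FALSE), "WT")

  pan <- make_panel(entries, growth = growth_model(noise_sd = 0), seed = 21,
                    render_traces = FALSE)
  expect_identical(nrow(pan$growth), 20L * 3L * 5L)
  expect_identical(pan$wt, "WT")
  fc <- fold_change(pan$growth, time = 48)
  fc <- fc[match(names(pan$activities), fc$genotype), ]
  expect_equal(cor(abs(pan$activities), fc$fold_change, method = "spearman"), 1)
})

test_that("panel recordings are emitted per genotype", {
  small <- preset_panel()[c(1, 3, 15)]
  small[[1]]$wt <- TRUE
  proto <- voltage_protocol(c(100, -140), per_voltage_duration = 0.2)
  pan <- make_panel(small, proto, acquisition_config(), seed = 2)
  expect_identical(names(pan$recordings), c("WT", "C", "R"))
  expect_identical(length(pan$recordings$WT$traces), 2L)
})
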
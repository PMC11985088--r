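#' Two-gate Markov gating model of a single channel
#'
#' Describes one channel as two independent two-state gates in series: a slow
#' gate that sets the burst structure (and hence the open probability measured
#' by idealization) and a fast "flicker" gate whose transitions can be faster
#' than the recording bandwidth, reducing the apparent open-channel amplitude
#' below the true one.  The channel conducts only when both gates are open.
#' Each rate follows a Boltzmann voltage dependence
#' \eqn{k(V) = k_0 \exp(z V F / RT)} with the temperature fixed at 25 °C.
#'
#' @param genotype label of the channel variant (e.g. `"WT"`).
#' @param g_true unitary conductance of the fully open channel (pS).
#' @param e_rev reversal potential (mV); 0 in symmetric 100 mM KCl.
#' @param slow_open_rate0,slow_close_rate0 slow-gate rates at 0 mV (1/s).
#' @param slow_z_open,slow_z_close effective gating charges of the slow gate.
#' @param fast_open_rate0,fast_close_rate0 flicker-gate rates at 0 mV (1/s).
#'   The default (`fast_close_rate0 = 0`) pins the flicker gate open.
#' @param fast_z_open,fast_z_close flicker-gate gating charges.
#' @return an object of class `gating_model`.
#' @examples
#' m <- gating_model("demo", g_true = 174, slow_open_rate0 = 1, slow_close_rate0 = 9)
#' stationary_po(m, -160)
#' @export
gating_model <- function(genotype, g_true, e_rev = 0,
                         slow_open_rate0, slow_close_rate0,
                         slow_z_open = 0, slow_z_close = 0,
                         fast_open_rate0 = 1, fast_close_rate0 = 0,
                         fast_z_open = 0, fast_z_close = 0) {
  stopifnot(is.character(genotype), length(genotype) == 1L)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    x
  }
  g_true <- num1(g_true, "g_true")
  if (g_true < 0) stop("g_true must be >= 0", call. = FALSE)
  for (nm in c("slow_open_rate0", "slow_close_rate0",
               "fast_open_rate0", "fast_close_rate0")) {
    v <- num1(get(nm), nm)
    if (v < 0) stop(sprintf("rate constant '%s' must be >= 0", nm), call. = FALSE)
  }
  if (slow_open_rate0 + slow_close_rate0 <= 0)
    stop("slow gate needs at least one positive rate", call. = FALSE)
  if (fast_open_rate0 + fast_close_rate0 <= 0)
    stop("fast gate needs at least one positive rate", call. = FALSE)
  structure(list(
    genotype = genotype, g_true = g_true, e_rev = num1(e_rev, "e_rev"),
    slow_open_rate0 = slow_open_rate0, slow_close_rate0 = slow_close_rate0,
    slow_z_open = num1(slow_z_open, "slow_z_open"),
    slow_z_close = num1(slow_z_close, "slow_z_close"),
    fast_open_rate0 = fast_open_rate0, fast_close_rate0 = fast_close_rate0,
    fast_z_open = num1(fast_z_open, "fast_z_open"),
    fast_z_close = num1(fast_z_close, "fast_z_close")
  ), class = "gating_model")
}

#' @export
print.gating_model <- function(x, ...) {
  cat(sprintf("<gating_model %s>  g_true = %.4g pS, e_rev = %g mV\n",
              x$genotype, x$g_true, x$e_rev))
  cat(sprintf("  slow gate: ko0 = %.4g, kc0 = %.4g 1/s, z = (%.3g, %.3g)\n",
              x$slow_open_rate0, x$slow_close_rate0, x$slow_z_open, x$slow_z_close))
  cat(sprintf("  fast gate: ko0 = %.4g, kc0 = %.4g 1/s, z = (%.3g, %.3g)\n",
              x$fast_open_rate0, x$fast_close_rate0, x$fast_z_open, x$fast_z_close))
  invisible(x)
}

# Voltage-dependent rate pair of one gate; errors name the offending rate on
# overflow at extreme voltages.
gate_rates <- function(k0_open, k0_close, z_open, z_close, voltage, gate) {
  voltage <- as.numeric(voltage)[1]
  ko <- unname(k0_open * exp(z_open * voltage / THERMAL_MV))
  kc <- unname(k0_close * exp(z_close * voltage / THERMAL_MV))
  for (v in list(c("open", ko), c("close", kc))) {
    k <- as.numeric(v[2L])
    if (!is.finite(k) || k > RATE_CAP)
      stop(sprintf("%s_%s_rate overflows (%.3g 1/s) at %g mV",
                   gate, v[1L], k, voltage), call. = FALSE)
  }
  c(open = ko, close = kc)
}

#' Stationary conducting probability and true current
#'
#' `stationary_po()` returns the product of the stationary open probabilities
#' of the slow and fast gates at a voltage, i.e. the fraction of time the
#' channel conducts at stationarity.  `stationary_slow_po()` returns the slow
#' gate's term alone, which is what burst-level idealization measures when
#' flicker is faster than the filter.  `true_current()` is the Ohmic current
#' of the fully open channel, \eqn{i = g (V - E_{rev}) / 1000} (pA for g in pS
#' and V in mV), and `channel_activity()` the time-averaged current
#' \eqn{i_{true}(V) \cdot P_O(V)}.
#'
#' @param model a [gating_model()].
#' @param voltage holding voltage (mV).
#' @return a single number.
#' @export
stationary_po <- function(model, voltage) {
  stationary_slow_po(model, voltage) * stationary_fast_po(model, voltage)
}

#' @rdname stationary_po
#' @export
stationary_slow_po <- function(model, voltage) {
  k <- gate_rates(model$slow_open_rate0, model$slow_close_rate0,
                  model$slow_z_open, model$slow_z_close, voltage, "slow")
  unname(k["open"] / sum(k))
}

#' @rdname stationary_po
#' @export
stationary_fast_po <- function(model, voltage) {
  k <- gate_rates(model$fast_open_rate0, model$fast_close_rate0,
                  model$fast_z_open, model$fast_z_close, voltage, "fast")
  unname(k["open"] / sum(k))
}

#' @rdname stationary_po
#' @export
true_current <- function(model, voltage) {
  model$g_true * (voltage - model$e_rev) / 1000
}

#' @rdname stationary_po
#' @export
channel_activity <- function(model, voltage = -140) {
  true_current(model, voltage) * stationary_po(model, voltage)
}

#' Acquisition settings of the recording chain
#'
#' Defaults mirror a standard bilayer setup: 5 kHz sampling after a 1 kHz
#' 4-pole Bessel low-pass.  Synthesis happens at `fs * oversample_factor`
#' so that flicker faster than the filter shapes the apparent amplitude the
#' way an analog filter acting before digitization would.
#'
#' @param fs sampling rate (Hz).
#' @param filter_cutoff low-pass −3 dB cutoff (Hz); must be below `fs/2`.
#' @param filter_order number of filter poles.
#' @param noise_sd Gaussian current noise (pA), quoted at the output rate.
#' @param oversample_factor internal synthesis rate multiplier (>= 1).
#' @param duration per-voltage record length (s).
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(fs = 5000, filter_cutoff = 1000,
                               filter_order = 4, noise_sd = 0.25,
                               oversample_factor = 10, duration = 30) {
  stopifnot(fs > 0, filter_cutoff > 0, filter_cutoff < fs / 2,
            filter_order >= 1, noise_sd >= 0, oversample_factor >= 1,
            duration > 0)
  structure(list(fs = fs, filter_cutoff = filter_cutoff,
                 filter_order = as.integer(filter_order), noise_sd = noise_sd,
                 oversample_factor = as.integer(round(oversample_factor)),
                 duration = duration),
            class = "acquisition_config")
}

#' Voltage-step protocol
#'
#' @param voltages ordered holding voltages (mV); default +160 to −160 mV in
#'   −20 mV steps.
#' @param per_voltage_duration record length per voltage (s).
#' @return an object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(voltages = seq(160, -160, by = -20),
                             per_voltage_duration = 30) {
  stopifnot(length(voltages) >= 1, !anyDuplicated(voltages),
            all(is.finite(voltages)), per_voltage_duration > 0)
  structure(list(voltages = as.numeric(voltages),
                 per_voltage_duration = per_voltage_duration),
            class = "voltage_protocol")
}

# --- dwell-time sampling -----------------------------------------------------

# One alternating-exponential two-state gate over [0, duration].  The initial
# state is drawn from the stationary distribution; a zero close (open) rate
# pins the gate once it is open (closed).  Returns alternating states/durations.
sample_gate <- function(ko, kc, duration) {
  p_open <- ko / (ko + kc)
  state0 <- runif(1) < p_open
  # absorbing once entered?
  if ((state0 && kc <= 0) || (!state0 && ko <= 0))
    return(list(states = state0, durations = duration))
  mean_cycle <- (if (ko > 0) 1 / ko else 0) + (if (kc > 0) 1 / kc else 0)
  n <- max(32, ceiling(2.4 * duration / mean_cycle) + 32)
  repeat {
    half <- ceiling(n / 2) + 1L
    d_open <- rexp(half, rate = kc)
    d_closed <- rexp(half, rate = ko)
    d <- numeric(2L * half)
    if (state0) {
      d[seq(1L, 2L * half, 2L)] <- d_open
      d[seq(2L, 2L * half, 2L)] <- d_closed
    } else {
      d[seq(1L, 2L * half, 2L)] <- d_closed
      d[seq(2L, 2L * half, 2L)] <- d_open
    }
    cs <- cumsum(d)
    if (cs[length(cs)] >= duration) {
      k <- which(cs >= duration)[1L]
      d <- d[seq_len(k)]
      d[k] <- duration - (cs[k] - d[k])
      states <- rep(c(state0, !state0), length.out = k)
      # guard against a zero-length truncated tail
      keep <- d > 0
      return(list(states = states[keep], durations = d[keep]))
    }
    n <- n * 2L
  }
}

#' Sample a conducting/non-conducting dwell sequence
#'
#' Overlays the slow and fast gates of `model` at one voltage: each gate is an
#' independent alternating-exponential process started from its stationary
#' distribution, and the channel conducts iff both gates are open.
#'
#' @param model a [gating_model()].
#' @param voltage holding voltage (mV).
#' @param duration record length (s).
#' @param seed integer seed; identical seeds give identical sequences.
#' @return an object of class `dwell_sequence`: alternating intervals with
#'   `conducting` flags, `durations` (s), `total_duration`, and the empirical
#'   `conducting_fraction` (the generator truth used to validate detectors).
#' @export
sample_dwells <- function(model, voltage, duration, seed = NULL) {
  stopifnot(inherits(model, "gating_model"))
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0)
    stop("duration must be a single positive number", call. = FALSE)
  ks <- gate_rates(model$slow_open_rate0, model$slow_close_rate0,
                   model$slow_z_open, model$slow_z_close, voltage, "slow")
  kf <- gate_rates(model$fast_open_rate0, model$fast_close_rate0,
                   model$fast_z_open, model$fast_z_close, voltage, "fast")
  with_seed(seed, {
    slow <- sample_gate(ks["open"], ks["close"], duration)
    fast <- sample_gate(kf["open"], kf["close"], duration)
    ends_s <- cumsum(slow$durations)
    ends_f <- cumsum(fast$durations)
    # union of breakpoints; interval i is (b[i], b[i+1]]
    b <- sort(unique(c(0, ends_s, ends_f, duration)))
    b <- b[b <= duration]
    starts <- b[-length(b)]
    durs <- diff(b)
    # state of each gate on every sub-interval (intervals are right-open in
    # start, so look up by interval start)
    is_s <- findInterval(starts, c(0, ends_s), rightmost.closed = FALSE)
    is_f <- findInterval(starts, c(0, ends_f), rightmost.closed = FALSE)
    cond <- slow$states[pmin(is_s, length(slow$states))] &
      fast$states[pmin(is_f, length(fast$states))]
    r <- rle(cond)
    durations <- as.numeric(tapply(durs, rep(seq_along(r$lengths), r$lengths), sum))
    conducting <- r$values
    structure(list(conducting = conducting, durations = durations,
                   total_duration = duration,
                   conducting_fraction =
                     sum(durations[conducting]) / duration,
                   voltage = voltage, genotype = model$genotype),
              class = "dwell_sequence")
  })
}

#' @export
print.dwell_sequence <- function(x, ...) {
  cat(sprintf("<dwell_sequence> %d intervals over %.6g s, conducting fraction %.4g\n",
              length(x$durations), x$total_duration, x$conducting_fraction))
  invisible(x)
}

#' @export
as.data.frame.dwell_sequence <- function(x, ...) {
  data.frame(conducting = x$conducting,
             start_s = cumsum(c(0, x$durations[-length(x$durations)])),
             duration_s = x$durations)
}

# --- trace container ---------------------------------------------------------

#' Construct a single-channel current trace
#'
#' @param current current samples (pA).
#' @param fs sampling rate (Hz).
#' @param voltage holding voltage (mV).
#' @param genotype channel variant label.
#' @param filter_hz low-pass cutoff the record was filtered with (Hz); used to
#'   derive detector dead time and amplitude edge margins.
#' @param ... further metadata stored alongside.
#' @return an object of class `sc_trace`.
#' @export
sc_trace <- function(current, fs, voltage = NA_real_, genotype = NA_character_,
                     filter_hz = NA_real_, ...) {
  stopifnot(is.numeric(current), length(current) >= 2L, fs > 0)
  if (!all(is.finite(current))) stop("trace samples must be finite", call. = FALSE)
  structure(list(current = as.numeric(current), fs = fs, voltage = voltage,
                 genotype = genotype, filter_hz = filter_hz,
                 meta = list(...)),
            class = "sc_trace")
}

#' @export
print.sc_trace <- function(x, ...) {
  cat(sprintf("<sc_trace %s @ %g mV>  %d samples at %g Hz (%.6g s), filter %g Hz\n",
              x$genotype, x$voltage, length(x$current), x$fs,
              length(x$current) / x$fs, x$filter_hz))
  invisible(x)
}

#' Trace sample times
#' @param trace an [sc_trace()].
#' @return time of each sample (s), starting at 0.
#' @export
trace_time <- function(trace) (seq_along(trace$current) - 1) / trace$fs

#' Render a dwell sequence into a filtered, sampled current trace
#'
#' Synthesizes the two-level current at `fs * oversample_factor` (conducting
#' level \eqn{i_{true}(V)}, zero otherwise), adds Gaussian noise of sd
#' `noise_sd * sqrt(oversample_factor)` at the oversampled rate, applies the
#' causal Bessel low-pass, and decimates to `fs`.  Because filtering happens
#' before decimation, flicker faster than the cutoff reduces the apparent
#' open-level amplitude exactly as in an analog acquisition chain.
#'
#' @param dwells a [sample_dwells()] result.
#' @param model the [gating_model()] that produced it.
#' @param voltage holding voltage (mV).
#' @param acq an [acquisition_config()].
#' @param seed integer seed for the noise stream.
#' @return an [sc_trace()].
#' @export
render_trace <- function(dwells, model, voltage, acq, seed = NULL) {
  stopifnot(inherits(dwells, "dwell_sequence"), inherits(model, "gating_model"),
            inherits(acq, "acquisition_config"))
  if (dwells$total_duration < 1 / acq$fs)
    stop("dwell sequence shorter than one sample period", call. = FALSE)
  os <- acq$oversample_factor
  fs_os <- acq$fs * os
  if (acq$filter_cutoff >= fs_os / 2)
    stop("filter cutoff at or above Nyquist of the oversampled rate",
         call. = FALSE)
  n_out <- floor(dwells$total_duration * acq$fs)
  n_os <- n_out * os
  t_os <- (seq_len(n_os) - 0.5) / fs_os
  ends <- cumsum(dwells$durations)
  idx <- findInterval(t_os, c(0, ends), rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(dwells$conducting))
  i_true <- true_current(model, voltage)
  x <- ifelse(dwells$conducting[idx], i_true, 0)
  with_seed(seed, {
    if (acq$noise_sd > 0)
      x <- x + rnorm(n_os, sd = acq$noise_sd * sqrt(os))
    y <- bessel_lowpass(x, fs_os, acq$filter_cutoff, acq$filter_order)
    sc_trace(y[seq(os, n_os, by = os)], fs = acq$fs, voltage = voltage,
             genotype = model$genotype, filter_hz = acq$filter_cutoff,
             filter_order = acq$filter_order, noise_sd = acq$noise_sd)
  })
}

#' Simulate a full voltage-protocol recording
#'
#' One trace per protocol voltage, each with its own deterministic child seed
#' (see [child_seed()]); the generating dwell sequences are retained as ground
#' truth for detector validation.
#'
#' @param model a [gating_model()].
#' @param protocol a [voltage_protocol()].
#' @param acq an [acquisition_config()]; its `duration` is overridden by the
#'   protocol's `per_voltage_duration`.
#' @param seed integer master seed.
#' @return a list of class `sc_recording` with elements `traces` and `dwells`
#'   (both named by voltage), plus `model` and `seed`.
#' @export
simulate_recording <- function(model, protocol = voltage_protocol(),
                               acq = acquisition_config(), seed = 1) {
  stopifnot(inherits(protocol, "voltage_protocol"))
  vs <- protocol$voltages
  traces <- vector("list", length(vs))
  dwells <- vector("list", length(vs))
  for (i in seq_along(vs)) {
    sd_i <- child_seed(seed, 2L * i - 1L)
    sn_i <- child_seed(seed, 2L * i)
    dw <- sample_dwells(model, vs[i], protocol$per_voltage_duration, seed = sd_i)
    traces[[i]] <- render_trace(dw, model, vs[i], acq, seed = sn_i)
    dwells[[i]] <- dw
  }
  names(traces) <- names(dwells) <- as.character(vs)
  structure(list(traces = traces, dwells = dwells, model = model, seed = seed),
            class = "sc_recording")
}

# --- growth model ------------------------------------------------------------

#' Activity-driven yeast growth model
#'
#' OD600 time courses follow logistic growth whose rate saturates with the
#' channel's time-averaged current ("activity") scaled by a hidden per-genotype
#' expression factor:
#' \deqn{r = r_0 + (r_{max} - r_0) \frac{A}{A + K_A},\qquad A = f_{expr} |activity|.}
#'
#' @param od0 OD600 at inoculation.
#' @param baseline_rate growth rate with zero channel activity (1/h).
#' @param max_rate rate at saturating activity (1/h).
#' @param half_sat_activity |time-averaged current| at half-maximal rate (pA).
#' @param carrying_capacity OD600 ceiling of the logistic.
#' @param expression_factor hidden multiplier on activity (>= 0).
#' @param noise_sd sd of multiplicative log-normal OD noise.
#' @param sample_times measurement times (h).
#' @return an object of class `growth_model`.
#' @export
growth_model <- function(od0 = 0.1, baseline_rate = 0, max_rate = 0.12,
                         half_sat_activity = 2, carrying_capacity = 1.0,
                         expression_factor = 1, noise_sd = 0.05,
                         sample_times = c(0, 6, 24, 48, 72)) {
  stopifnot(od0 > 0, baseline_rate >= 0, max_rate >= 0, half_sat_activity > 0,
            carrying_capacity > od0, expression_factor >= 0, noise_sd >= 0,
            all(sample_times >= 0))
  structure(list(od0 = od0, baseline_rate = baseline_rate, max_rate = max_rate,
                 half_sat_activity = half_sat_activity,
                 carrying_capacity = carrying_capacity,
                 expression_factor = expression_factor, noise_sd = noise_sd,
                 sample_times = sort(unique(sample_times))),
            class = "growth_model")
}

# Closed-form logistic OD at time t (h) for effective rate r.
logistic_od <- function(t, r, od0, K) K / (1 + (K / od0 - 1) * exp(-r * t))

#' Simulate OD600 growth records for one genotype
#'
#' @param activity the channel's time-averaged current at the physiological
#'   voltage (pA); only its absolute value matters.
#' @param model a [growth_model()].
#' @param seed integer seed.
#' @param genotype label attached to the records.
#' @param replicates number of independent cultures.
#' @return a data.frame with columns `genotype`, `replicate`, `time_h`,
#'   `od600` (one row per replicate and sample time).
#' @export
simulate_growth <- function(activity, model = growth_model(), seed = NULL,
                            genotype = "NA", replicates = 3) {
  stopifnot(inherits(model, "growth_model"), is.finite(activity),
            replicates >= 1)
  A <- model$expression_factor * abs(activity)
  r <- model$baseline_rate +
    (model$max_rate - model$baseline_rate) * A / (A + model$half_sat_activity)
  tt <- model$sample_times
  od_det <- logistic_od(tt, r, model$od0, model$carrying_capacity)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(replicates), function(rep) {
      noise <- if (model$noise_sd > 0) exp(rnorm(length(tt), sd = model$noise_sd)) else 1
      data.frame(genotype = genotype, replicate = rep, time_h = tt,
                 od600 = od_det * noise)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a full mutant panel: recordings plus growth table
#'
#' @param panel list of entries `list(model = <gating_model>,
#'   expression_factor = 1, wt = FALSE)`; exactly one entry must have
#'   `wt = TRUE`.
#' @param protocol a [voltage_protocol()].
#' @param acq an [acquisition_config()].
#' @param growth a [growth_model()]; its `expression_factor` is replaced
#'   per genotype.
#' @param seed master seed.
#' @param render_traces if `FALSE`, skip trace synthesis and return only dwell
#'   truth and growth records (fast, e.g. for growth-model studies).
#' @param growth_voltage voltage (mV) at which channel activity drives growth.
#' @return list of class `sc_panel` with `recordings` (named by genotype, each
#'   a [simulate_recording()] result or truth-only list), `growth` (one
#'   GrowthRecord data.frame), `activities` (true per-channel time-averaged
#'   currents), and `wt` (the reference genotype label).
#' @export
make_panel <- function(panel, protocol = voltage_protocol(),
                       acq = acquisition_config(), growth = growth_model(),
                       seed = 1, render_traces = TRUE, growth_voltage = -140) {
  stopifnot(is.list(panel), length(panel) >= 1)
  wt_flags <- vapply(panel, function(e) isTRUE(e$wt), logical(1))
  if (sum(wt_flags) != 1L)
    stop("panel must flag exactly one WT reference entry", call. = FALSE)
  labels <- vapply(panel, function(e) e$model$genotype, character(1))
  if (anyDuplicated(labels)) stop("duplicate genotype labels in panel", call. = FALSE)
  recordings <- vector("list", length(panel))
  growth_rows <- vector("list", length(panel))
  activities <- numeric(length(panel))
  for (i in seq_along(panel)) {
    e <- panel[[i]]
    stopifnot(inherits(e$model, "gating_model"))
    gseed <- child_seed(seed, 100000L + i)
    if (render_traces) {
      recordings[[i]] <- simulate_recording(e$model, protocol, acq,
                                            seed = child_seed(seed, i * 1000L))
    } else {
      recordings[[i]] <- list(model = e$model)
    }
    activities[i] <- channel_activity(e$model, growth_voltage)
    gm <- growth
    gm$expression_factor <- e$expression_factor %||% 1
    growth_rows[[i]] <- simulate_growth(activities[i], gm, seed = gseed,
                                        genotype = labels[i])
  }
  names(recordings) <- labels
  structure(list(recordings = recordings,
                 growth = do.call(rbind, growth_rows),
                 activities = setNames(activities, labels),
                 wt = labels[wt_flags]),
            class = "sc_panel")
}
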
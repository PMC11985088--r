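#' Baseline description of a trace
#'
#' @param closed_level closed-channel (baseline) current level (pA).
#' @param noise_sd Gaussian noise sd of the trace (pA).
#' @return an object of class `baseline_estimate`.
#' @export
baseline_estimate <- function(closed_level, noise_sd) {
  stopifnot(is.finite(closed_level), is.finite(noise_sd), noise_sd >= 0)
  structure(list(closed_level = closed_level, noise_sd = noise_sd),
            class = "baseline_estimate")
}

#' Robust baseline (closed level) and noise estimation
#'
#' The closed level is taken as the mode of the sample amplitude distribution
#' (kernel density peak): the channels analysed here spend most of their time
#' closed, so the dominant mode is the baseline even when open events are
#' present.  The noise sd is the median absolute deviation of the first
#' differences divided by \eqn{\sqrt 2}, rescaled to a Gaussian sd — first
#' differencing removes the two-level structure, and the MAD ignores the
#' transition samples.
#'
#' @param trace an [sc_trace()].
#' @return an object of class `baseline_estimate` with fields `closed_level`
#'   and `noise_sd` (both pA).
#' @export
estimate_baseline <- function(trace) {
  stopifnot(inherits(trace, "sc_trace"))
  x <- trace$current
  if (length(x) < 100L)
    stop("trace too short (< 100 samples) for a reliable baseline estimate",
         call. = FALSE)
  if (max(x) == min(x)) return(baseline_estimate(x[1], 0))
  noise <- mad(diff(x)) / sqrt(2)
  d <- density(x, n = 512)
  mode0 <- d$x[which.max(d$y)]
  # refine the coarse density mode by averaging the samples in a
  # noise-scaled window around it; open-level samples stay excluded as long
  # as the level separation exceeds the window
  if (noise > 0) {
    near <- x[abs(x - mode0) < 2.5 * noise]
    if (length(near) >= 100L) mode0 <- mean(near)
  }
  baseline_estimate(mode0, noise)
}

#' @export
print.baseline_estimate <- function(x, ...) {
  cat(sprintf("<baseline_estimate> closed = %.4g pA, noise sd = %.4g pA\n",
              x$closed_level, x$noise_sd))
  invisible(x)
}

#' Hinkley detector settings
#'
#' @param order detector order p: the order-1 statistic is a clipped cumulative
#'   sum toward the alternative level and each higher order accumulates the
#'   previous one, boosting sensitivity to brief events.
#' @param threshold_lambda detection threshold in units of the trace noise sd.
#' @param open_level_hint known open-channel level (pA), or `NULL` to estimate
#'   it from the trace.
#' @param dead_time minimum resolvable event (s); defaults to
#'   `0.4 / filter_hz` of the trace — events shorter than the filter rise time
#'   are unresolvable and get merged into their neighbours.
#' @param edge_margin samples excluded around each transition when estimating
#'   amplitudes; defaults to `ceiling(2 * fs / filter_hz)`.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(order = 4, threshold_lambda = 6,
                            open_level_hint = NULL, dead_time = NULL,
                            edge_margin = NULL) {
  stopifnot(order >= 1, threshold_lambda > 0,
            is.null(dead_time) || dead_time >= 0,
            is.null(edge_margin) || edge_margin >= 0)
  structure(list(order = as.integer(order), threshold_lambda = threshold_lambda,
                 open_level_hint = open_level_hint, dead_time = dead_time,
                 edge_margin = edge_margin),
            class = "detector_config")
}

# Resolve trace-dependent defaults.
resolve_detector <- function(config, trace) {
  fh <- trace$filter_hz
  if (is.null(config$dead_time))
    config$dead_time <- if (is.finite(fh)) 0.4 / fh else 0
  if (is.null(config$edge_margin))
    config$edge_margin <- if (is.finite(fh)) ceiling(2 * trace$fs / fh) else 2L
  config
}

# Firing threshold of the order-p statistic: noise-free value reached d_star
# samples after a true jump, with d_star the smallest dwell whose integrated
# evidence exceeds lambda noise sds, d* = max(1, ceil((2 lambda sigma_n)^2)).
hohd_threshold <- function(order, lambda, sigma_norm) {
  d_star <- max(1, ceiling((2 * lambda * sigma_norm)^2))
  0.5 * choose(d_star + order - 1, order)
}

# Initial open-level guess: extreme of a short running mean, i.e. the largest
# sustained excursion from baseline at roughly the filter timescale.
initial_open_level <- function(trace, closed) {
  w <- if (is.finite(trace$filter_hz))
    max(3L, round(trace$fs / trace$filter_hz)) else 5L
  x <- trace$current
  cs <- cumsum(c(0, x))
  n <- length(x)
  if (n <= w) return(mean(x))
  sm <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  sm[which.max(abs(sm - closed))]
}

# Merge events shorter than dead_n samples into their neighbours, preserving
# alternation; returns integer vector of event start indices plus states.
merge_dead_time <- function(starts, states, n_total, dead_n) {
  repeat {
    durs <- diff(c(starts, n_total))
    if (length(starts) <= 1L) break
    short <- which(durs < dead_n)
    short <- setdiff(short, integer(0))
    if (!length(short)) break
    i <- short[which.min(durs[short])]
    if (i == 1L) {
      # absorb into the following event, which then starts where this one did
      starts[2L] <- starts[1L]
      starts <- starts[-1L]
      states <- states[-1L]
    } else if (i == length(starts)) {
      starts <- starts[-i]
      states <- states[-i]
    } else {
      # neighbours share a state; drop event i and the following boundary
      starts <- starts[-c(i, i + 1L)]
      states <- states[-c(i, i + 1L)]
    }
  }
  list(starts = starts, states = states)
}

#' Two-level trace idealization with a higher-order Hinkley jump detector
#'
#' Idealizes a trace between the closed level and an open level (given as a
#' hint or estimated adaptively from detected open segments in a second pass).
#' Jumps are detected with an order-p Hinkley cumulative statistic; jump times
#' are placed at the most recent zero of the order-1 statistic; events shorter
#' than the dead time are merged into their neighbours.
#'
#' If the level separation is below detectability (less than
#' `threshold_lambda` times the estimated trace noise), the whole record is
#' returned as a single closed event carrying attribute `undetectable = TRUE`,
#' with a warning.
#'
#' @param trace an [sc_trace()].
#' @param baseline a [estimate_baseline()] result, or `NULL` to estimate.
#' @param config a [detector_config()].
#' @return an event table: data.frame with columns `state` ("closed"/"open"),
#'   `start_s`, `duration_s`, `amplitude_pA` (per-event mean minus closed
#'   level; `NA` for events too short to average), of class `event_table` with
#'   attributes `t_total`, `fs`, `closed_level`, `open_level`, `undetectable`.
#' @export
hinkley_detect <- function(trace, baseline = NULL, config = detector_config()) {
  stopifnot(inherits(trace, "sc_trace"), inherits(config, "detector_config"))
  if (is.null(baseline)) baseline <- estimate_baseline(trace)
  config <- resolve_detector(config, trace)
  x <- trace$current
  n <- length(x)
  t_total <- n / trace$fs
  if (t_total < config$dead_time)
    stop("trace shorter than the detector dead time", call. = FALSE)
  closed <- baseline$closed_level
  sigma <- baseline$noise_sd
  open0 <- config$open_level_hint %||% initial_open_level(trace, closed)

  undetectable <- function() {
    warning("open/closed separation below detectability; returning a single closed event",
            call. = FALSE)
    ev <- data.frame(state = "closed", start_s = 0, duration_s = t_total,
                     amplitude_pA = mean(x) - closed)
    structure(ev, class = c("event_table", "data.frame"), t_total = t_total,
              fs = trace$fs, closed_level = closed, open_level = NA_real_,
              config = config, undetectable = TRUE)
  }
  sep <- abs(open0 - closed)
  if (sep == 0 || (sigma > 0 && sep <= config$threshold_lambda * sigma))
    return(undetectable())

  detect_pass <- function(open_level) {
    sigma_norm <- if (sigma > 0) sigma / abs(open_level - closed) else 0
    h <- hohd_threshold(config$order, config$threshold_lambda, sigma_norm)
    trans <- hohd_core(x, closed, open_level, config$order, h)
    starts <- c(0L, as.integer(trans))
    states <- rep(c(FALSE, TRUE), length.out = length(starts)) # FALSE = closed
    # zero-length events (e.g. a trace that starts open) yield duplicated
    # start indices; keep the later state at each index
    keep <- c(diff(starts) > 0, TRUE)
    merged <- merge_dead_time(starts[keep], states[keep], n,
                              dead_n = config$dead_time * trace$fs)
    merged
  }

  pass1 <- detect_pass(open0)
  # adaptive open-level re-estimate from accepted open segments (edge-trimmed)
  open1 <- reestimate_open_level(x, pass1, n, closed, config$edge_margin)
  final <- if (is.finite(open1) &&
               abs(open1 - closed) > (if (sigma > 0) config$threshold_lambda * sigma else 0)) {
    detect_pass(open1)
  } else pass1
  open_used <- if (is.finite(open1)) open1 else open0

  starts <- final$starts
  states <- final$states
  durs_n <- diff(c(starts, n))
  amp <- vapply(seq_along(starts), function(i) {
    i0 <- starts[i] + 1L
    i1 <- starts[i] + durs_n[i]
    mean(x[i0:i1]) - closed
  }, numeric(1))
  ev <- data.frame(state = ifelse(states, "open", "closed"),
                   start_s = starts / trace$fs,
                   duration_s = durs_n / trace$fs,
                   amplitude_pA = amp)
  structure(ev, class = c("event_table", "data.frame"), t_total = t_total,
            fs = trace$fs, closed_level = closed, open_level = open_used,
            config = config, undetectable = FALSE)
}

# Duration-weighted mean open level over detected open segments, excluding
# edge_margin samples at each boundary; NA if no segment is long enough.
reestimate_open_level <- function(x, pass, n, closed, edge_margin) {
  starts <- pass$starts
  states <- pass$states
  if (!any(states)) return(NA_real_)
  durs <- diff(c(starts, n))
  tot <- 0; wsum <- 0
  for (i in which(states)) {
    i0 <- starts[i] + 1L + edge_margin
    i1 <- starts[i] + durs[i] - edge_margin
    if (i1 >= i0) {
      m <- mean(x[i0:i1])
      w <- i1 - i0 + 1
      wsum <- wsum + w * m
      tot <- tot + w
    }
  }
  if (tot == 0) {
    # fall back to untrimmed means of all open segments
    op <- which(states)
    m <- vapply(op, function(i) mean(x[(starts[i] + 1L):(starts[i] + durs[i])]),
                numeric(1))
    return(sum(m * durs[op]) / sum(durs[op]))
  }
  wsum / tot
}

#' Open probability from an event table
#'
#' \eqn{P_O = t_{open} / t_{total}}: the summed open dwell times divided by
#' the total record time.
#'
#' @param events an [hinkley_detect()] event table.
#' @return open probability in \[0, 1\].
#' @export
open_probability <- function(events) {
  stopifnot(inherits(events, "event_table"))
  if (nrow(events) == 0L) stop("empty event table", call. = FALSE)
  t_total <- attr(events, "t_total")
  if (!is.numeric(t_total) || t_total <= 0)
    stop("event table has no positive t_total", call. = FALSE)
  po <- sum(events$duration_s[events$state == "open"]) / t_total
  min(max(po, 0), 1)
}

#' Measured open-channel amplitude from idealized events
#'
#' The duration-weighted mean of per-open-event sample means, excluding
#' `edge_margin` samples at each event boundary (filter-smeared transition
#' samples), minus the closed level.  The sign is preserved: negative at
#' negative voltages.  Flicker is deliberately not deconvolved — this is the
#' "measured" amplitude the recording instrumentation provides, which at
#' strongly hyperpolarized voltages lies below the true open-channel current.
#'
#' @param trace the [sc_trace()] the events came from.
#' @param events the [hinkley_detect()] event table.
#' @param baseline the [estimate_baseline()] used (or `NULL` to re-estimate).
#' @param config the [detector_config()] (for `edge_margin`).
#' @return the measured amplitude `i_meas` (pA), or `NA` with a warning when
#'   no open event is long enough to average.
#' @export
estimate_amplitude <- function(trace, events, baseline = NULL,
                               config = detector_config()) {
  stopifnot(inherits(trace, "sc_trace"), inherits(events, "event_table"))
  if (is.null(baseline)) baseline <- estimate_baseline(trace)
  config <- resolve_detector(config, trace)
  m <- config$edge_margin
  fs <- trace$fs
  x <- trace$current
  op <- events[events$state == "open", , drop = FALSE]
  if (nrow(op)) {
    i0 <- round(op$start_s * fs) + 1L + m
    i1 <- round((op$start_s + op$duration_s) * fs) - m
    ok <- i1 >= i0  # event strictly longer than 2 * edge_margin samples
    op <- op[ok, , drop = FALSE]; i0 <- i0[ok]; i1 <- i1[ok]
  }
  if (!nrow(op)) {
    warning("no open event long enough for amplitude estimation; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  w <- i1 - i0 + 1L
  means <- mapply(function(a, b) mean(x[a:b]), i0, i1)
  sum(means * w) / sum(w) - baseline$closed_level
}

#' Idealize one trace end to end
#'
#' Convenience wrapper: baseline estimation, Hinkley detection, open
#' probability and measured amplitude in one call.
#'
#' @inheritParams hinkley_detect
#' @return list with `events`, `baseline`, `po`, `i_meas`.
#' @export
idealize_trace <- function(trace, config = detector_config(), baseline = NULL) {
  if (is.null(baseline)) baseline <- estimate_baseline(trace)
  events <- hinkley_detect(trace, baseline, config)
  po <- open_probability(events)
  i_meas <- if (any(events$state == "open"))
    suppressWarnings(estimate_amplitude(trace, events, baseline, config))
  else NA_real_
  list(events = events, baseline = baseline, po = po, i_meas = i_meas)
}
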
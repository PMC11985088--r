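#' Assemble per-voltage i/V and P_O/V relations
#'
#' Aggregates per-recording results (one row per independent recording and
#' voltage) into mean, sample sd (n−1 denominator) and n per voltage.  Missing
#' amplitudes are excluded from the i/V relation but their open probabilities
#' are retained.  With a single recording at a voltage the sd is undefined and
#' reported as `NA`.
#'
#' @param results data.frame with columns `voltage`, `i_meas`, `po` (one row
#'   per recording).
#' @return list with elements `iv` and `pov`, data.frames of class
#'   `iv_relation` / `po_relation` with columns `voltage`, `mean`, `sd`, `n`.
#' @export
build_relations <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("voltage", "i_meas", "po") %in% names(results)))
  if (nrow(results) == 0L) stop("empty input", call. = FALSE)
  if (any(results$po < 0 | results$po > 1, na.rm = TRUE))
    stop("open probabilities must lie in [0, 1]", call. = FALSE)
  agg <- function(v, x) {
    ok <- is.finite(x)
    v <- v[ok]; x <- x[ok]
    if (!length(v)) return(NULL)
    out <- do.call(rbind, lapply(split(x, v), function(z)
      data.frame(mean = mean(z), sd = if (length(z) > 1) sd(z) else NA_real_,
                 n = length(z))))
    out$voltage <- as.numeric(rownames(out))
    rownames(out) <- NULL
    out[order(-out$voltage), c("voltage", "mean", "sd", "n")]
  }
  iv <- agg(results$voltage, results$i_meas)
  pov <- agg(results$voltage, results$po)
  if (is.null(pov)) stop("no finite open probabilities", call. = FALSE)
  list(iv = structure(iv, class = c("iv_relation", "data.frame")),
       pov = structure(pov, class = c("po_relation", "data.frame")))
}

#' Unitary conductance from the i/V relation
#'
#' Ordinary least-squares line (free intercept) through the per-voltage mean
#' currents over the inclusive fit range; the unitary conductance is the slope
#' converted to pS (pA/mV × 1000).  The default range 0 to +100 mV restricts
#' the fit to the voltages where the channel is fully resolved.
#'
#' @param iv an `iv_relation` from [build_relations()].
#' @param v_lo,v_hi inclusive fit range (mV).
#' @return object of class `conductance_fit`: list with `g_pS`,
#'   `intercept_pA`, `v_lo`, `v_hi`, `n`.
#' @export
fit_conductance <- function(iv, v_lo = 0, v_hi = 100) {
  stopifnot(inherits(iv, "iv_relation") || is.data.frame(iv))
  sel <- iv$voltage >= v_lo & iv$voltage <= v_hi & is.finite(iv$mean)
  if (sum(sel) < 2L)
    stop(sprintf("need >= 2 i/V points in [%g, %g] mV (have %d)",
                 v_lo, v_hi, sum(sel)), call. = FALSE)
  fit <- lm(mean ~ voltage, data = iv[sel, , drop = FALSE])
  structure(list(g_pS = unname(coef(fit)[2]) * 1000,
                 intercept_pA = unname(coef(fit)[1]),
                 v_lo = v_lo, v_hi = v_hi, n = sum(sel)),
            class = "conductance_fit")
}

#' @export
print.conductance_fit <- function(x, ...) {
  cat(sprintf("<conductance_fit> g = %.4g pS over [%g, %g] mV (%d points), intercept %.4g pA\n",
              x$g_pS, x$v_lo, x$v_hi, x$n, x$intercept_pA))
  invisible(x)
}

#' Extrapolated true open-channel current
#'
#' Evaluates the positive-limb linear i/V fit at voltage `v`, approximating
#' the full open-channel amplitude where flicker gating hides it from direct
#' measurement (symmetric-KCl extrapolation).
#'
#' @inheritParams fit_conductance
#' @param v voltage at which to evaluate the fitted line (mV).
#' @return `i_true(v)` in pA.
#' @export
true_current_at <- function(iv, v = -140, v_lo = 0, v_hi = 100) {
  fit <- fit_conductance(iv, v_lo, v_hi)
  fit$g_pS / 1000 * v + fit$intercept_pA
}

#' Time-averaged current ("activity")
#'
#' @param i single-channel current (pA); sign preserved.
#' @param po open probability in \[0, 1\].
#' @param absolute return `|i * po|` (used for plotting/classification where
#'   currents are expressed as absolute numbers).
#' @return the product `i * po` (pA).
#' @export
activity <- function(i, po, absolute = FALSE) {
  if (any(!is.finite(po)) || any(po < 0 | po > 1))
    stop("po must lie in [0, 1]", call. = FALSE)
  out <- i * po
  if (absolute) abs(out) else out
}

#' Global mean open probability across the voltage window
#'
#' Unweighted arithmetic mean of the per-voltage mean open probabilities over
#' the protocol window (recording durations differ between voltages, so no
#' duration weighting is attempted).
#'
#' @param pov a `po_relation` from [build_relations()].
#' @return mean P_O.
#' @export
mean_po <- function(pov) {
  stopifnot(is.data.frame(pov), nrow(pov) >= 1)
  mean(pov$mean)
}

#' Open probability at one protocol voltage (exact lookup)
#'
#' Values at the physiological voltage are read directly from the P_O/V
#' relation; a voltage absent from the protocol is an error — never silently
#' interpolated.
#'
#' @param pov a `po_relation`.
#' @param v voltage (mV); must be present in the relation.
#' @return mean P_O at `v`.
#' @export
po_at <- function(pov, v) {
  i <- which(abs(pov$voltage - v) < 1e-9)
  if (length(i) != 1L)
    stop(sprintf("voltage %g mV not in the P_O/V relation; no interpolation is performed", v),
         call. = FALSE)
  pov$mean[i]
}

# i/V counterpart of po_at (internal).
iv_at <- function(iv, v) {
  i <- which(abs(iv$voltage - v) < 1e-9)
  if (length(i) != 1L || !is.finite(iv$mean[i])) return(NA_real_)
  iv$mean[i]
}

#' Per-genotype functional channel summary
#'
#' Assembles the standard set of functional parameters: unitary conductance
#' (positive-limb fit), global mean P_O, the −140 mV values read from the
#' relations, the extrapolated true current, and the time-averaged current
#' products used for growth correlation.
#'
#' @param genotype label.
#' @param iv,pov relations from [build_relations()].
#' @param v_lo,v_hi conductance fit range (mV).
#' @param activity_voltage physiological voltage (mV) for the activity
#'   products.
#' @return one-row data.frame with columns `genotype`, `g_pS`, `fit_lo`,
#'   `fit_hi`, `mean_po`, `po_m140`, `i_meas_m140_pA`, `i_true_m140_pA`,
#'   `activity_meas_pA`, `activity_true_pA`, `activity_p140_pA`, `n`.
#'   Fields that cannot be computed (insufficient points, voltage missing from
#'   the protocol) are `NA` with a warning.
#' @export
channel_summary <- function(genotype, iv, pov, v_lo = 0, v_hi = 100,
                            activity_voltage = -140) {
  g <- NA_real_; icept <- NA_real_
  fit <- tryCatch(fit_conductance(iv, v_lo, v_hi), error = function(e) {
    warning(sprintf("%s: %s", genotype, conditionMessage(e)), call. = FALSE)
    NULL
  })
  if (!is.null(fit)) { g <- fit$g_pS; icept <- fit$intercept_pA }
  va <- activity_voltage
  po_v <- tryCatch(po_at(pov, va), error = function(e) {
    warning(sprintf("%s: %s", genotype, conditionMessage(e)), call. = FALSE)
    NA_real_
  })
  i_meas_v <- iv_at(iv, va)
  i_true_v <- if (!is.null(fit)) g / 1000 * va + icept else NA_real_
  po_pos <- tryCatch(po_at(pov, -va), error = function(e) NA_real_)
  i_true_pos <- if (!is.null(fit)) g / 1000 * (-va) + icept else NA_real_
  data.frame(
    genotype = genotype, g_pS = g, fit_lo = v_lo, fit_hi = v_hi,
    mean_po = mean_po(pov), po_m140 = po_v,
    i_meas_m140_pA = i_meas_v, i_true_m140_pA = i_true_v,
    activity_meas_pA = if (is.finite(i_meas_v) && is.finite(po_v))
      activity(i_meas_v, po_v) else NA_real_,
    activity_true_pA = if (is.finite(i_true_v) && is.finite(po_v))
      activity(i_true_v, po_v) else NA_real_,
    activity_p140_pA = if (is.finite(i_true_pos) && is.finite(po_pos))
      activity(i_true_pos, po_pos) else NA_real_,
    n = max(pov$n))
}

#' Summarize one simulated or measured recording set
#'
#' Runs idealization over every trace of a recording, builds the relations and
#' returns the per-genotype [channel_summary()] row plus the relations.
#'
#' @param recording an `sc_recording` from [simulate_recording()], or a list
#'   of [sc_trace()] objects.
#' @param config a [detector_config()].
#' @param v_lo,v_hi conductance fit range (mV).
#' @param activity_voltage physiological voltage (mV).
#' @return list with `summary` (one-row data.frame), `iv`, `pov`,
#'   `per_voltage` (the raw per-trace results).
#' @export
summarize_recording <- function(recording, config = detector_config(),
                                v_lo = 0, v_hi = 100, activity_voltage = -140) {
  traces <- if (inherits(recording, "sc_recording")) recording$traces
            else recording
  stopifnot(length(traces) >= 1)
  rows <- lapply(traces, function(tr) {
    res <- suppressWarnings(idealize_trace(tr, config))
    data.frame(voltage = tr$voltage, i_meas = res$i_meas, po = res$po)
  })
  per_voltage <- do.call(rbind, rows)
  rownames(per_voltage) <- NULL
  rel <- build_relations(per_voltage)
  genotype <- traces[[1]]$genotype
  summ <- channel_summary(genotype, rel$iv, rel$pov, v_lo, v_hi,
                          activity_voltage)
  list(summary = summ, iv = rel$iv, pov = rel$pov, per_voltage = per_voltage)
}
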
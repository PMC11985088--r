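#' OD600 fold changes over inoculation
#'
#' Per replicate, the fold change is od(t) divided by the replicate's od at
#' time 0; mean and sample sd are then taken across replicates.
#'
#' @param table growth data.frame with columns `genotype`, `replicate`,
#'   `time_h`, `od600`.
#' @param genotype restrict to one genotype (`NULL`: all).
#' @param time restrict to one timepoint in hours (`NULL`: all non-zero
#'   times).
#' @return data.frame with columns `genotype`, `time_h`, `fold_change`
#'   (mean across replicates), `sd`, `n`.
#' @export
fold_change <- function(table, genotype = NULL, time = NULL) {
  stopifnot(is.data.frame(table),
            all(c("genotype", "replicate", "time_h", "od600") %in% names(table)))
  if (any(table$od600 <= 0)) stop("od600 values must be positive", call. = FALSE)
  if (!is.null(genotype)) table <- table[table$genotype %in% genotype, , drop = FALSE]
  if (nrow(table) == 0L) stop("no growth rows selected", call. = FALSE)
  key <- interaction(table$genotype, table$replicate, drop = TRUE)
  fc_rows <- lapply(split(table, key), function(d) {
    i0 <- which(d$time_h == 0)
    if (length(i0) != 1L)
      stop(sprintf("replicate %s of genotype %s has no unique time-0 entry",
                   d$replicate[1], d$genotype[1]), call. = FALSE)
    data.frame(genotype = d$genotype, replicate = d$replicate,
               time_h = d$time_h, fold = d$od600 / d$od600[i0])
  })
  fc <- do.call(rbind, fc_rows)
  if (!is.null(time)) fc <- fc[fc$time_h %in% time, , drop = FALSE]
  else fc <- fc[fc$time_h > 0, , drop = FALSE]
  if (nrow(fc) == 0L) stop("no rows at the requested timepoint", call. = FALSE)
  out <- do.call(rbind, lapply(split(fc, interaction(fc$genotype, fc$time_h, drop = TRUE)),
    function(d) data.frame(genotype = d$genotype[1], time_h = d$time_h[1],
                           fold_change = mean(d$fold),
                           sd = if (nrow(d) > 1) sd(d$fold) else NA_real_,
                           n = nrow(d))))
  rownames(out) <- NULL
  out[order(out$genotype, out$time_h), , drop = FALSE]
}

# Per-replicate fold changes at one timepoint (vector), used for t-tests.
replicate_folds <- function(table, genotype, time) {
  d <- table[table$genotype == genotype, , drop = FALSE]
  if (nrow(d) == 0L) stop(sprintf("genotype %s absent from growth table", genotype),
                          call. = FALSE)
  vapply(split(d, d$replicate), function(r) {
    i0 <- which(r$time_h == 0)
    it <- which(r$time_h == time)
    if (length(i0) != 1L || length(it) != 1L)
      stop(sprintf("replicate %s of %s lacks time 0 or %g h", r$replicate[1],
                   genotype, time), call. = FALSE)
    r$od600[it] / r$od600[i0]
  }, numeric(1))
}

#' Two-sample Student's t-test of mutant vs WT fold changes
#'
#' Classical two-tailed unpaired t-test; equal variances assumed by default
#' (Welch's correction available via `welch = TRUE`).  Significance is called
#' at p < 0.05.
#'
#' @param mutant,wt numeric vectors of per-replicate fold changes (>= 2 each).
#' @param welch use the Welch (unequal-variance) statistic.
#' @return list with `t`, `df`, `p`, `significant`.
#' @export
ttest_vs_wt <- function(mutant, wt, welch = FALSE) {
  if (length(mutant) < 2L || length(wt) < 2L)
    stop("need >= 2 replicates per group", call. = FALSE)
  if (sd(mutant) == 0 && sd(wt) == 0 && mean(mutant) == mean(wt))
    return(list(t = 0, df = length(mutant) + length(wt) - 2, p = 1,
                significant = FALSE))
  tt <- stats::t.test(mutant, wt, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, significant = tt$p.value < 0.05)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return correlation coefficient r.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in x or y; correlation undefined", call. = FALSE)
  stats::cor(x, y)
}

#' WT-anchored quadrant classification of mutants
#'
#' Each mutant's channel feature (taken as an absolute value when the feature
#' is a current) and its growth fold change are compared with the WT values;
#' the two strict comparisons define quadrants.  A mutant is `concordant` when
#' feature and growth fall on the same side of the WT point, `discordant`
#' otherwise; exact ties with WT are excluded with a warning (the WT itself is
#' never classified).
#'
#' @param features data.frame with columns `genotype` and the feature column.
#' @param growth a [fold_change()] summary at a single timepoint.
#' @param wt the WT reference label.
#' @param feature name of the feature column in `features` (e.g.
#'   `"activity_meas_pA"`, `"po_m140"`, `"i_meas_m140_pA"`).
#' @param feature_is_current take `abs()` of the feature before comparison.
#' @return data.frame of class `classification_outcome` with columns
#'   `genotype`, `feature_value`, `growth_value`, `feature_relation`,
#'   `growth_relation`, `call`; attribute `counts` holds the
#'   concordant/discordant/tie tallies.
#' @export
classify_vs_wt <- function(features, growth, wt, feature = "activity_meas_pA",
                           feature_is_current = TRUE) {
  stopifnot(is.data.frame(features), "genotype" %in% names(features),
            feature %in% names(features),
            is.data.frame(growth), all(c("genotype", "fold_change") %in% names(growth)))
  if (length(unique(growth$time_h)) > 1L)
    stop("growth summary spans several timepoints; pick one", call. = FALSE)
  if (!(wt %in% features$genotype) || !(wt %in% growth$genotype))
    stop(sprintf("WT reference '%s' missing from features or growth", wt),
         call. = FALSE)
  fv <- setNames(features[[feature]], features$genotype)
  if (feature_is_current) fv <- abs(fv)
  gv <- setNames(growth$fold_change, growth$genotype)
  muts <- setdiff(intersect(names(fv), names(gv)), wt)
  rel <- function(x, ref) {
    ifelse(!is.finite(x), NA_character_,
           ifelse(x > ref, "above_wt", ifelse(x < ref, "below_wt", "tie")))
  }
  fr <- rel(fv[muts], fv[[wt]])
  gr <- rel(gv[muts], gv[[wt]])
  call <- ifelse(is.na(fr) | is.na(gr), NA_character_,
                 ifelse(fr == "tie" | gr == "tie", "tie-excluded",
                        ifelse(fr == gr, "concordant", "discordant")))
  if (any(call == "tie-excluded", na.rm = TRUE))
    warning("ties with the WT reference excluded from classification",
            call. = FALSE)
  out <- data.frame(genotype = muts, feature_value = unname(fv[muts]),
                    growth_value = unname(gv[muts]),
                    feature_relation = unname(fr), growth_relation = unname(gr),
                    call = unname(call))
  counts <- c(concordant = sum(call == "concordant", na.rm = TRUE),
              discordant = sum(call == "discordant", na.rm = TRUE),
              tie_excluded = sum(call == "tie-excluded", na.rm = TRUE),
              missing = sum(is.na(call)))
  structure(out, class = c("classification_outcome", "data.frame"),
            counts = counts, feature = feature, wt = wt)
}

#' Multilinear model of growth on current, open probability and their product
#'
#' Ordinary least squares (with intercept) of the growth readout on the
#' single-channel current, the open probability, and their product;
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}.
#'
#' @param growth response vector (e.g. OD600 fold changes).
#' @param i single-channel currents (pA).
#' @param po open probabilities.
#' @return list of class `multilinear_fit` with `coefficients` (intercept,
#'   beta_i, beta_po, beta_product), `r_squared`, `n`.
#' @export
multilinear_r2 <- function(growth, i, po) {
  if (!(length(growth) == length(i) && length(i) == length(po)))
    stop("growth, i and po must have equal length", call. = FALSE)
  ok <- is.finite(growth) & is.finite(i) & is.finite(po)
  growth <- growth[ok]; i <- i[ok]; po <- po[ok]
  n <- length(growth)
  if (n < 5L) stop("need >= 5 complete observations", call. = FALSE)
  X <- cbind(intercept = 1, i = i, po = po, product = i * po)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design: regressor(s) %s collinear",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  fit <- lm(growth ~ i + po + I(i * po))
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((growth - mean(growth))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  structure(list(coefficients = setNames(unname(coef(fit)),
                                         c("intercept", "beta_i", "beta_po",
                                           "beta_product")),
                 r_squared = max(0, min(1, r2)), n = n),
            class = "multilinear_fit")
}

#' @export
print.multilinear_fit <- function(x, ...) {
  cat(sprintf("<multilinear_fit> R^2 = %.4g on n = %d\n", x$r_squared, x$n))
  print(round(x$coefficients, 6))
  invisible(x)
}
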
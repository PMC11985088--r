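#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates simulate (or ingest) → idealize → summarize → growth analysis
#' and writes the per-genotype summary, fold-change, classification and report
#' files.  Configuration is a JSON file or an equivalent nested list; every
#' default that is applied (fit range, timepoint, feature) is logged.
#'
#' Configuration keys (all optional unless noted):
#' \describe{
#'   \item{panel}{`"default"` (the built-in 20-genotype panel) or a list of
#'     entries with fields `genotype`, `g_true`, `po_n160`, `dz`,
#'     `expression_factor`, `wt`.}
#'   \item{protocol}{`voltages` (mV), `per_voltage_duration` (s).}
#'   \item{acquisition}{arguments of [acquisition_config()].}
#'   \item{detector}{arguments of [detector_config()].}
#'   \item{fit}{`v_lo`, `v_hi` (mV).}
#'   \item{growth}{arguments of [growth_model()], plus `file` (a growth CSV to
#'     read instead of simulating), `timepoint` (h) and `feature` (one of
#'     `activity_meas`, `activity_true`, `po`, `i_meas`, `activity_p140`).}
#'   \item{seed}{integer master seed.}
#' }
#'
#' @param config path to a JSON config file, or a nested list.
#' @param seed overrides the config's master seed.
#' @param out_dir output directory (created if needed); `NULL` writes nothing.
#' @param quiet suppress per-stage log messages.
#' @return list with `summaries`, `fold_changes`, `classification`,
#'   `correlation`, `multilinear`, `files`, invisibly.
#' @export
run_pipeline <- function(config = list(), seed = NULL, out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  }
  stopifnot(is.list(config))
  log <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  seed <- seed %||% config$seed %||% 1L
  fit_lo <- config$fit$v_lo %||% 0
  fit_hi <- config$fit$v_hi %||% 100
  timepoint <- config$growth$timepoint %||% 48
  feature <- config$growth$feature %||% "activity_meas"
  feature_col <- switch(feature,
    activity_meas = "activity_meas_pA", activity_true = "activity_true_pA",
    po = "po_m140", i_meas = "i_meas_m140_pA",
    activity_p140 = "activity_p140_pA",
    stop(sprintf("unknown feature '%s'", feature), call. = FALSE))
  log("settings: seed %d, fit range [%g, %g] mV, timepoint %g h, feature %s",
      seed, fit_lo, fit_hi, timepoint, feature)

  panel <- build_config_panel(config$panel)
  proto_cfg <- config$protocol %||% list()
  protocol <- voltage_protocol(
    voltages = proto_cfg$voltages %||% seq(160, -160, by = -20),
    per_voltage_duration = proto_cfg$per_voltage_duration %||% 30)
  acq <- do.call(acquisition_config, config$acquisition %||% list())
  det <- do.call(detector_config, config$detector %||% list())
  gm_args <- config$growth %||% list()
  gm_args <- gm_args[setdiff(names(gm_args), c("file", "timepoint", "feature"))]
  gmod <- do.call(growth_model, gm_args)

  log("simulating %d genotypes x %d voltages (%g s each)", length(panel),
      length(protocol$voltages), protocol$per_voltage_duration)
  pan <- make_panel(panel, protocol, acq, gmod, seed = seed)

  summaries <- vector("list", length(pan$recordings))
  n_events <- 0L
  for (i in seq_along(pan$recordings)) {
    res <- summarize_recording(pan$recordings[[i]], det, fit_lo, fit_hi)
    summaries[[i]] <- res$summary
    n_events <- n_events + sum(vapply(
      pan$recordings[[i]]$traces, function(tr) 1L, integer(1)))
  }
  summaries <- do.call(rbind, summaries)
  log("idealized %d traces; %d genotype summaries", n_events, nrow(summaries))

  growth_tab <- if (!is.null(config$growth$file)) {
    if (!file.exists(config$growth$file))
      stop(sprintf("growth stage: file not found: %s", config$growth$file),
           call. = FALSE)
    read_growth(config$growth$file)
  } else pan$growth
  fc <- fold_change(growth_tab)
  fc_t <- fc[fc$time_h == timepoint, , drop = FALSE]
  if (nrow(fc_t) == 0L)
    stop(sprintf("growth stage: no fold changes at timepoint %g h", timepoint),
         call. = FALSE)
  log("growth: %d genotypes at %g h", nrow(fc_t), timepoint)

  cls <- suppressWarnings(classify_vs_wt(
    summaries, fc_t, wt = pan$wt, feature = feature_col,
    feature_is_current = feature != "po"))
  merged <- merge(summaries, fc_t, by = "genotype")
  fv <- if (feature == "po") merged[[feature_col]] else abs(merged[[feature_col]])
  corr <- tryCatch(pearson_r(fv, merged$fold_change), error = function(e) NA_real_)
  ml <- tryCatch(multilinear_r2(merged$fold_change, merged$i_meas_m140_pA,
                                merged$po_m140),
                 error = function(e) NULL)
  counts <- attr(cls, "counts")
  log("classification vs %s on %s: %d concordant, %d discordant, %d excluded",
      pan$wt, feature, counts["concordant"], counts["discordant"],
      counts["tie_excluded"] + counts["missing"])

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f_sum <- file.path(out_dir, "channel_summary.tsv")
    write_summary(summaries, f_sum)
    f_fc <- file.path(out_dir, "growth_foldchange.tsv")
    out_fc <- fc
    out_fc[c("fold_change", "sd")] <- lapply(out_fc[c("fold_change", "sd")], fmt_num)
    write.table(out_fc, f_fc, sep = "\t", quote = FALSE, row.names = FALSE)
    f_cls <- file.path(out_dir, "classification.tsv")
    out_cls <- as.data.frame(cls)
    out_cls[c("feature_value", "growth_value")] <-
      lapply(out_cls[c("feature_value", "growth_value")], fmt_num)
    write.table(out_cls, f_cls, sep = "\t", quote = FALSE, row.names = FALSE)
    f_rep <- file.path(out_dir, "report.json")
    jsonlite::write_json(list(
      seed = seed, wt = pan$wt, feature = feature, timepoint_h = timepoint,
      fit_range_mV = c(fit_lo, fit_hi),
      n_genotypes = nrow(summaries),
      concordant = unname(counts["concordant"]),
      discordant = unname(counts["discordant"]),
      tie_excluded = unname(counts["tie_excluded"] + counts["missing"]),
      pearson_r = corr,
      multilinear_r2 = if (!is.null(ml)) ml$r_squared else NA
    ), f_rep, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(f_sum, f_fc, f_cls, f_rep)
    log("wrote %s", paste(basename(files), collapse = ", "))
  }
  invisible(list(summaries = summaries, fold_changes = fc,
                 classification = cls, correlation = corr, multilinear = ml,
                 files = files))
}

# Panel from a config entry: "default", NULL, or a list of entry descriptors.
build_config_panel <- function(entries) {
  if (is.null(entries) || identical(entries, "default")) return(preset_panel())
  stopifnot(is.list(entries), length(entries) >= 1)
  lapply(entries, function(e) {
    stopifnot(!is.null(e$genotype), !is.null(e$g_true))
    list(model = build_preset(e$genotype, e$g_true,
                              e$po_n160 %||% 0.034, e$dz %||% 0.156278,
                              flicker = e$flicker %||% TRUE),
         expression_factor = e$expression_factor %||% 1,
         wt = isTRUE(e$wt))
  })
}
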
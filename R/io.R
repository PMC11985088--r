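# Plain-text formats.  All writers use period decimal separators, fixed
# column order and no timestamps, so identical inputs produce byte-identical
# files.

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

write_meta <- function(con, meta) {
  for (k in names(meta))
    if (!is.null(meta[[k]]) && !is.na(meta[[k]]))
      writeLines(sprintf("# %s: %s", k, format(meta[[k]], trim = TRUE)), con)
}

read_meta <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  out <- list()
  for (m in kv) if (length(m) == 3L) out[[trimws(m[2])]] <- trimws(m[3])
  out
}

#' Write / read a single-channel trace as TSV
#'
#' Format: `#`-prefixed metadata header (keys `genotype`, `voltage_mV`,
#' `fs_hz`, `filter_hz`), a column header line, then two tab-separated columns
#' `time_s` and `current_pA` at 6 significant digits.
#'
#' @param trace an [sc_trace()].
#' @param path file path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns an
#'   [sc_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sc_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, list(genotype = trace$genotype, voltage_mV = trace$voltage,
                       fs_hz = trace$fs, filter_hz = trace$filter_hz))
  writeLines("time_s\tcurrent_pA", con)
  writeLines(paste(fmt_num(trace_time(trace), 9), fmt_num(trace$current),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("trace file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  meta <- read_meta(lines)
  if (is.null(meta$fs_hz))
    stop(sprintf("%s: required metadata key 'fs_hz' missing", path),
         call. = FALSE)
  fs <- as.numeric(meta$fs_hz)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2L) stop(sprintf("%s: no data rows", path), call. = FALSE)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!all(c("time_s", "current_pA") %in% header))
    stop(sprintf("%s: expected columns time_s, current_pA", path), call. = FALSE)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  mat <- suppressWarnings(vapply(rows, function(r) as.numeric(r[1:2]), numeric(2)))
  bad <- which(!is.finite(mat[1, ]) | !is.finite(mat[2, ]))
  if (length(bad))
    stop(sprintf("%s: non-numeric cell on data line %d", path, bad[1]),
         call. = FALSE)
  tt <- mat[1, ]; cur <- mat[2, ]
  if (any(diff(tt) <= 0))
    stop(sprintf("%s: time column not strictly increasing", path), call. = FALSE)
  dt <- median(diff(tt))
  if (abs(dt - 1 / fs) / (1 / fs) > 0.001)
    warning(sprintf("%s: median time step %.6g s disagrees with fs_hz %g by > 0.1%%",
                    path, dt, fs), call. = FALSE)
  sc_trace(cur, fs = fs,
           voltage = if (!is.null(meta$voltage_mV)) as.numeric(meta$voltage_mV) else NA_real_,
           genotype = meta$genotype %||% NA_character_,
           filter_hz = if (!is.null(meta$filter_hz)) as.numeric(meta$filter_hz) else NA_real_,
           source = path)
}

#' Write / read an idealized event table as TSV
#'
#' Columns `event_index`, `state`, `start_s`, `duration_s`, `amplitude_pA`
#' after a `#` metadata header carrying genotype, voltage and detector
#' settings.
#'
#' @param events an event table from [hinkley_detect()].
#' @param path file path.
#' @param genotype,voltage optional metadata overrides.
#' @return `write_events()` returns `path` invisibly; `read_events()` an
#'   `event_table`.
#' @export
write_events <- function(events, path, genotype = NA, voltage = NA) {
  stopifnot(inherits(events, "event_table"))
  cfg <- attr(events, "config")
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, list(genotype = genotype, voltage_mV = voltage,
                       t_total_s = attr(events, "t_total"),
                       fs_hz = attr(events, "fs"),
                       closed_level_pA = attr(events, "closed_level"),
                       open_level_pA = attr(events, "open_level"),
                       detector_order = cfg$order,
                       threshold_lambda = cfg$threshold_lambda,
                       dead_time_s = cfg$dead_time))
  writeLines("event_index\tstate\tstart_s\tduration_s\tamplitude_pA", con)
  writeLines(paste(seq_len(nrow(events)), events$state,
                   fmt_num(events$start_s, 9), fmt_num(events$duration_s, 9),
                   fmt_num(events$amplitude_pA), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop(sprintf("event file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  meta <- read_meta(lines)
  body <- lines[!grepl("^#", lines)]
  dat <- read.table(text = body, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  ev <- data.frame(state = dat$state, start_s = dat$start_s,
                   duration_s = dat$duration_s,
                   amplitude_pA = dat$amplitude_pA)
  structure(ev, class = c("event_table", "data.frame"),
            t_total = as.numeric(meta$t_total_s %||% sum(ev$duration_s)),
            fs = as.numeric(meta$fs_hz %||% NA),
            closed_level = as.numeric(meta$closed_level_pA %||% NA),
            open_level = as.numeric(meta$open_level_pA %||% NA),
            undetectable = FALSE)
}

#' Write / read dwell-sequence truth tables as TSV
#'
#' @param dwells a [sample_dwells()] result.
#' @param path file path.
#' @return `write_dwells()` returns `path` invisibly.
#' @export
write_dwells <- function(dwells, path) {
  stopifnot(inherits(dwells, "dwell_sequence"))
  df <- as.data.frame(dwells)
  con <- file(path, "w")
  on.exit(close(con))
  write_meta(con, list(genotype = dwells$genotype, voltage_mV = dwells$voltage,
                       total_duration_s = dwells$total_duration))
  writeLines("conducting_flag\tstart_s\tduration_s", con)
  writeLines(paste(as.integer(df$conducting), fmt_num(df$start_s, 9),
                   fmt_num(df$duration_s, 9), sep = "\t"), con)
  invisible(path)
}

#' Write / read growth tables as CSV
#'
#' Columns `genotype,replicate,time_h,od600`.
#'
#' @param table growth data.frame.
#' @param path file path.
#' @return `write_growth()` returns `path` invisibly; `read_growth()` the
#'   data.frame.
#' @export
write_growth <- function(table, path) {
  stopifnot(all(c("genotype", "replicate", "time_h", "od600") %in% names(table)))
  out <- table[, c("genotype", "replicate", "time_h", "od600")]
  out$od600 <- fmt_num(out$od600)
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth
#' @export
read_growth <- function(path) {
  if (!file.exists(path)) stop(sprintf("growth file not found: %s", path),
                               call. = FALSE)
  dat <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("genotype", "replicate", "time_h", "od600")
  if (!all(need %in% names(dat)))
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ",")),
         call. = FALSE)
  if (!is.numeric(dat$od600) || any(!is.finite(dat$od600)) || any(dat$od600 <= 0))
    stop(sprintf("%s: od600 must be positive numbers", path), call. = FALSE)
  dat
}

#' Write a per-genotype summary table as TSV
#'
#' @param summaries data.frame of [channel_summary()] rows.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summaries, path) {
  out <- summaries
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], fmt_num)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
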
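#' Multichannel recording container
#'
#' A \code{recording} holds uniformly sampled signals from one feeding
#' session: extracellular nerve channels (RN, BN2, BN3), the I2 muscle EMG,
#' and, for loaded swallows, a single force channel in mN. All channels share
#' one sample rate and start time; all times elsewhere in the package are
#' seconds from \code{t0} and all intervals are closed.
#'
#' @param signals named list of equal-length numeric vectors, one per channel.
#' @param roles named character vector mapping each channel name to one of
#'   \code{"nerve"}, \code{"emg"}, \code{"force"}.
#' @param sample_rate sampling rate in Hz (the recordings this package
#'   targets are digitized at 5000 Hz).
#' @param t0 time of the first sample in seconds (default 0).
#' @return an object of class \code{"recording"}.
#' @export
recording <- function(signals, roles, sample_rate, t0 = 0) {
  if (!is.list(signals) || is.null(names(signals)) || any(names(signals) == ""))
    stop("`signals` must be a named list of numeric vectors")
  lens <- vapply(signals, length, integer(1))
  if (length(unique(lens)) > 1)
    stop("ragged channels: all channels must have the same length")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number")
  roles <- roles[names(signals)]
  if (anyNA(roles) || !all(roles %in% c("nerve", "emg", "force")))
    stop("every channel needs a role in {nerve, emg, force}")
  structure(
    list(signals = lapply(signals, as.numeric), roles = roles,
         sample_rate = as.numeric(sample_rate), t0 = as.numeric(t0)),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  n <- length(x$signals[[1]])
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.2f s, t0 = %g)\n",
              length(x$signals), n, x$sample_rate, n / x$sample_rate, x$t0))
  for (nm in names(x$signals))
    cat(sprintf("  %-6s [%s]\n", nm, x$roles[[nm]]))
  invisible(x)
}

#' Number of samples and duration of a recording
#' @param rec a \code{recording}.
#' @return sample count (\code{n_samples}) or duration in seconds.
#' @export
n_samples <- function(rec) length(rec$signals[[1]])

#' @rdname n_samples
#' @export
rec_duration <- function(rec) n_samples(rec) / rec$sample_rate

#' Sample times of a recording
#' @param rec a \code{recording}.
#' @return numeric vector of times (s) for each sample.
#' @export
rec_times <- function(rec) rec$t0 + (seq_len(n_samples(rec)) - 1) / rec$sample_rate

#' Extract the single force channel
#' @param rec a \code{recording}.
#' @return numeric vector of force samples (mN).
#' @export
force_channel <- function(rec) {
  i <- which(rec$roles == "force")
  if (length(i) != 1)
    stop("force analysis requires exactly one force channel, found ", length(i))
  rec$signals[[i]]
}

#' Spike train of one identified unit
#'
#' @param unit unit label (e.g. \code{"B38"}, \code{"I2"}, \code{"B8a/b"},
#'   \code{"B6/B9"}, \code{"B3"}, \code{"B4/B5"}, or user-defined).
#' @param times strictly increasing spike times in seconds.
#' @return an object of class \code{"spike_train"}.
#' @export
spike_train <- function(unit, times) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  structure(list(unit = as.character(unit), times = times), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spikes", x$unit, length(x$times)))
  if (length(x$times)) cat(sprintf(" in [%.3f, %.3f] s", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' Burst of one unit
#'
#' Closed interval of sustained firing. The mean rate is defined as
#' (number of spikes − 1) / duration, the reciprocal of the mean
#' interspike interval within the burst.
#'
#' @param unit unit label.
#' @param start,end burst bounds (s), spike times at the boundary included.
#' @param n_spikes spike count within \code{[start, end]}.
#' @return an object of class \code{"burst"}, with fields \code{unit},
#'   \code{start}, \code{end}, \code{n_spikes}, \code{mean_rate}.
#' @export
burst <- function(unit, start, end, n_spikes) {
  if (end <= start) stop("burst end must exceed start")
  structure(list(unit = as.character(unit), start = as.numeric(start),
                 end = as.numeric(end), n_spikes = as.integer(n_spikes),
                 mean_rate = (n_spikes - 1) / (end - start)),
            class = "burst")
}

#' @export
print.burst <- function(x, ...) {
  cat(sprintf("<burst> %s [%.3f, %.3f] s, %d spikes, %.2f Hz\n",
              x$unit, x$start, x$end, x$n_spikes, x$mean_rate))
  invisible(x)
}

#' Convert a list of bursts to a data frame
#' @param bursts list of \code{burst} objects (NULLs are dropped).
#' @return data.frame with columns unit, start, end, n_spikes, mean_rate.
#' @export
bursts_df <- function(bursts) {
  bursts <- Filter(Negate(is.null), bursts)
  if (!length(bursts))
    return(data.frame(unit = character(), start = numeric(), end = numeric(),
                      n_spikes = integer(), mean_rate = numeric()))
  do.call(rbind, lapply(bursts, function(b)
    data.frame(unit = b$unit, start = b$start, end = b$end,
               n_spikes = b$n_spikes, mean_rate = b$mean_rate)))
}

# ---- disk formats -----------------------------------------------------------
# Signals travel as CSV: '#'-prefixed header lines carry sample_rate, t0 and
# channel roles, then a regular header row and one column per channel.
# Comma separated, '.' decimal, full float precision for bit-faithful
# round-trips.

#' Write a recording to CSV
#'
#' @param rec a \code{recording}.
#' @param path output file path.
#' @param format only \code{"csv"} is supported.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path, format = "csv") {
  format <- match.arg(format, "csv")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample_rate: %s", format(rec$sample_rate, digits = 17)),
    sprintf("# t0: %s", format(rec$t0, digits = 17)),
    sprintf("# roles: %s", paste(names(rec$roles), rec$roles,
                                 sep = "=", collapse = ","))), con)
  df <- as.data.frame(rec$signals, check.names = FALSE)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a recording from CSV
#'
#' @param path file written by \code{\link{write_recording}} (or following the
#'   same layout).
#' @param format only \code{"csv"} is supported.
#' @return a \code{recording}.
#' @export
read_recording <- function(path, format = "csv") {
  format <- match.arg(format, "csv")
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(m)) return(NULL)
    trimws(sub(sprintf("^# %s:", key), "", m[[1]]))
  }
  sr <- get_meta("sample_rate")
  if (is.null(sr)) stop("format error: missing sample rate metadata in ", path)
  t0 <- get_meta("t0")
  roles_raw <- get_meta("roles")
  if (is.null(roles_raw)) stop("format error: missing channel roles in ", path)
  kv <- strsplit(strsplit(roles_raw, ",")[[1]], "=")
  roles <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  recording(as.list(df), roles = roles, sample_rate = as.numeric(sr),
            t0 = if (is.null(t0)) 0 else as.numeric(t0))
}

#' Swallow annotation table I/O
#'
#' Behavioral annotations delimit swallow cycles and, when visible in the
#' video, the period of inward seaweed movement. Columns: animal, condition
#' (\code{unloaded}/\code{loaded}), cycle_start, cycle_end, inward_start,
#' inward_end (the last two may be NA). Inward-movement intervals must lie
#' inside their cycle window.
#'
#' @param path CSV file path.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path)
  need <- c("animal", "condition", "cycle_start", "cycle_end",
            "inward_start", "inward_end")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have columns: ", paste(need, collapse = ", "))
  validate_annotations(df)
  df
}

#' @rdname read_annotations
#' @param ann annotation data.frame.
#' @export
write_annotations <- function(ann, path) {
  validate_annotations(ann)
  utils::write.csv(ann, path, row.names = FALSE)
  invisible(path)
}

validate_annotations <- function(ann) {
  if (!all(ann$condition %in% c("unloaded", "loaded")))
    stop("condition must be 'unloaded' or 'loaded'")
  if (any(ann$cycle_end <= ann$cycle_start))
    stop("cycle_end must exceed cycle_start")
  has_in <- !is.na(ann$inward_start) & !is.na(ann$inward_end)
  bad <- has_in & (ann$inward_start < ann$cycle_start |
                   ann$inward_end > ann$cycle_end |
                   ann$inward_end <= ann$inward_start)
  if (any(bad))
    stop("inward-movement interval must lie inside its cycle window")
  invisible(ann)
}

#' Per-animal paired condition means for one measure
#'
#' The shape used by the statistical battery: one row per animal, the
#' per-condition mean of a measure (a duration in s or a firing rate in Hz)
#' and the per-condition swallow counts.
#'
#' @param measure name of the measure.
#' @param animal animal identifiers (one per row).
#' @param unloaded,loaded per-animal condition means.
#' @param n_unloaded,n_loaded per-condition sample sizes (swallows).
#' @return data.frame of class \code{"paired_table"}.
#' @export
paired_table <- function(measure, animal, unloaded, loaded,
                         n_unloaded = NA_integer_, n_loaded = NA_integer_) {
  if (anyDuplicated(animal)) stop("one row per animal required")
  df <- data.frame(animal = animal, unloaded = as.numeric(unloaded),
                   loaded = as.numeric(loaded),
                   n_unloaded = n_unloaded, n_loaded = n_loaded)
  attr(df, "measure") <- measure
  class(df) <- c("paired_table", "data.frame")
  df
}

#' Write result tables and statistics reports
#'
#' Writes one CSV per paired table (deterministic column order
#' animal, unloaded, loaded, n_unloaded, n_loaded) and one JSON file for the
#' statistics report, into \code{dir}.
#'
#' @param tables list of \code{paired_table} objects (may be empty).
#' @param stats_report list of statistical results (e.g. from
#'   \code{\link{paired_battery}}), or NULL.
#' @param dir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(tables, stats_report = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (tab in tables) {
    nm <- gsub("[^A-Za-z0-9_]+", "_", attr(tab, "measure"))
    f <- file.path(dir, paste0("table_", nm, ".csv"))
    out <- tab[, c("animal", "unloaded", "loaded", "n_unloaded", "n_loaded")]
    utils::write.csv(out, f, row.names = FALSE)
    written <- c(written, f)
  }
  if (!is.null(stats_report)) {
    f <- file.path(dir, "stats_report.json")
    strip_s3 <- function(x) {
      if (inherits(x, "stat_report")) x <- unclass(x)
      if (is.list(x) && !is.data.frame(x)) lapply(x, strip_s3) else x
    }
    jsonlite::write_json(strip_s3(stats_report), f, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    written <- c(written, f)
  }
  invisible(written)
}

#' Read back a paired table written by \code{write_results}
#' @param path CSV path.
#' @param measure measure name to attach.
#' @return a \code{paired_table}.
#' @export
read_paired_table <- function(path, measure = NULL) {
  df <- utils::read.csv(path)
  if (is.null(measure))
    measure <- sub("^table_", "", sub("\\.csv$", "", basename(path)))
  paired_table(measure, df$animal, df$unloaded, df$loaded,
               df$n_unloaded, df$n_loaded)
}
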
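# Delimited-text IO. Dialect is fixed: comma separator, mandatory header
# row, "." decimal, ISO-8601 timestamps at millisecond precision.

.iso_fmt <- "%Y-%m-%dT%H:%M:%OS"

.format_iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")

.parse_iso <- function(x) {
  out <- as.POSIXct(strptime(x, .iso_fmt, tz = "UTC"))
  if (any(is.na(out)))
    stop("unparseable ISO-8601 timestamp: ", x[which(is.na(out))[1]])
  out
}

# Full-precision numeric formatting so text round-trips are exact.
.num <- function(x) formatC(x, digits = 17, format = "g")

#' Read an EEG recording from EDF or delimited text
#'
#' Delimited input must have a header `t,<ch1>,<ch2>,...` with `t` in seconds
#' at uniform spacing. EDF input is the plain 16-bit European Data Format;
#' labels are matched case-insensitively and reference suffixes such as
#' `"F4-M1"` are stripped, since the mastoid references are not data channels.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"edf"` or `"delimited"`.
#' @param channels Channels to return; default all channels present.
#'   Requesting an absent channel is an error. Channels present in the file
#'   beyond the requested/expected set are reported via `message()`, never
#'   silently dropped.
#' @return An [eeg_recording].
#' @export
read_eeg <- function(path, format = c("auto", "edf", "delimited"), channels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  rec <- if (format == "edf") read_edf(path) else .read_eeg_delimited(path)
  if (!is.null(channels)) {
    have <- channel_labels(rec)
    missing <- setdiff(channels, have)
    if (length(missing))
      stop("channel(s) absent from file: ", paste(missing, collapse = ", "))
    extra <- setdiff(have, channels)
    if (length(extra))
      message("ignoring additional channel(s): ", paste(extra, collapse = ", "))
    rec$samples <- rec$samples[, channels, drop = FALSE]
  }
  rec
}

.read_eeg_delimited <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"t" %in% names(df))
    stop("delimited EEG input requires a 't' column")
  t <- as.numeric(df$t)
  if (length(t) < 2) stop("need at least two samples to infer sampling rate")
  dt <- diff(t)
  if (any(dt <= 0)) stop("non-monotone timestamps in delimited EEG input")
  if (max(dt) - min(dt) > 1e-4 * mean(dt))
    stop("non-uniform sample spacing in delimited EEG input")
  chans <- setdiff(names(df), "t")
  if (anyNA(df[chans]))
    stop("unequal channel lengths (missing values) in delimited EEG input")
  eeg_recording(as.matrix(df[chans]), sampling_rate = 1 / mean(dt))
}

#' Write an EEG recording as delimited text
#'
#' @param rec An [eeg_recording].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eeg_delimited <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- nrow(rec$samples)
  t <- (seq_len(n) - 1) / rec$sampling_rate
  header <- paste(c("t", colnames(rec$samples)), collapse = ",")
  body <- do.call(paste, c(list(.num(t)),
                           lapply(seq_len(ncol(rec$samples)),
                                  function(j) .num(rec$samples[, j])),
                           sep = ","))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an eye-aspect-ratio trace from delimited text
#'
#' Accepts either a two-column file with header `t,ear` (time in seconds,
#' uniform spacing) or a one-column file with header `ear` plus a declared
#' `frame_rate`.
#'
#' @param path Path to the CSV file.
#' @param frame_rate Declared frame rate (required for one-column input;
#'   for two-column input the rate is inferred from the time column).
#' @return An [ear_trace].
#' @export
read_ear_trace <- function(path, frame_rate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if ("t" %in% names(df) && "ear" %in% names(df)) {
    t <- as.numeric(df$t)
    if (length(t) >= 2) {
      dt <- diff(t)
      if (any(dt <= 0)) stop("non-monotone timestamps in EAR trace")
      if (max(dt) - min(dt) > 1e-3 * mean(dt))
        stop("non-uniform frame spacing in EAR trace")
      frame_rate <- 1 / mean(dt)
    } else if (is.null(frame_rate)) {
      stop("cannot infer frame rate from fewer than two frames")
    }
    values <- as.numeric(df$ear)
  } else if ("ear" %in% names(df)) {
    if (is.null(frame_rate))
      stop("one-column EAR input requires a declared frame_rate")
    values <- as.numeric(df$ear)
  } else {
    stop("EAR input requires columns 't,ear' or 'ear'")
  }
  ear_trace(values, frame_rate = frame_rate)
}

#' Write an eye-aspect-ratio trace as delimited text
#'
#' @param trace An [ear_trace].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ear_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ear_trace"))
  n <- length(trace$values)
  t <- (seq_len(n) - 1) / trace$frame_rate
  writeLines(c("t,ear", paste(.num(t), .num(trace$values), sep = ",")), path)
  invisible(path)
}

#' Write an episode table as delimited text
#'
#' Episodes are written with absolute ISO-8601 timestamps at millisecond
#' precision (`index,label,start_time,end_time`), anchored at the table's
#' `start_time` attribute.
#'
#' @param episodes An [episode_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_episode_table <- function(episodes, path) {
  stopifnot(inherits(episodes, "episode_table"))
  t0 <- attr(episodes, "start_time")
  header <- "index,label,start_time,end_time"
  if (nrow(episodes) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  st <- .format_iso(t0 + round(episodes$start, 3))
  en <- .format_iso(t0 + round(episodes$end, 3))
  writeLines(c(header, paste(episodes$index, episodes$label, st, en, sep = ",")),
             path)
  invisible(path)
}

#' Read an episode table from delimited text
#'
#' @param path Path to the CSV file.
#' @param on_unordered `"reorder"` (default) sorts rows by start time before
#'   validation; `"error"` rejects out-of-order files.
#' @return An [episode_table]; overlapping episodes are an error.
#' @export
read_episode_table <- function(path, on_unordered = c("reorder", "error")) {
  on_unordered <- match.arg(on_unordered)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "label", "start_time", "end_time")
  if (!all(need %in% names(df)))
    stop("episode table requires columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0)
    return(episode_table(character(), numeric(), numeric()))
  st <- .parse_iso(df$start_time)
  en <- .parse_iso(df$end_time)
  ord <- order(st)
  if (is.unsorted(ord)) {
    if (on_unordered == "error") stop("episodes out of order in file")
    df <- df[ord, ]; st <- st[ord]; en <- en[ord]
  }
  t0 <- st[1]
  episode_table(df$label,
                round(as.numeric(difftime(st, t0, units = "secs")), 3),
                round(as.numeric(difftime(en, t0, units = "secs")), 3),
                start_time = t0)
}

#' Write / read a per-episode feature matrix
#'
#' Plain CSV with one row per (episode, channel) and one column per feature.
#'
#' @param features Data frame as returned by [episode_features()].
#' @param path File path.
#' @return `path` (writer, invisibly) or the data frame (reader).
#' @export
write_feature_matrix <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a sensitivity report
#'
#' Delimited text with columns `feature`, `scope` (channel/region/all),
#' `scope_members`, `mean_pct` and the per-subject percentages packed as a
#' semicolon-separated string.
#'
#' @param report Data frame component `table` of [build_report()].
#' @param path File path.
#' @return `path` (writer, invisibly) or the data frame (reader).
#' @export
write_sensitivity_report <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensitivity_report
#' @export
read_sensitivity_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read a key/value configuration file
#'
#' Plain `key: value` lines (a YAML subset): scalars are parsed as
#' numbers where possible, comma-separated values become vectors, and
#' `#` starts a comment. Used by the command-line wrapper to override
#' the numeric parameters of any stage.
#'
#' @param path Path to the configuration file.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE))
      stop("malformed config line (expected 'key: value'): ", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else parts
  }
  out
}
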
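# Minimal European Data Format (EDF) reader/writer: plain EDF, 16-bit
# little-endian samples, no EDF+ annotations, no BDF. This covers the way
# polysomnography software exports continuous EEG. Physical values are
# mapped linearly onto the full digital range, so a write/read round trip
# is exact to within one 16-bit quantisation step of each channel's range.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: '", x, "'")
  formatC(x, width = width, flag = "-")
}

# Render a number into at most `width` characters (EDF header fields).
.edf_num <- function(x, width = 8) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g")
    if (nchar(s) <= width) return(s)
  }
  stop("cannot render ", x, " in ", width, " characters")
}

.edf_strip_label <- function(x) {
  # "EEG F4-M1" -> "F4": drop a leading signal-type word and the reference.
  x <- trimws(x)
  x <- sub("^EEG[ .]*", "", x, ignore.case = TRUE)
  x <- sub("-.*$", "", x)
  toupper(trimws(x))
}

#' Write an EEG recording to a plain EDF file
#'
#' @param rec An [eeg_recording]; the sampling rate must be a whole number
#'   of samples per second.
#' @param path Output path.
#' @param physical_dim Physical dimension string stored per channel
#'   (default `"uV"`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_dim = "uV") {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  fs <- round(fs)
  n <- nrow(rec$samples)
  ns <- ncol(rec$samples)
  if (n %% fs == 0) {
    spr <- fs                    # 1-second records
    n_rec <- n %/% fs
    rec_dur <- 1
  } else {
    spr <- n                     # single record holding the whole signal
    n_rec <- 1L
    rec_dur <- n / fs
  }
  phys_min <- apply(rec$samples, 2, min)
  phys_max <- apply(rec$samples, 2, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  # Widen slightly, then snap the bounds to their 8-character header
  # rendering so writer and reader use identical scaling.
  span <- phys_max - phys_min
  phys_min <- vapply(phys_min - 1e-3 * span, function(x) as.numeric(.edf_num(x)), 0)
  phys_max <- vapply(phys_max + 1e-3 * span, function(x) as.numeric(.edf_num(x)), 0)
  dmin <- -32768; dmax <- 32767

  st <- as.POSIXlt(rec$start_time, tz = "UTC")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(.edf_pad(x, width), con, nchars = width, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)                               # patient id
  wr("Startdate X X X X", 80)                     # recording id
  wr(format(st, "%d.%m.%y"), 8)
  wr(format(st, "%H.%M.%S"), 8)
  wr(256 * (1 + ns), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(.edf_num(rec_dur), 8)
  wr(ns, 4)
  for (lab in colnames(rec$samples)) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)               # transducer
  for (i in seq_len(ns)) wr(physical_dim, 8)
  for (i in seq_len(ns)) wr(.edf_num(phys_min[i]), 8)
  for (i in seq_len(ns)) wr(.edf_num(phys_max[i]), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)               # prefiltering
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)

  scale <- (dmax - dmin) / (phys_max - phys_min)
  dig <- matrix(0L, nrow = n, ncol = ns)
  for (j in seq_len(ns))
    dig[, j] <- as.integer(pmin(pmax(
      round((rec$samples[, j] - phys_min[j]) * scale[j]) + dmin, dmin), dmax))
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    for (j in seq_len(ns))
      writeBin(dig[rows, j], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a plain EDF file
#'
#' @param path Path to the EDF file.
#' @param strip_labels If `TRUE` (default) normalise channel labels by
#'   dropping a leading signal-type prefix and a `-M1`/`-M2` style reference
#'   suffix, and upper-casing.
#' @return An [eeg_recording]. Channels with differing per-record sample
#'   counts (differing rates) are an error.
#' @export
read_edf <- function(path, strip_labels = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8)
  if (ver != "0") stop("not a plain EDF file (version '", ver, "')")
  rd(80); rd(80)
  date <- rd(8); time <- rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)                    # physical dim
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("channels with differing sampling rates are not supported")
  spr1 <- spr[1]
  fs <- spr1 / rec_dur

  n <- n_rec * spr1
  out <- matrix(NA_real_, nrow = n, ncol = ns)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * spr1 + 1):(r * spr1)
    for (j in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr1, size = 2, signed = TRUE,
                   endian = "little")
      if (length(d) < spr1) stop("truncated EDF data record")
      out[rows, j] <- pmin[j] + (d - dmin[j]) * scale[j]
    }
  }
  if (strip_labels) labels <- .edf_strip_label(labels)
  if (anyDuplicated(labels))
    stop("duplicate channel labels after normalisation: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  colnames(out) <- labels

  # EDF clips years to two digits; pivot per the format's 1985 convention.
  dt <- strptime(paste(date, time), "%d.%m.%y %H.%M.%S", tz = "UTC")
  if (is.na(dt)) dt <- as.POSIXlt("2000-01-01 00:00:00", tz = "UTC")
  eeg_recording(out, sampling_rate = fs, start_time = as.POSIXct(dt))
}
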
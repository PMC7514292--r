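#' Multichannel recording
#'
#' Container for a channels-by-samples signal matrix with its sampling
#' rate, channel labels and an optional condition tag (e.g. "RS", "ST",
#' "2B"). All pipeline stages consume this type.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one unique label per row;
#'   defaults to `rownames(data)` or `Ch1..ChN`.
#' @param condition free-text condition tag.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, channel_labels = NULL, condition = "") {
  data <- as.matrix(data)
  if (is.null(channel_labels))
    channel_labels <- rownames(data)
  if (is.null(channel_labels))
    channel_labels <- sprintf("Ch%d", seq_len(nrow(data)))
  rec <- structure(list(data = unname(data), fs = fs,
                        channel_labels = as.character(channel_labels),
                        condition = condition),
                   class = "recording")
  validate_recording(rec)
}

validate_recording <- function(rec) {
  if (!is.numeric(rec$fs) || length(rec$fs) != 1 || rec$fs <= 0)
    stop("sampling rate must be a single positive number")
  if (nrow(rec$data) < 2 || ncol(rec$data) < 2)
    stop("recording needs at least 2 channels and 2 samples")
  if (length(rec$channel_labels) != nrow(rec$data))
    stop("number of channel labels (", length(rec$channel_labels),
         ") does not match number of channels (", nrow(rec$data), ")")
  if (anyDuplicated(rec$channel_labels))
    stop("duplicate channel labels: ",
         paste(unique(rec$channel_labels[duplicated(rec$channel_labels)]),
               collapse = ", "))
  bad <- which(!is.finite(rec$data), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite value in channel %s (row %d) at sample %d",
                 rec$channel_labels[bad[1, 1]], bad[1, 1], bad[1, 2]))
  rec
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.2f s)%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              if (nzchar(x$condition)) paste0(" [", x$condition, "]") else ""))
  invisible(x)
}

#' Number of channels / samples of a recording
#' @param rec a [recording()].
#' @return integer count.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname n_channels
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Read a recording from disk
#'
#' Supports three dialects: `"matrix"` (delimited numeric table, rows =
#' channels, one header line `fs=<Hz>; labels=<comma-separated>`), `"edf"`
#' (European Data Format, 16-bit), and `"brainvision"` (a
#' `.vhdr`/`.vmrk`/`.eeg` triplet; pass the `.vhdr` path). The channel
#' order of the file is preserved.
#'
#' @param path file path (for BrainVision, the header file).
#' @param format one of `"matrix"`, `"edf"`, `"brainvision"`; guessed
#'   from the extension by default.
#' @param condition condition tag to attach.
#' @return A validated [recording()].
#' @export
read_recording <- function(path, format = c("auto", "matrix", "edf", "brainvision"),
                           condition = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read recording: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", vhdr = "brainvision", "matrix")
  }
  rec <- switch(format,
                matrix = read_matrix_recording(path),
                edf = read_edf(path),
                brainvision = read_brainvision(path))
  rec$condition <- condition
  validate_recording(rec)
}

#' Write a recording to disk
#'
#' @inheritParams read_recording
#' @param rec a [recording()].
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "matrix", "edf", "brainvision")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", vhdr = "brainvision", "matrix")
  }
  switch(format,
         matrix = write_matrix_recording(rec, path),
         edf = write_edf(rec, path),
         brainvision = write_brainvision(rec, path))
  invisible(path)
}

# --- matrix dialect: header "fs=<Hz>; labels=a,b,c", rows = channels ----

read_matrix_recording <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec("fs=([0-9.eE+-]+);\\s*labels=(.*)$", header))[[1]]
  if (length(m) != 3)
    stop("matrix recording header must be 'fs=<Hz>; labels=<comma-separated>': ", path)
  fs <- as.numeric(m[2])
  labels <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
  dat <- as.matrix(read.table(path, skip = 1, sep = "\t"))
  recording(dat, fs, labels)
}

write_matrix_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fs=%.10g; labels=%s", rec$fs,
                     paste(rec$channel_labels, collapse = ",")), con)
  write.table(format(rec$data, digits = 17, trim = TRUE, scientific = TRUE),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
}

# --- EDF (European Data Format), 16-bit integer with physical scaling ----

pad <- function(x, n) formatC(as.character(x), width = n, flag = "-")

# format a number into at most `n` ASCII characters (EDF header fields)
num_field <- function(x, n = 8) {
  for (d in seq(8, 1)) {
    s <- sprintf("%.*g", d, x)
    if (nchar(s) <= n) return(pad(s, n))
  }
  stop("cannot format ", x, " into ", n, " characters")
}

write_edf <- function(rec, path) {
  ns <- n_channels(rec)
  nsamp <- n_samples(rec)
  # one-second records; pad the tail record with the last value
  spr <- as.integer(round(rec$fs))
  n_rec <- as.integer(ceiling(nsamp / spr))
  con <- file(path, "wb")
  on.exit(close(con))
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  same <- phys_max - phys_min < .Machine$double.eps
  phys_max[same] <- phys_min[same] + 1
  hdr <- paste0(pad("0", 8), pad("local patient", 80), pad("local recording", 80),
                pad("01.01.20", 8), pad("00.00.00", 8),
                pad(256 * (1 + ns), 8), pad("", 44), pad(n_rec, 8),
                pad(format(1, nsmall = 0), 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(vapply(rec$channel_labels, pad, "", n = 16), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad("", 80), ns), collapse = ""), con, eos = NULL)  # transducer
  writeChar(paste0(rep(pad("uV", 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(phys_min, num_field, ""), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(phys_max, num_field, ""), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad(-32768, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad(32767, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad("", 80), ns), collapse = ""), con, eos = NULL)  # prefilter
  writeChar(paste0(rep(pad(spr, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad("", 32), ns), collapse = ""), con, eos = NULL)
  scale <- (phys_max - phys_min) / (32767 - (-32768))
  full <- matrix(rec$data[, c(seq_len(nsamp), rep(nsamp, n_rec * spr - nsamp))],
                 nrow = ns)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((full[ch, idx] - phys_min[ch]) / scale[ch]) - 32768)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  rd(80 * ns); rd(8 * ns)
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  if (length(unique(spr)) != 1)
    stop("EDF with heterogeneous per-signal sampling rates is not supported: ", path)
  out <- matrix(0, ns, n_rec * spr[1])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      out[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        phys_min[ch] + (dig - dig_min[ch]) * scale[ch]
    }
  }
  recording(out, spr[1] / rec_dur, labels)
}

# --- BrainVision triplet (.vhdr / .vmrk / .eeg), IEEE float32 ------------

write_brainvision <- function(rec, path) {
  stem <- tools::file_path_sans_ext(path)
  base <- basename(stem)
  vhdr <- c("Brain Vision Data Exchange Header File Version 1.0",
            "", "[Common Infos]",
            paste0("DataFile=", base, ".eeg"),
            paste0("MarkerFile=", base, ".vmrk"),
            "DataFormat=BINARY",
            "DataOrientation=MULTIPLEXED",
            paste0("NumberOfChannels=", n_channels(rec)),
            sprintf("SamplingInterval=%.10g", 1e6 / rec$fs),
            "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
            "", "[Channel Infos]",
            sprintf("Ch%d=%s,,1,µV", seq_len(n_channels(rec)),
                    rec$channel_labels))
  writeLines(vhdr, paste0(stem, ".vhdr"))
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "", "[Common Infos]", paste0("DataFile=", base, ".eeg"),
               "", "[Marker Infos]",
               "Mk1=New Segment,,1,1,0"), paste0(stem, ".vmrk"))
  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")  # column-major = multiplexed
  invisible(path)
}

read_brainvision <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_val <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (length(ln) == 0) stop("missing ", key, " in ", path)
    sub(paste0("^", key, "="), "", ln[1])
  }
  n_ch <- as.integer(get_val("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_val("SamplingInterval"))
  fmt <- get_val("BinaryFormat")
  orient <- get_val("DataOrientation")
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",", fixed = TRUE),
                   `[`, "", 1)
  datafile <- file.path(dirname(path), get_val("DataFile"))
  sz <- switch(fmt, IEEE_FLOAT_32 = 4, INT_16 = 2,
               stop("unsupported BinaryFormat: ", fmt))
  what <- if (fmt == "INT_16") "integer" else "numeric"
  n_val <- file.size(datafile) / sz
  con <- file(datafile, "rb")
  on.exit(close(con))
  vals <- readBin(con, what, n = n_val, size = sz, endian = "little")
  dat <- if (orient == "MULTIPLEXED") matrix(vals, nrow = n_ch)
         else t(matrix(vals, ncol = n_ch))
  recording(dat, fs, labels)
}

# --- preprocessing -------------------------------------------------------

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every channel forward and backward (no phase distortion, which
#' would otherwise bias directed-connectivity estimates). Offered as
#' optional preprocessing; synthetic fixtures are not filtered.
#'
#' @param rec a [recording()].
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order filter order (applied twice by filtfilt).
#' @return A filtered [recording()] with unchanged shape and labels.
#' @export
bandpass_filter <- function(rec, low, high, order = 4) {
  if (!(low > 0 && low < high && high < rec$fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2 (fs = ", rec$fs, ")")
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  out <- rec
  out$data <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch)))
  validate_recording(out)
}

#' Re-reference channels to their common average
#'
#' Subtracts the instantaneous across-channel mean from every channel.
#' Explicit and off by default so synthetic fixtures are never silently
#' altered.
#'
#' @param rec a [recording()].
#' @return A re-referenced [recording()].
#' @export
rereference_average <- function(rec) {
  out <- rec
  out$data <- sweep(rec$data, 2, colMeans(rec$data))
  out
}
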
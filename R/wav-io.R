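#' Write a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for mono 16-bit PCM. Samples are expected in
#' [-1, 1]; values outside are clipped with a warning.
#'
#' @param samples Numeric vector of samples in [-1, 1].
#' @param fs Sampling rate in Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, fs > 0)
  if (any(abs(samples) > 1)) {
    warning("samples outside [-1, 1] clipped")
    samples <- pmin(pmax(samples, -1), 1)
  }
  pcm <- as.integer(round(samples * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Counterpart of [write_wav()]. Walks the RIFF chunks, requires mono 16-bit
#' PCM, and rescales to [-1, 1].
#'
#' @param path WAV file path.
#' @return List with `samples` (numeric, in [-1, 1]) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path, call. = FALSE)
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt != 1L) stop("only PCM WAV supported", call. = FALSE)
      channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      extra <- sz - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (id == "data") {
      if (is.null(bits)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (channels != 1L || bits != 16L)
        stop("only mono 16-bit PCM supported", call. = FALSE)
      samples <- readBin(con, "integer", sz / 2L, size = 2, signed = TRUE,
                         endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path, call. = FALSE)
  list(samples = samples / 32767, fs = fs)
}

#' Read or write an EMG trace as CSV
#'
#' EMG traces are exchanged as two-column CSV with header
#' `time_s,amplitude_uv`. The sampling rate is recovered from the median
#' time step on read.
#'
#' @param rec An `emg_recording` (for writing).
#' @param path CSV file path.
#' @return `write_emg_csv()` returns `path` invisibly; `read_emg_csv()`
#'   returns an `emg_recording` (identity fields `NA` unless supplied).
#' @export
write_emg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  t <- (seq_along(rec$samples) - 1) / rec$fs
  utils::write.csv(data.frame(time_s = t, amplitude_uv = rec$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @param subject_id,muscle,side,tone Identity labels attached on read.
#' @export
read_emg_csv <- function(path, subject_id = NA_character_, muscle = "CT",
                         side = "lesion", tone = NA_integer_) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude_uv") %in% names(d)))
    stop("EMG CSV must have columns time_s, amplitude_uv", call. = FALSE)
  dt <- stats::median(diff(d$time_s))
  structure(list(samples = d$amplitude_uv, fs = 1 / dt,
                 subject_id = subject_id, muscle = muscle, side = side,
                 tone = tone, ground_truth = NULL),
            class = "emg_recording")
}
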
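#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader covering the encodings found in bioacoustic
#' archives: integer PCM (8/16/24/32 bit) and IEEE float (32/64 bit).
#' Integer samples are scaled to \[-1, 1). Multi-channel files are mixed
#' down by averaging channels.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector in \[-1, 1\]) and `fs`
#'   (sampling rate in Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        fs           = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)
  # WAVE_FORMAT_EXTENSIBLE (0xFFFE) wraps the real format; bits decide here
  fm <- fmt$audio_format
  bits <- fmt$bits
  x <- if (fm %in% c(3L, 65534L) && bits == 32) {
    readBin(data_raw, "numeric", length(data_raw) %/% 4, 4, endian = "little")
  } else if (fm == 3L && bits == 64) {
    readBin(data_raw, "numeric", length(data_raw) %/% 8, 8, endian = "little")
  } else if (bits == 16) {
    readBin(data_raw, "integer", length(data_raw) %/% 2, 2, signed = TRUE,
            endian = "little") / 32768
  } else if (bits == 8) {
    (readBin(data_raw, "integer", length(data_raw), 1, signed = FALSE) - 128) / 128
  } else if (bits == 24) {
    n <- length(data_raw) %/% 3
    b <- matrix(as.integer(data_raw), nrow = 3)[, seq_len(n), drop = FALSE]
    v <- b[1, ] + b[2, ] * 256L + b[3, ] * 65536L
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (bits == 32) {
    readBin(data_raw, "integer", length(data_raw) %/% 4, 4, endian = "little") / 2147483648
  } else {
    stop("unsupported WAV encoding: format ", fm, ", ", bits, " bits")
  }
  if (fmt$n_channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  list(samples = x, fs = fmt$fs)
}

#' Write a PCM WAV file
#'
#' Writes mono 16-bit integer PCM (default) or 32-bit IEEE float.
#' Values outside \[-1, 1\] are clipped for integer output.
#'
#' @param samples Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param path Output path.
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path, bits = 16L) {
  stopifnot(bits %in% c(16L, 32L))
  n <- length(samples)
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(if (bits == 16L) 1L else 3L, 1L), con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, 4, endian = "little")
  writeBin(c(as.integer(bytes_per), as.integer(bits)), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16L) {
    v <- as.integer(round(pmax(-1, pmin(1 - 1 / 32768, samples)) * 32768))
    writeBin(v, con, 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, 4, endian = "little")
  }
  invisible(path)
}
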
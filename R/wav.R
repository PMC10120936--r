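#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the recording format used throughout the
#' package: integer PCM (8/16/24/32 bit), any sample rate, any channel
#' count. Samples are returned on the native integer scale of the file
#' (16-bit files give values in -32768..32767).
#'
#' @param path Path to a RIFF PCM WAV file.
#' @return A list with `samples` (numeric matrix, frames x channels),
#'   `sample_rate` (Hz) and `bits_per_sample`.
#' @keywords internal
read_wav_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size + size %% 2)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(body[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw) || length(data_raw) == 0L) stop("WAV file has no audio data: ", path)
  if (fmt$audio_format != 1L) stop("unsupported WAV encoding (not integer PCM): format tag ", fmt$audio_format)

  bytes <- fmt$bits / 8
  n <- length(data_raw) %/% (bytes * fmt$n_channels)
  if (n == 0L) stop("zero-length audio in ", path)
  if (fmt$bits == 8L) {
    vals <- as.numeric(readBin(data_raw, "integer", n * fmt$n_channels, 1, signed = FALSE)) - 128
  } else if (fmt$bits %in% c(16L, 32L)) {
    vals <- as.numeric(readBin(data_raw, "integer", n * fmt$n_channels, bytes, signed = TRUE, endian = "little"))
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw[seq_len(n * fmt$n_channels * 3)]), nrow = 3)
    vals <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    vals <- ifelse(vals >= 2^23, vals - 2^24, vals)
  } else stop("unsupported bit depth: ", fmt$bits)

  list(
    samples = matrix(vals, ncol = fmt$n_channels, byrow = TRUE),
    sample_rate = fmt$sample_rate,
    bits_per_sample = fmt$bits
  )
}

#' Write a 16-bit PCM WAV file
#'
#' @param samples Numeric vector (mono) or frames x channels matrix on the
#'   16-bit integer scale; values are rounded and clipped to -32768..32767.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  n_channels <- ncol(samples)
  x <- as.integer(pmax(-32768, pmin(32767, round(t(samples)))))
  data_size <- length(x) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, n_channels), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_channels * 2L), con, size = 4, endian = "little")
  writeBin(c(as.integer(n_channels * 2L), 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}
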
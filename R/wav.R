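# Minimal RIFF/WAVE codec: linear PCM 16-bit and IEEE float 32-bit,
# mono or two-channel.

#' Read a WAV file
#'
#' Supports linear PCM 16-bit and IEEE float 32-bit, mono (returned as a
#' [waveform()]) or two channels (returned as a [mic_pair()]). PCM samples are
#' scaled to \[-1, 1\].
#'
#' @param path Path to a `.wav` file.
#' @return A `waveform` or `mic_pair` tibble with the file's sample rate.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("Not a RIFF file.")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("Not a WAVE file.")
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      extra <- size - 16
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort("Malformed WAV: missing fmt or data chunk.")
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
  } else {
    abort(sprintf("Unsupported WAV format (format %d, %d bits).",
                  fmt$audio_format, fmt$bits))
  }
  if (fmt$n_channels == 1L) {
    waveform(x, fmt$sample_rate)
  } else if (fmt$n_channels == 2L) {
    mic_pair(x[c(TRUE, FALSE)], x[c(FALSE, TRUE)], fmt$sample_rate)
  } else {
    abort("Only mono and two-channel WAV files are supported.")
  }
}

#' Write a WAV file
#'
#' Writes a [waveform()] (mono) or [mic_pair()] (two interleaved channels) as
#' linear PCM 16-bit or IEEE float 32-bit. PCM output clips to \[-1, 1).
#'
#' @param wave A `waveform` or `mic_pair`.
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, bits = 16) {
  if (!bits %in% c(16, 32)) abort("`bits` must be 16 (PCM) or 32 (float).")
  fs <- round(wave_fs(wave))
  if (inherits(wave, "mic_pair")) {
    x <- as.numeric(rbind(wave$mic1, wave$mic2))
    n_channels <- 2L
  } else {
    x <- wave_values(wave)
    n_channels <- 1L
  }
  bytes_per <- bits / 8
  block_align <- n_channels * bytes_per
  data_size <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(if (bits == 16) 1L else 3L, con, 2, endian = "little")
  writeBin(n_channels, con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * block_align), con, 4, endian = "little")
  writeBin(as.integer(block_align), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    q <- as.integer(pmax(pmin(round(x * 32768), 32767), -32768))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(x, con, 4, endian = "little")
  }
  invisible(path)
}
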
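#' Audio container
#'
#' A minimal audio object: a numeric sample vector (mono) or matrix (one
#' column per channel) in `[-1, 1]`, plus its sample rate.
#'
#' @param samples Numeric vector (mono) or matrix (columns = channels).
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `audio_wave`.
#' @export
audio_wave <- function(samples, sample_rate) {
  if (!is.numeric(samples) || !length(samples)) stopf("samples must be non-empty numeric")
  if (!is.numeric(sample_rate) || sample_rate <= 0) stopf("sample_rate must be > 0")
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate)),
            class = "audio_wave")
}

#' @export
print.audio_wave <- function(x, ...) {
  n <- if (is.matrix(x$samples)) nrow(x$samples) else length(x$samples)
  ch <- if (is.matrix(x$samples)) ncol(x$samples) else 1L
  cat(sprintf("<audio_wave> %.3f s @ %g Hz, %d channel(s)\n",
              n / x$sample_rate, x$sample_rate, ch))
  invisible(x)
}

audio_length <- function(audio) {
  if (is.matrix(audio$samples)) nrow(audio$samples) else length(audio$samples)
}

## collapse to mono for analysis
audio_mono <- function(audio) {
  if (is.matrix(audio$samples)) audio_wave(rowMeans(audio$samples), audio$sample_rate)
  else audio
}

#' Write a PCM 16-bit WAV file
#'
#' @param audio An [audio_wave()] object; samples are clipped to `[-1, 1]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  stopifnot(inherits(audio, "audio_wave"))
  x <- audio$samples
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  x[x > 1] <- 1; x[x < -1] <- -1
  n_ch <- ncol(x)
  sr <- as.integer(round(audio$sample_rate))
  pcm <- as.integer(round(t(x) * 32767))  # interleaved
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * n_ch * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(n_ch * 2L, con, size = 2, endian = "little")       # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM 16-bit WAV file
#'
#' Supports uncompressed 16-bit PCM, mono or multi-channel.
#'
#' @param path WAV file path.
#' @return An [audio_wave()] with samples scaled to `[-1, 1]`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stopf("%s: not a RIFF/WAV file", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stopf("%s: not a WAVE file", path)
  sr <- NULL; n_ch <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || !nzchar(id)) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stopf("%s: only PCM WAV supported", path)
      n_ch <- fmt[2]
      sr <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16L) stopf("%s: only 16-bit PCM supported", path)
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, raw(), n = extra))
    } else if (identical(id, "data")) {
      samples <- readBin(con, integer(), n = size / 2, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
  if (is.null(samples)) stopf("%s: no data chunk found", path)
  x <- samples / 32767
  if (n_ch > 1) x <- t(matrix(x, nrow = n_ch))
  audio_wave(x, sr)
}
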
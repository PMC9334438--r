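#' Write a waveform to a 16-bit PCM mono WAV file
#'
#' @param w A \code{\link{waveform}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
wav_write <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  x <- pmin(pmax(w$samples, -1), 1)
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(w$sample_rate_hz)
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Reads PCM WAV audio; stereo files are downmixed to mono with a warning.
#'
#' @param path WAV file path.
#' @return A \code{\link{waveform}}.
#' @export
wav_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file", call. = FALSE)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file", call. = FALSE)
  fs <- NULL
  n_channels <- NULL
  bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found", call. = FALSE)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported", call. = FALSE)
      n_channels <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (identical(id, "data")) {
      if (bits != 16L) stop("only 16-bit PCM is supported", call. = FALSE)
      pcm <- readBin(con, integer(), n = sz / 2, size = 2,
                     signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), n = sz + (sz %% 2)))
    }
  }
  x <- pcm / 32767
  if (n_channels == 2L) {
    warning("stereo WAV downmixed to mono")
    x <- (x[seq(1, length(x), by = 2)] + x[seq(2, length(x), by = 2)]) / 2
  }
  waveform(x, fs)
}
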
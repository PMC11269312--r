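# Minimal RIFF/WAVE PCM I/O (16-bit integer, mono or stereo read, mono write).
# Only the canonical chunks are handled: "fmt " and "data"; other chunks are
# skipped. Floats are scaled to the signed 16-bit range on write.

#' Write a mono waveform to a 16-bit PCM WAV file
#'
#' @param waveform Numeric vector in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, sample_rate, path) {
  stopifnot(is.numeric(waveform), length(waveform) > 0, sample_rate >= 1)
  pcm <- as.integer(round(pmax(pmin(waveform, 1), -1) * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM WAV file
#'
#' @param path WAV file path.
#' @return List with `waveform` (numeric, `[-1, 1]`), `sample_rate`,
#'   `n_channels`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort(paste0("not a RIFF/WAVE file: ", path))
  }
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) abort(paste0("no data chunk in ", path))
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, integer(), size = 2, endian = "little", signed = FALSE),
        channels = readBin(con, integer(), size = 2, endian = "little", signed = FALSE),
        sample_rate = readBin(con, integer(), size = 4, endian = "little"),
        byte_rate = readBin(con, integer(), size = 4, endian = "little"),
        block_align = readBin(con, integer(), size = 2, endian = "little", signed = FALSE),
        bits = readBin(con, integer(), size = 2, endian = "little", signed = FALSE)
      )
      if (size > 16) readBin(con, raw(), size - 16)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) abort(paste0("data chunk before fmt in ", path))
      if (fmt$format != 1L || fmt$bits != 16L) {
        abort("only 16-bit integer PCM WAV is supported")
      }
      pcm <- readBin(con, integer(), n = size / 2L, size = 2, endian = "little")
      return(list(
        waveform = pcm / 32767,
        sample_rate = fmt$sample_rate,
        n_channels = fmt$channels
      ))
    } else {
      readBin(con, raw(), size + size %% 2L)  # skip unknown chunk (word-aligned)
    }
  }
}
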
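#' Write a mono waveform as a 16-bit PCM WAV file
#'
#' Samples outside `[-1, 1]` are clipped before quantisation.
#'
#' @param waveform Numeric vector of samples in `[-1, 1]`.
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, sample_rate = 22050) {
  stopifnot(is.numeric(waveform), length(waveform) >= 1, sample_rate > 0)
  pcm <- as.integer(round(pmax(-1, pmin(1, waveform)) * 32767))
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Minimal RIFF reader for the files this package writes: PCM, mono,
#' 16-bit. Chunks other than `fmt ` and `data` are skipped.
#'
#' @param path WAV file path.
#' @return List with `waveform` (numeric in `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only PCM mono WAV is supported")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, raw(), n = size - 8L)
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = size %/% 2L, size = 2, endian = "little")
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  if (is.null(sample_rate)) stop("no fmt chunk in ", path)
  list(waveform = pcm / 32767, sample_rate = sample_rate)
}
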
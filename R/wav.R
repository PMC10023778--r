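#' Read and write mono 16-bit PCM WAV files
#'
#' Minimal RIFF/WAVE support for the single format the pipeline produces and
#' consumes: mono, 16-bit signed PCM. `wav_write()` scales samples in
#' `[-1, 1]` to the full int16 range; values outside `[-1, 1]` are clipped
#' with a warning. `wav_read()` returns samples rescaled to `[-1, 1)`.
#'
#' @param x Numeric vector of samples in `[-1, 1]`.
#' @param path File path.
#' @param sample_rate Sampling rate in Hz.
#' @return `wav_read()` returns a list with elements `samples` (numeric
#'   vector in `[-1, 1)`) and `sample_rate` (Hz). `wav_write()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".wav")
#' wav_write(sin(2 * pi * 20 * seq(0, 1, by = 1 / 500)) * 0.5, f, 500)
#' w <- wav_read(f)
#' w$sample_rate
#' @export
wav_write <- function(x, path, sample_rate) {
  stopifnot(is.numeric(x), length(x) > 0, sample_rate > 0)
  if (any(abs(x) > 1)) {
    warn("samples outside [-1, 1] clipped on WAV write")
    x <- pmin(1, pmax(-1, x))
  }
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname wav_write
#' @export
wav_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort(paste0("not a RIFF file: ", path))
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) abort(paste0("not a WAVE file: ", path))
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) abort("no data chunk found")
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) {
        abort("only mono PCM WAV is supported")
      }
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      ba_bits <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (ba_bits[2] != 16L) abort("only 16-bit PCM WAV is supported")
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size %/% 2, size = 2,
                     signed = TRUE, endian = "little")
      return(list(samples = pcm / 32768, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
}
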
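#' Write a waveform to a RIFF/WAV file
#'
#' Minimal WAV writer supporting IEEE float32 (default) and PCM16 encodings,
#' the two dialects browsers and audio toolchains consume. Float32 output is
#' bit-transparent for the synthesis pipeline (no quantization).
#'
#' @param wave A [waveform()].
#' @param path Output file path.
#' @param bits 32 (IEEE float) or 16 (integer PCM).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, bits = 32) {
  stopifnot(inherits(wave, "waveform"), bits %in% c(16, 32))
  x <- wave$samples
  n_ch <- ncol(x)
  n <- nrow(x)
  interleaved <- as.numeric(t(x))
  bytes_per_sample <- bits / 8
  data_size <- n * n_ch * bytes_per_sample
  fmt <- if (bits == 32) 3L else 1L # 3 = IEEE float, 1 = PCM
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(wave$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(wave$sample_rate * n_ch * bytes_per_sample), con,
           size = 4, endian = "little")
  writeBin(as.integer(n_ch * bytes_per_sample), con, size = 2,
           endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 32) {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(pmin(interleaved, 1), -1) * 32767)),
             con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a RIFF/WAV file written by [write_wav()]
#'
#' Supports float32 and PCM16 chunks.
#'
#' @param path Input file path.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        code = readBin(con, "integer", size = 2, endian = "little"),
        n_ch = readBin(con, "integer", size = 2, endian = "little"),
        rate = readBin(con, "integer", size = 4, endian = "little")
      )
      readBin(con, "raw", n = size - 8) # skip remainder of fmt chunk
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk precedes fmt chunk in ", path)
      if (fmt$code == 3) {
        raw <- readBin(con, "numeric", n = size / 4, size = 4,
                       endian = "little")
      } else if (fmt$code == 1) {
        raw <- readBin(con, "integer", n = size / 2, size = 2,
                       endian = "little") / 32767
      } else {
        stop("unsupported WAV format code ", fmt$code)
      }
      samples <- matrix(raw, ncol = fmt$n_ch, byrow = TRUE)
      return(waveform(samples, fmt$rate))
    } else {
      readBin(con, "raw", n = size)
    }
  }
}
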
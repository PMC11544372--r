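# RIFF WAV reading/writing (mono PCM, 16/24-bit).

#' Write a waveform to a RIFF WAV file
#'
#' Mono PCM output; samples are clipped to \[-1, 1\] and quantized.
#'
#' @param wav A [waveform()].
#' @param path Output path.
#' @param bits Bits per sample: 16 (default) or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wav, path, bits = 16) {
  if (!bits %in% c(16L, 24L)) {
    stop_config("only 16- and 24-bit PCM output is supported")
  }
  x <- pmin(1, pmax(-1, wav$samples))
  full <- 2^(bits - 1) - 1
  q <- as.integer(round(x * full))
  n <- length(q)
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(wav$rate), con, size = 4, endian = "little")
  writeBin(as.integer(wav$rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16L) {
    writeBin(q, con, size = 2, endian = "little")
  } else {
    # 24-bit little-endian: write the three low bytes of each sample
    u <- ifelse(q < 0, q + 16777216, q)
    raw3 <- as.raw(rbind(u %% 256L, (u %/% 256L) %% 256L,
                         (u %/% 65536L) %% 256L))
    writeBin(raw3, con)
  }
  invisible(path)
}

#' Read a RIFF WAV file
#'
#' Supports PCM 16- and 24-bit encodings. Stereo input is downmixed to mono
#' by the channel mean (with a message); amplitudes are scaled to \[-1, 1\]
#' by the full-scale integer of the bit depth.
#'
#' @param path WAV file path.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") {
    stop_config("%s is not a RIFF file", path)
  }
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") {
    stop_config("%s is not a WAVE file", path)
  }
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || !nzchar(id)) {
      stop_config("no data chunk found in %s", path)
    }
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", size = 2, endian = "little"),
        channels = readBin(con, "integer", size = 2, endian = "little"),
        rate = readBin(con, "integer", size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", size = 4, endian = "little"),
        block_align = readBin(con, "integer", size = 2, endian = "little"),
        bits = readBin(con, "integer", size = 2, endian = "little")
      )
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (id == "data") {
      if (is.null(fmt)) {
        stop_config("data chunk precedes fmt chunk in %s", path)
      }
      break
    } else {
      readBin(con, "raw", n = size + size %% 2L)
    }
  }
  if (fmt$audio_format != 1L) {
    stop_config("unsupported WAV encoding (format tag %d); only PCM is read",
                fmt$audio_format)
  }
  if (!fmt$bits %in% c(16L, 24L)) {
    stop_config("unsupported PCM bit depth %d; only 16/24-bit is read",
                fmt$bits)
  }
  n_samp <- size %/% (fmt$bits %/% 8L)
  if (fmt$bits == 16L) {
    x <- readBin(con, "integer", n = n_samp, size = 2, signed = TRUE,
                 endian = "little") / 32767
  } else {
    raw3 <- readBin(con, "raw", n = n_samp * 3L)
    m <- matrix(as.integer(raw3), nrow = 3L)
    u <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
    x <- ifelse(u >= 8388608, u - 16777216, u) / 8388607
  }
  if (fmt$channels > 1L) {
    message("downmixing ", fmt$channels, "-channel WAV to mono by channel mean")
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  waveform(pmin(1, pmax(-1, x)), fmt$rate)
}
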
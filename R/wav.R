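#' Write a waveform to a WAV file
#'
#' Minimal RIFF/WAVE writer supporting 16- and 24-bit integer PCM and 32-bit
#' IEEE float, mono or stereo.  Samples are expected in \[-1, 1\]; integer
#' formats clip anything outside.
#'
#' @param samples Numeric vector (mono) or matrix with one column per
#'   channel.
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param bit_depth 16, 24 (integer PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 44100, bit_depth = 16L) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  n_ch <- ncol(samples)
  n <- nrow(samples)
  if (!bit_depth %in% c(16L, 24L, 32L)) stop("bit_depth must be 16, 24 or 32")
  interleaved <- as.numeric(t(samples))
  bytes_per <- bit_depth / 8L
  data_size <- n * n_ch * bytes_per
  fmt_code <- if (bit_depth == 32L) 3L else 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_ch * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(n_ch * bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 32L) {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    full <- 2^(bit_depth - 1)
    q <- as.integer(pmin(pmax(round(interleaved * full), -full), full - 1))
    if (bit_depth == 16L) {
      writeBin(q, con, size = 2, endian = "little")
    } else {
      u <- ifelse(q < 0, q + 16777216, q)  # two's complement, 3 bytes LE
      raw3 <- rbind(u %% 256, (u %/% 256) %% 256, (u %/% 65536) %% 256)
      writeBin(as.raw(raw3), con)
    }
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Counterpart of [write_wav()]: reads 16/24-bit PCM and 32-bit float RIFF
#' WAV files, mono or stereo, returning samples scaled to \[-1, 1\].
#'
#' @param path File path.
#' @return List with `samples` (matrix, one column per channel),
#'   `sample_rate` and `bit_depth`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_id <- function() {
    r <- readBin(con, "raw", 4)
    if (length(r) < 4) "" else rawToChar(r)
  }
  if (read_id() != "RIFF") stop("not a RIFF file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (read_id() != "WAVE") stop("not a WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- read_id()
    if (nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, "integer", 1, size = 2, endian = "little")
      n_ch <- readBin(con, "integer", 1, size = 2, endian = "little")
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
      fmt <- list(code = fmt_code, n_ch = n_ch, sr = sr, bits = bits)
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt or data chunk")
  if (fmt$bits == 32L && fmt$code == 3L) {
    x <- readBin(data_raw, "double", length(data_raw) / 4, size = 4,
                 endian = "little")
  } else if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    b <- as.integer(data_raw)
    m <- matrix(b, nrow = 3)
    u <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    x <- ifelse(u >= 8388608, u - 16777216, u) / 8388608
  } else stop("unsupported WAV format (", fmt$bits, "-bit, code ",
              fmt$code, ")")
  list(samples = matrix(x, ncol = fmt$n_ch, byrow = TRUE),
       sample_rate = fmt$sr, bit_depth = fmt$bits)
}
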
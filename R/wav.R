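#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader covering canonical PCM (8/16/24/32-bit integer)
#' and IEEE-float encodings. Samples are returned as doubles scaled to
#' \[-1, 1\]. Only mono files are accepted; multi-channel input is an error
#' (call measurement is defined on single-call mono clips).
#'
#' @param path path to a .wav file.
#' @param expect_rate sampling rate (Hz) the downstream measurements assume;
#'   a differing file rate triggers a warning, never silent resampling.
#' @return a `waveform` object: list with `samples` (numeric vector) and
#'   `sample_rate` (integer, Hz).
#' @export
read_wav <- function(path, expect_rate = 44100) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        n_channels   = readBin(raw[3:4], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        sample_rate  = readBin(raw[5:8], "integer", 1, size = 4,
                               endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, size = 2,
                               endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      samples <- .decode_wav_data(con, sz, fmt)
      if (sz %% 2L == 1L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2L)  # skip unknown chunk (word-aligned)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (fmt$n_channels != 1L)
    stop("only mono WAV is supported (file has ", fmt$n_channels, " channels)")
  if (fmt$sample_rate != expect_rate)
    warning("sample rate ", fmt$sample_rate, " Hz differs from expected ",
            expect_rate, " Hz; measurements use the file's own rate")
  waveform(samples, fmt$sample_rate)
}

.decode_wav_data <- function(con, sz, fmt) {
  if (fmt$audio_format == 1L) {        # integer PCM
    if (fmt$bits == 8L) {
      x <- readBin(con, "integer", sz, size = 1, signed = FALSE)
      (x - 128) / 128
    } else if (fmt$bits == 16L) {
      readBin(con, "integer", sz %/% 2L, size = 2, endian = "little") / 32768
    } else if (fmt$bits == 24L) {
      raw <- readBin(con, "raw", sz)
      n <- length(raw) %/% 3L
      b <- matrix(as.integer(raw[seq_len(3L * n)]), nrow = 3L)
      v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (fmt$bits == 32L) {
      readBin(con, "integer", sz %/% 4L, size = 4, endian = "little") / 2147483648
    } else stop("unsupported PCM bit depth: ", fmt$bits)
  } else if (fmt$audio_format == 3L) { # IEEE float
    readBin(con, "double", sz %/% (fmt$bits %/% 8L),
            size = fmt$bits %/% 8L, endian = "little")
  } else stop("unsupported WAV audio format code: ", fmt$audio_format)
}

#' Write a mono waveform as 16-bit PCM WAV
#'
#' @param w a `waveform` (see [waveform()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  pcm <- as.integer(pmax(-32768, pmin(32767, round(w$samples * 32768))))
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # PCM
  writeBin(1L, con, size = 2, endian = "little")                 # mono
  writeBin(as.integer(w$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                 # block align
  writeBin(16L, con, size = 2, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Construct a waveform object
#'
#' @param samples numeric vector of mono amplitudes.
#' @param sample_rate sampling rate in Hz (positive).
#' @return object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("samples must be a non-empty numeric vector")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.integer(sample_rate)),
            class = "waveform")
}

#' @exportS3Method base::print
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %d Hz (%.3f s)>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}
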
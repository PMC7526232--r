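#' Read a mono WAV file
#'
#' Reads a RIFF/WAVE file holding a single channel of either 16-bit integer
#' PCM or 32-bit IEEE-float samples — the two encodings produced by the
#' emulated stethoscope devices. Samples are returned on the \[-1, 1\] scale
#' (PCM values are divided by 2^15); the file's sample rate and bit depth are
#' preserved as waveform metadata.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little") # overall size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        n_channels = readBin(raw_fmt[3:4], "integer", 1, size = 2,
                             endian = "little", signed = FALSE),
        sample_rate = readBin(raw_fmt[5:8], "integer", 1, size = 4,
                              endian = "little"),
        bits_per_sample = readBin(raw_fmt[15:16], "integer", 1, size = 2,
                                  endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt$bits_per_sample == 16L) {
        samples <- readBin(con, "integer", size / 2, size = 2,
                           endian = "little", signed = TRUE) / 2^15
      } else {
        samples <- readBin(con, "numeric", size / 4, size = 4,
                           endian = "little")
      }
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2) # skip unknown chunk (word-aligned)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }

  if (is.null(fmt) || is.null(samples)) {
    stop("malformed WAV file: ", path, call. = FALSE)
  }
  if (fmt$n_channels != 1L) {
    stop("only mono WAV files are supported (got ", fmt$n_channels,
         " channels): ", path, call. = FALSE)
  }
  ok <- (fmt$audio_format == 1L && fmt$bits_per_sample == 16L) ||
    (fmt$audio_format == 3L && fmt$bits_per_sample == 32L)
  if (!ok) {
    stop("unsupported WAV encoding (format ", fmt$audio_format, ", ",
         fmt$bits_per_sample, " bits): ", path, call. = FALSE)
  }
  waveform(samples, fmt$sample_rate, bit_depth = fmt$bits_per_sample)
}

#' Write a mono WAV file
#'
#' Writes a [waveform()] as RIFF/WAVE: 16-bit integer PCM for `bit_depth` 16
#' (the low-fidelity device encoding) or 32-bit IEEE float for 32. Continuous
#' waveforms default to float output.
#'
#' @param w A [waveform()].
#' @param path Output path.
#' @param bit_depth 16 or 32; defaults to the waveform's own bit depth, or 32
#'   for continuous waveforms.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bit_depth = NULL) {
  stopifnot(is_waveform(w))
  if (is.null(bit_depth)) {
    bit_depth <- if (identical(w$bit_depth, "continuous")) 32L else w$bit_depth
  }
  if (!bit_depth %in% c(16, 32)) stop("bit_depth must be 16 or 32", call. = FALSE)

  n <- length(w$samples)
  bytes_per <- bit_depth / 8
  data_size <- n * bytes_per
  fact <- bit_depth == 32 # fact chunk is conventional for non-PCM encodings
  riff_size <- 4 + (8 + 16) + (if (fact) 12 else 0) + (8 + data_size)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(riff_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(as.integer(if (bit_depth == 16) 1L else 3L), con, size = 2,
           endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(round(w$sample_rate_hz)), con, size = 4,
           endian = "little")
  writeBin(as.integer(round(w$sample_rate_hz) * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  if (fact) {
    writeChar("fact", con, eos = NULL)
    writeBin(4L, con, size = 4, endian = "little")
    writeBin(as.integer(n), con, size = 4, endian = "little")
  }
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16) {
    ints <- pmin(pmax(round(w$samples * 2^15), -2^15), 2^15 - 1)
    writeBin(as.integer(ints), con, size = 2, endian = "little")
  } else {
    writeBin(w$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}
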
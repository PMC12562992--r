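#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader for integer PCM (8/16/24/32 bit) and IEEE
#' float32/float64 encodings.  Multichannel files are reduced to their first
#' channel (noted by a message).
#'
#' @param path Path to a `.wav` file.
#' @return List with `samples` (numeric, scaled to roughly `[-1, 1]` for
#'   integer PCM), `sample_rate` and `bits`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("cannot read WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")     # overall size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, 2,
                               endian = "little", signed = FALSE),
        channels = readBin(raw_fmt[3:4], "integer", 1, 2,
                           endian = "little", signed = FALSE),
        sample_rate = readBin(raw_fmt[5:8], "integer", 1, 4,
                              endian = "little"),
        bits = readBin(raw_fmt[15:16], "integer", 1, 2,
                       endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt: ", path)
      n <- size %/% (fmt$bits %/% 8)
      if (fmt$audio_format == 1L) {            # integer PCM
        if (fmt$bits == 8L) {
          v <- as.numeric(readBin(con, "integer", n, 1, signed = FALSE))
          samples <- (v - 128) / 128
        } else if (fmt$bits %in% c(16L, 32L)) {
          v <- readBin(con, "integer", n, fmt$bits %/% 8, endian = "little")
          samples <- v / 2^(fmt$bits - 1)
        } else if (fmt$bits == 24L) {
          raw <- readBin(con, "raw", size)
          b <- matrix(as.integer(raw), nrow = 3)
          v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
          v <- ifelse(v >= 2^23, v - 2^24, v)
          samples <- v / 2^23
        } else {
          stop(sprintf("unsupported PCM bit depth %d in %s", fmt$bits, path))
        }
      } else if (fmt$audio_format == 3L) {     # IEEE float
        samples <- readBin(con, "numeric", n, fmt$bits %/% 8,
                           endian = "little")
      } else {
        stop(sprintf("unsupported WAV encoding (format %d) in %s",
                     fmt$audio_format, path))
      }
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)    # skip unknown chunk (padded)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (fmt$channels > 1L) {
    message(sprintf("%s: %d channels; using the first", path, fmt$channels))
    samples <- samples[seq(1, length(samples), by = fmt$channels)]
  }
  list(samples = samples, sample_rate = fmt$sample_rate, bits = fmt$bits)
}

#' Write a mono WAV file
#'
#' @param samples Numeric sample vector.
#' @param sample_rate Hz.
#' @param path Output path.
#' @param format `"float32"` (default; lossless for analysis round trips) or
#'   `"pcm16"`.
#' @return The path, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path,
                      format = c("float32", "pcm16")) {
  format <- match.arg(format)
  n <- length(samples)
  bits <- if (format == "float32") 32L else 16L
  audio_format <- if (format == "float32") 3L else 1L
  bytes <- n * (bits %/% 8)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(audio_format), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * (bits %/% 8)), con, 4, endian = "little")
  writeBin(as.integer(bits %/% 8), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(bytes), con, 4, endian = "little")
  if (format == "float32") {
    writeBin(as.numeric(samples), con, 4, endian = "little")
  } else {
    v <- as.integer(round(pmax(pmin(samples, 1), -1) * 32767))
    writeBin(v, con, 2, endian = "little")
  }
  invisible(path)
}

#' Load audio into analysis frames
#'
#' Reads a WAV file, resamples to the target rate (polyphase resampling via
#' the signal package), splits into non-overlapping frames of the configured
#' length (any trailing remainder is dropped, with a message) and optionally
#' standardizes each frame to zero mean and unit standard deviation.
#'
#' @param path Path to a WAV file.
#' @param target_rate Target sample rate in Hz; default 16000.
#' @param frame_length Samples per frame; default 16384.
#' @param standardize Center and scale each frame?
#' @return List of [signal_frame()]s.
#' @export
load_audio <- function(path, target_rate = 16000, frame_length = 16384L,
                       standardize = TRUE) {
  wav <- read_wav(path)
  x <- wav$samples
  if (wav$sample_rate != target_rate) {
    r <- ratio_approx(target_rate, wav$sample_rate)
    x <- signal::resample(x, p = r[1], q = r[2])
  }
  n_frames <- length(x) %/% frame_length
  if (n_frames == 0) {
    stop(sprintf("%s: %d samples after resampling, shorter than one frame",
                 path, length(x)))
  }
  rem <- length(x) - n_frames * frame_length
  if (rem > 0) {
    message(sprintf("%s: dropping %d trailing samples (< one frame)",
                    path, rem))
  }
  lapply(seq_len(n_frames), function(i) {
    fr <- signal_frame(x[((i - 1) * frame_length + 1):(i * frame_length)],
                       target_rate,
                       label = sprintf("%s#%d", basename(path), i))
    if (standardize) standardize_frame(fr) else fr
  })
}

# Small-integer ratio p/q approximating a/b for the resampler.
ratio_approx <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  ai <- round(a)
  bi <- round(b)
  d <- g(ai, bi)
  c(ai / d, bi / d)
}

#' Write results to JSON or CSV
#'
#' Serializes a result object (a `detection_result`, a feature table, or any
#' list/data frame) with the package version and the field order fixed, so
#' identical runs produce byte-identical files.
#'
#' @param results The object to write.
#' @param path Output path.
#' @param format `"json"` or `"csv"` (CSV requires a data frame or a
#'   `detection_result`, whose `curves` table is written).
#' @return The path, invisibly.
#' @export
write_results <- function(results, path, format = c("json", "csv")) {
  format <- match.arg(format)
  version <- as.character(utils::packageVersion("tfdinfo"))
  if (format == "csv") {
    df <- if (inherits(results, "detection_result")) results$curves else
      as.data.frame(results)
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  payload <- if (inherits(results, "detection_result")) {
    cfg <- results$config
    cfg$window <- unclass(cfg$window)
    list(package = "tfdinfo", version = version,
         config = unclass(cfg), curves = results$curves)
  } else {
    list(package = "tfdinfo", version = version, results = results)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
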
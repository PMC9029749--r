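#' Construct an audio clip
#'
#' An `audio_clip` is the unit of audio handled by the package: a mono
#' real-valued waveform with amplitudes in \[-1, 1\] and a sample rate in Hz.
#'
#' @param samples Numeric vector of samples, amplitudes in \[-1, 1\].
#' @param sample_rate_hz Positive integer sample rate in Hz.
#' @param source_id Optional character label identifying the clip's origin.
#' @return An object of class `audio_clip`.
#' @export
audio_clip <- function(samples, sample_rate_hz, source_id = NULL) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  structure(
    list(
      samples = as.numeric(samples),
      sample_rate_hz = as.integer(round(sample_rate_hz)),
      source_id = source_id
    ),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf(
    "<audio_clip> %d samples @ %d Hz (%.3f s)%s\n",
    length(x$samples), x$sample_rate_hz,
    length(x$samples) / x$sample_rate_hz,
    if (is.null(x$source_id)) "" else paste0(" [", x$source_id, "]")
  ))
  invisible(x)
}

#' @export
length.audio_clip <- function(x) length(x$samples)

# full-scale divisors for integer PCM; symmetric so that write/read
# round-trips stay within half a quantization step
.pcm_full_scale <- c(`8` = 127, `16` = 32767, `24` = 8388607,
                     `32` = 2147483647)

#' Read a PCM WAV file
#'
#' Parses a RIFF/WAVE file and returns a mono [audio_clip()]. Integer PCM
#' samples (8/16/24/32-bit) are rescaled to \[-1, 1\] by the bit-depth
#' full-scale value; 8-bit data is decoded as offset binary per the RIFF
#' convention (128 = zero). IEEE-float data (32/64-bit) is used as-is.
#' Multichannel audio is averaged down to mono.
#'
#' @param path Path to a RIFF/WAVE PCM or IEEE-float file.
#' @return An [audio_clip()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop("WAV file not found: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("unsupported format: not a RIFF file: ", path, call. = FALSE)
  }
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("unsupported format: not a WAVE file: ", path, call. = FALSE)
  }

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size + size %% 2L)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, 2L,
                               signed = FALSE, endian = "little"),
        n_channels = readBin(body[3:4], "integer", 1L, 2L,
                             signed = FALSE, endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1L, 4L,
                              endian = "little"),
        bits = readBin(body[15:16], "integer", 1L, 2L,
                       signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) {
    stop("unsupported format: missing fmt chunk in ", path, call. = FALSE)
  }
  # 0xFFFE = WAVE_FORMAT_EXTENSIBLE; treated as PCM by sub-format assumption
  if (!fmt$audio_format %in% c(1L, 3L, 65534L)) {
    stop("unsupported format: compressed/non-PCM encoding (format code ",
         fmt$audio_format, ") in ", path, call. = FALSE)
  }
  if (is.null(data_raw) || length(data_raw) == 0L) {
    stop("empty audio: zero-length data chunk in ", path, call. = FALSE)
  }

  bits <- fmt$bits
  is_float <- fmt$audio_format == 3L
  n_values <- length(data_raw) %/% (bits %/% 8L)
  x <- if (is_float) {
    readBin(data_raw, "numeric", n_values, size = bits %/% 8L,
            endian = "little")
  } else if (bits == 8L) {
    (readBin(data_raw, "integer", n_values, size = 1L, signed = FALSE) -
       128) / .pcm_full_scale[["8"]]
  } else if (bits == 16L) {
    readBin(data_raw, "integer", n_values, size = 2L, signed = TRUE,
            endian = "little") / .pcm_full_scale[["16"]]
  } else if (bits == 24L) {
    b <- as.integer(data_raw)
    lo <- b[seq(1L, length(b), 3L)]
    mid <- b[seq(2L, length(b), 3L)]
    hi <- b[seq(3L, length(b), 3L)]
    v <- lo + 256 * mid + 65536 * hi
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / .pcm_full_scale[["24"]]
  } else if (bits == 32L) {
    readBin(data_raw, "integer", n_values, size = 4L,
            endian = "little") / .pcm_full_scale[["32"]]
  } else {
    stop("unsupported format: ", bits, "-bit PCM in ", path, call. = FALSE)
  }

  if (fmt$n_channels > 1L) {
    n_frames <- length(x) %/% fmt$n_channels
    x <- x[seq_len(n_frames * fmt$n_channels)]
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  x <- pmin(1, pmax(-1, x))
  audio_clip(x, fmt$sample_rate, source_id = basename(path))
}

#' Write a PCM WAV file
#'
#' Writes a mono clip as an 8- or 16-bit PCM RIFF/WAVE file (canonical
#' 44-byte header). Amplitudes outside \[-1, 1\] are clipped with a warning.
#'
#' @param clip An [audio_clip()].
#' @param path Output file path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, bit_depth = 16L) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16, got ", bit_depth, call. = FALSE)
  }
  x <- clip$samples
  if (any(abs(x) > 1)) {
    warning("amplitudes outside [-1, 1] clipped on write", call. = FALSE)
    x <- pmin(1, pmax(-1, x))
  }
  n <- length(x)
  bytes_per <- bit_depth %/% 8L
  data_size <- n * bytes_per
  pad <- data_size %% 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size + pad), con, size = 4L,
           endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")              # PCM
  writeBin(1L, con, size = 2L, endian = "little")              # mono
  writeBin(clip$sample_rate_hz, con, size = 4L, endian = "little")
  writeBin(clip$sample_rate_hz * bytes_per, con, size = 4L,
           endian = "little")                                   # byte rate
  writeBin(bytes_per, con, size = 2L, endian = "little")        # block align
  writeBin(as.integer(bit_depth), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bit_depth == 8L) {
    v <- as.integer(round(x * .pcm_full_scale[["8"]]) + 128)
    writeBin(as.raw(v), con)
  } else {
    v <- as.integer(round(x * .pcm_full_scale[["16"]]))
    writeBin(v, con, size = 2L, endian = "little")
  }
  if (pad == 1L) writeBin(as.raw(0L), con)
  invisible(path)
}

#' Decimate a clip with anti-alias filtering
#'
#' Reduces the sample rate by an integer factor. Before subsampling, a
#' zero-phase low-pass filter (order-4 Butterworth run forward and backward,
#' effective magnitude order 8) with cutoff at 0.8 x the new Nyquist removes
#' content that would alias. Used by the Stockwell representation path.
#'
#' @param clip An [audio_clip()].
#' @param factor Integer decimation factor >= 1.
#' @return An [audio_clip()] at `sample_rate_hz / factor`.
#' @export
decimate_clip <- function(clip, factor) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor)) {
    stop("`factor` must be a single integer >= 1", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(clip)
  n <- length(clip$samples)
  if (n < factor) {
    stop("clip shorter than decimation factor", call. = FALSE)
  }
  # filtfilt needs a few filter lengths of signal to settle
  if (n < 30L) {
    stop("short signal: clip too short for anti-alias filter warm-up",
         call. = FALSE)
  }
  bf <- signal::butter(4, 0.8 / factor)
  y <- signal::filtfilt(bf, clip$samples)
  y <- y[seq(1L, by = factor, length.out = n %/% factor)]
  y <- pmin(1, pmax(-1, y))
  audio_clip(y, clip$sample_rate_hz / factor, source_id = clip$source_id)
}
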
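# Time-frequency image representations of roar audio.
#
# Eight representations are supported: power spectrogram, Mel spectrogram,
# the iterated-log LM/L2M/L3M family, MFCC, a decimated Stockwell
# transform, and an embedding-over-time image. Each yields a 2-D real
# matrix (rows = frequency bins / bands / coefficients, columns = time
# frames) that downstream image classifiers consume.

#' The eight supported representation names
#'
#' @format Character vector of length 8.
#' @export
REPRESENTATIONS <- c("spectrogram", "mel", "lm", "l2m", "l3m",
                     "mfcc", "stockwell", "embedding")

#' Representation configuration
#'
#' Analysis parameters shared by the short-time transforms. Defaults target
#' low-pitched roars at 16 kHz: a 512-sample Hamming window (32 ms, long
#' enough to resolve a ~200 Hz fundamental), 50 % hop, 32 Mel bands,
#' 13 cepstral coefficients, and a x10 decimation on the Stockwell path.
#'
#' @param window_length Analysis window length in samples.
#' @param hop_length Hop between frames in samples.
#' @param fft_length FFT length (>= `window_length`; window is zero-padded).
#' @param window_kind One of "hamming", "hann", "gaussian".
#' @param n_mel_bands Number of triangular Mel filters.
#' @param n_mfcc Number of cepstral coefficients kept (<= `n_mel_bands`).
#' @param log_floor Positive floor applied inside every logarithm.
#' @param stockwell_decimation Decimation factor before the Stockwell
#'   transform.
#' @param frequency_range_hz Frequency range of the Mel filterbank; `NA`
#'   upper bound means the Nyquist frequency of the clip at hand.
#' @return A list of class `rep_config`.
#' @export
rep_config <- function(window_length = 512L, hop_length = 256L,
                       fft_length = 512L, window_kind = "hamming",
                       n_mel_bands = 32L, n_mfcc = 13L,
                       log_floor = 1e-16, stockwell_decimation = 10L,
                       frequency_range_hz = c(0, NA)) {
  if (hop_length > window_length || window_length > fft_length) {
    stop("need hop_length <= window_length <= fft_length", call. = FALSE)
  }
  if (log_floor <= 0) stop("`log_floor` must be > 0", call. = FALSE)
  window_kind <- match.arg(window_kind, c("hamming", "hann", "gaussian"))
  structure(
    list(window_length = as.integer(window_length),
         hop_length = as.integer(hop_length),
         fft_length = as.integer(fft_length),
         window_kind = window_kind,
         n_mel_bands = as.integer(n_mel_bands),
         n_mfcc = as.integer(n_mfcc),
         log_floor = log_floor,
         stockwell_decimation = as.integer(stockwell_decimation),
         frequency_range_hz = frequency_range_hz),
    class = "rep_config"
  )
}

#' Construct a time-frequency image
#'
#' @param values 2-D real matrix, rows = frequency bins / bands /
#'   coefficients, columns = time frames.
#' @param representation One of the supported representation tags.
#' @param row_axis Row-axis kind: "linear_hz", "mel", "cepstral",
#'   "stockwell_hz", or "embedding".
#' @param scaling Scaling tag: "raw", "min_max", "db", "box_n".
#' @param scaling_constant Constant used by `box_n` scaling.
#' @param row_freqs_hz Optional numeric vector of row center frequencies.
#' @return A `tf_image` object.
#' @export
tf_image <- function(values, representation, row_axis, scaling = "raw",
                     scaling_constant = NA_real_, row_freqs_hz = NULL) {
  stopifnot(is.matrix(values))
  if (any(!is.finite(values))) {
    stop("time-frequency image contains non-finite values", call. = FALSE)
  }
  representation <- match.arg(representation, REPRESENTATIONS)
  row_axis <- match.arg(row_axis, c("linear_hz", "mel", "cepstral",
                                    "stockwell_hz", "embedding"))
  structure(
    list(values = values, representation = representation,
         row_axis = row_axis, scaling = scaling,
         scaling_constant = scaling_constant, row_freqs_hz = row_freqs_hz),
    class = "tf_image"
  )
}

#' @export
print.tf_image <- function(x, ...) {
  cat(sprintf("<tf_image> %s [%s], %d x %d, scaling=%s\n",
              x$representation, x$row_axis, nrow(x$values),
              ncol(x$values), x$scaling))
  invisible(x)
}

.analysis_window <- function(kind, n) {
  k <- 0:(n - 1L)
  switch(kind,
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1L)),
         hann = 0.5 - 0.5 * cos(2 * pi * k / (n - 1L)),
         gaussian = exp(-0.5 * ((k - (n - 1L) / 2) / (0.4 * (n - 1L) / 2))^2))
}

# frames without padding or centering: 1 + floor((n - win)/hop) columns
.frame_signal <- function(x, win, hop) {
  n <- length(x)
  if (n < win) {
    stop("short signal: clip shorter than one analysis window",
         call. = FALSE)
  }
  n_frames <- 1L + (n - win) %/% hop
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(win), starts, `+`)
  matrix(x[idx], nrow = win)
}

#' Power spectrogram via the short-time Fourier transform
#'
#' Windows the clip (no padding, no centering), zero-pads each windowed
#' frame to `fft_length` and returns the one-sided power spectrum
#' `|STFT|^2`: `fft_length / 2 + 1` rows, `1 + floor((n - window) / hop)`
#' columns.
#'
#' @param clip An [audio_clip()].
#' @param cfg A [rep_config()].
#' @return A [tf_image()] with representation `"spectrogram"`.
#' @export
compute_spectrogram <- function(clip, cfg = rep_config()) {
  stopifnot(inherits(clip, "audio_clip"))
  frames <- .frame_signal(clip$samples, cfg$window_length, cfg$hop_length)
  w <- .analysis_window(cfg$window_kind, cfg$window_length)
  frames <- frames * w
  if (cfg$fft_length > cfg$window_length) {
    frames <- rbind(frames,
                    matrix(0, cfg$fft_length - cfg$window_length,
                           ncol(frames)))
  }
  spec <- Mod(stats::mvfft(frames))^2
  n_bins <- cfg$fft_length %/% 2L + 1L
  freqs <- (0:(n_bins - 1L)) * clip$sample_rate_hz / cfg$fft_length
  tf_image(spec[seq_len(n_bins), , drop = FALSE], "spectrogram",
           "linear_hz", row_freqs_hz = freqs)
}

#' Hertz to Mel conversion
#'
#' The standard Mel scale, `m = 2595 log10(1 + f / 700)`.
#'
#' @param f Frequency in Hz (>= 0), vectorized.
#' @return Mel value(s).
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("frequency must be >= 0", call. = FALSE)
  2595 * log10(1 + f / 700)
}

#' Mel to Hertz conversion (inverse of [hz_to_mel()])
#'
#' @param m Mel value(s) (>= 0).
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(m) {
  if (any(m < 0)) stop("mel value must be >= 0", call. = FALSE)
  700 * (10^(m / 2595) - 1)
}

# triangular filters spaced uniformly on the Mel scale; rows sum over the
# one-sided FFT bins they cover
.mel_filterbank <- function(n_mel, fft_length, sample_rate_hz,
                            fmin_hz, fmax_hz) {
  n_bins <- fft_length %/% 2L + 1L
  if (n_mel > n_bins) {
    stop("`n_mel_bands` exceeds the number of FFT bins", call. = FALSE)
  }
  if (n_mel < 2L) stop("`n_mel_bands` must be >= 2", call. = FALSE)
  edges_hz <- mel_to_hz(seq(hz_to_mel(fmin_hz), hz_to_mel(fmax_hz),
                            length.out = n_mel + 2L))
  bin_freqs <- (0:(n_bins - 1L)) * sample_rate_hz / fft_length
  fb <- matrix(0, n_mel, n_bins)
  for (k in seq_len(n_mel)) {
    lo <- edges_hz[k]; ce <- edges_hz[k + 1L]; hi <- edges_hz[k + 2L]
    up <- (bin_freqs - lo) / (ce - lo)
    down <- (hi - bin_freqs) / (hi - ce)
    fb[k, ] <- pmax(0, pmin(up, down))
  }
  attr(fb, "centers_hz") <- edges_hz[2:(n_mel + 1L)]
  fb
}

.resolve_frange <- function(cfg, sample_rate_hz) {
  fr <- cfg$frequency_range_hz
  if (is.na(fr[2])) fr[2] <- sample_rate_hz / 2
  fr
}

#' Mel spectrogram
#'
#' Applies a triangular Mel filterbank (filters spaced uniformly on the
#' [hz_to_mel()] scale over `cfg$frequency_range_hz`) to the power
#' spectrogram. Rows = `cfg$n_mel_bands`.
#'
#' @inheritParams compute_spectrogram
#' @return A [tf_image()] with representation `"mel"`.
#' @export
compute_mel_spectrogram <- function(clip, cfg = rep_config()) {
  spec <- compute_spectrogram(clip, cfg)
  fr <- .resolve_frange(cfg, clip$sample_rate_hz)
  fb <- .mel_filterbank(cfg$n_mel_bands, cfg$fft_length,
                        clip$sample_rate_hz, fr[1], fr[2])
  tf_image(fb %*% spec$values, "mel", "mel",
           row_freqs_hz = attr(fb, "centers_hz"))
}

#' LM spectrogram: iterated-log transform of the Mel spectrogram, step 1
#'
#' `LM = 100 * log10(S)` applied elementwise to the Mel spectrogram `S`,
#' with the configured positive floor inside the log so that the result is
#' finite on silent bins.
#'
#' @param mel_image A [tf_image()] with representation `"mel"`.
#' @param cfg A [rep_config()] (supplies `log_floor`).
#' @return A [tf_image()] with representation `"lm"`.
#' @export
compute_lm <- function(mel_image, cfg = rep_config()) {
  stopifnot(inherits(mel_image, "tf_image"))
  if (mel_image$representation != "mel") {
    stop("LM must be computed from a Mel spectrogram, got ",
         mel_image$representation, call. = FALSE)
  }
  vals <- 100 * log10(pmax(mel_image$values, cfg$log_floor))
  tf_image(vals, "lm", "mel", row_freqs_hz = mel_image$row_freqs_hz)
}

.iterated_log_step <- function(img, from, to, cfg) {
  stopifnot(inherits(img, "tf_image"))
  if (img$representation != from) {
    stop(to, " must be computed from ", from, ", got ",
         img$representation, call. = FALSE)
  }
  minref <- min(img$values)
  vals <- 100 * log10(pmax(img$values - minref, cfg$log_floor))
  tf_image(vals, to, "mel", row_freqs_hz = img$row_freqs_hz)
}

#' L2M: second iterated-log step
#'
#' `L2M = 100 * log10(LM - minref)` where `minref` is the global minimum of
#' the LM image; subtracting it shifts all values to be nonnegative before
#' the log (the configured floor keeps the minimum entry finite at
#' `100 * log10(log_floor)`). The result is invariant to any global
#' additive offset of its input.
#'
#' @param lm_image A [tf_image()] with representation `"lm"`.
#' @param cfg A [rep_config()].
#' @return A [tf_image()] with representation `"l2m"`.
#' @export
compute_l2m <- function(lm_image, cfg = rep_config()) {
  .iterated_log_step(lm_image, "lm", "l2m", cfg)
}

#' L3M: third iterated-log step
#'
#' As [compute_l2m()], applied to an L2M image.
#'
#' @param l2m_image A [tf_image()] with representation `"l2m"`.
#' @param cfg A [rep_config()].
#' @return A [tf_image()] with representation `"l3m"`.
#' @export
compute_l3m <- function(l2m_image, cfg = rep_config()) {
  .iterated_log_step(l2m_image, "l2m", "l3m", cfg)
}

#' MFCC image
#'
#' Per frame: Mel-filter the one-sided power spectrum, take the natural log
#' (with floor), apply an inverse DFT over the band axis, and keep the
#' squared magnitude of the first `n_mfcc` coefficients:
#' `|IDFT(log(mel(|DFT(frame)|^2) + floor))|^2`.
#'
#' @inheritParams compute_spectrogram
#' @return A [tf_image()] with representation `"mfcc"`,
#'   `cfg$n_mfcc` rows.
#' @export
compute_mfcc <- function(clip, cfg = rep_config()) {
  if (cfg$n_mfcc > cfg$n_mel_bands) {
    stop("`n_mfcc` must be <= `n_mel_bands`", call. = FALSE)
  }
  mel <- compute_mel_spectrogram(clip, cfg)
  logmel <- log(mel$values + cfg$log_floor)
  ceps <- Mod(stats::mvfft(logmel, inverse = TRUE) / nrow(logmel))^2
  tf_image(ceps[seq_len(cfg$n_mfcc), , drop = FALSE], "mfcc", "cepstral")
}

#' Decimated Stockwell transform magnitude
#'
#' Decimates the clip by `cfg$stockwell_decimation` (anti-aliased, see
#' [decimate_clip()]), then computes the discrete Stockwell transform in
#' its frequency-domain fast form: for voice `n`, the inverse DFT over `m`
#' of `X[m + n] * exp(-2 pi^2 m^2 / n^2)`, where `X` is the DFT of the
#' decimated signal and `m` is wrapped to `[-N/2, N/2)`. The magnitude for
#' one-sided voices `1..N/2` is returned (the zero-frequency voice, a pure
#' mean, is dropped): `N/2` rows and `N` columns for a decimated length
#' `N`.
#'
#' @inheritParams compute_spectrogram
#' @return A [tf_image()] with representation `"stockwell"`.
#' @export
compute_stockwell <- function(clip, cfg = rep_config()) {
  stopifnot(inherits(clip, "audio_clip"))
  dclip <- decimate_clip(clip, cfg$stockwell_decimation)
  x <- dclip$samples
  n <- length(x)
  if (n < 8L) {
    stop("short signal: decimated clip shorter than 8 samples",
         call. = FALSE)
  }
  X <- stats::fft(x)
  m <- 0:(n - 1L)
  m_wrapped <- ifelse(m < n / 2, m, m - n)
  n_voices <- n %/% 2L
  out <- matrix(0, n_voices, n)
  for (v in seq_len(n_voices)) {
    shifted <- X[((m + v) %% n) + 1L]
    gauss <- exp(-2 * pi^2 * m_wrapped^2 / v^2)
    out[v, ] <- Mod(stats::fft(shifted * gauss, inverse = TRUE) / n)
  }
  freqs <- seq_len(n_voices) * dclip$sample_rate_hz / n
  tf_image(out, "stockwell", "stockwell_hz", row_freqs_hz = freqs)
}

#' Deterministic stub audio embedder
#'
#' A stand-in for a pretrained 128-dimensional audio embedding network,
#' suitable for tests and offline runs: each fixed-length window is mapped
#' to a 128-vector by a seeded random projection of the window's log-Mel
#' spectrogram. Deterministic in `(seed, window_samples)`. It is labelled
#' synthetic: it carries no learned acoustic knowledge, only a stable,
#' identity-preserving linear sketch.
#'
#' @param seed Integer seed for the projection matrix.
#' @param window_samples Window length in samples consumed per column.
#' @param sample_rate_hz Sample rate the embedder expects.
#' @return A function of class `roar_embedder` mapping a numeric window to
#'   a length-128 vector, with attributes `window_samples` and
#'   `embedding_dim`.
#' @export
make_stub_embedder <- function(seed = 1L, window_samples = 2048L,
                               sample_rate_hz = 16000L) {
  if (window_samples < 256L) {
    stop("`window_samples` must be >= 256", call. = FALSE)
  }
  inner_cfg <- rep_config(window_length = 256L, hop_length = 128L,
                          fft_length = 256L, n_mel_bands = 16L)
  n_frames <- 1L + (window_samples - inner_cfg$window_length) %/%
    inner_cfg$hop_length
  feat_dim <- inner_cfg$n_mel_bands * n_frames
  proj <- .with_seed(seed, {
    matrix(stats::rnorm(128L * feat_dim) / sqrt(feat_dim), 128L, feat_dim)
  })
  f <- function(window) {
    stopifnot(length(window) == window_samples)
    wclip <- audio_clip(window, sample_rate_hz)
    mel <- compute_mel_spectrogram(wclip, inner_cfg)
    feat <- log(as.numeric(mel$values) + 1e-16)
    as.numeric(proj %*% feat)
  }
  structure(f, class = c("roar_embedder", "function"),
            window_samples = as.integer(window_samples),
            embedding_dim = 128L)
}

#' Embedding-over-time image
#'
#' Applies an audio embedder to consecutive non-overlapping windows of the
#' clip and stacks the embeddings as columns: 128 rows, one column per
#' full window.
#'
#' @param clip An [audio_clip()].
#' @param embedder An embedder such as [make_stub_embedder()] (or a
#'   registered pretrained plug-in with the same contract).
#' @return A [tf_image()] with representation `"embedding"`.
#' @export
compute_embedding_image <- function(clip, embedder) {
  stopifnot(inherits(clip, "audio_clip"), is.function(embedder))
  win <- attr(embedder, "window_samples")
  n <- length(clip$samples)
  k <- n %/% win
  if (k < 1L) {
    stop("short signal: clip shorter than one embedder window (",
         win, " samples)", call. = FALSE)
  }
  cols <- vapply(seq_len(k), function(i) {
    embedder(clip$samples[((i - 1L) * win + 1L):(i * win)])
  }, numeric(attr(embedder, "embedding_dim")))
  tf_image(matrix(cols, nrow = attr(embedder, "embedding_dim")),
           "embedding", "embedding")
}

#' Apply a scaling mode to a time-frequency image
#'
#' Three modes:
#' \describe{
#'   \item{min_max}{affine map of `[min, max]` onto `[0, 255]`}
#'   \item{db}{elementwise `10 * log10(x + 1e-16)` (requires `x >= 0`)}
#'   \item{box_n}{affine map onto `[0, constant]`; with `constant = 1000`
#'     this is the \[0-1000\] Mel normalization}
#' }
#' A constant input matrix has no range to map; `min_max` and `box_n`
#' return all-zeros with a warning rather than dividing by zero.
#'
#' @param img A [tf_image()].
#' @param mode `"min_max"`, `"db"`, or `"box_n"`.
#' @param constant Upper bound for `box_n` (> 0).
#' @return The rescaled [tf_image()] with its scaling tag updated.
#' @export
apply_scaling <- function(img, mode, constant = 1000) {
  stopifnot(inherits(img, "tf_image"))
  mode <- match.arg(mode, c("min_max", "db", "box_n"))
  x <- img$values
  out <- switch(mode,
    min_max = {
      rng <- range(x)
      if (rng[1] == rng[2]) {
        warning("constant image: min_max scaling returns all zeros",
                call. = FALSE)
        x * 0
      } else {
        (x - rng[1]) / (rng[2] - rng[1]) * 255
      }
    },
    db = {
      if (any(x < 0)) {
        stop("db scaling requires nonnegative values", call. = FALSE)
      }
      10 * log10(x + 1e-16)
    },
    box_n = {
      if (!is.numeric(constant) || constant <= 0) {
        stop("`constant` must be > 0 for box_n scaling", call. = FALSE)
      }
      rng <- range(x)
      if (rng[1] == rng[2]) {
        warning("constant image: box_n scaling returns all zeros",
                call. = FALSE)
        x * 0
      } else {
        (x - rng[1]) / (rng[2] - rng[1]) * constant
      }
    })
  tf_image(out, img$representation, img$row_axis, scaling = mode,
           scaling_constant = if (mode == "box_n") constant else NA_real_,
           row_freqs_hz = img$row_freqs_hz)
}

# separable bilinear interpolation weights, half-pixel center convention:
# output center i maps to input coordinate (i - 0.5) * n_in / n_out + 0.5
.bilinear_weights <- function(n_in, n_out) {
  w <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    xi <- (i - 0.5) * n_in / n_out + 0.5
    xi <- min(max(xi, 1), n_in)
    i0 <- floor(xi)
    i1 <- min(i0 + 1, n_in)
    frac <- xi - i0
    w[i, i0] <- w[i, i0] + (1 - frac)
    w[i, i1] <- w[i, i1] + frac
  }
  w
}

#' Render a time-frequency image as a 3-channel network input
#'
#' Affinely rescales values to `[0, 255]`, bilinearly resizes to the target
#' size (half-pixel center convention), and replicates across 3 channels. A
#' constant (degenerate) image has no contrast to map and becomes uniform
#' mid-gray 127.5 with a warning.
#'
#' @param img A [tf_image()] with at least 2 rows and 2 columns.
#' @param target_height,target_width Output size in pixels.
#' @return A numeric array `target_height x target_width x 3` in
#'   `[0, 255]`.
#' @export
to_network_image <- function(img, target_height = 64L, target_width = 64L) {
  stopifnot(inherits(img, "tf_image"))
  x <- img$values
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("image must have at least 2 rows and 2 columns", call. = FALSE)
  }
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("constant image mapped to uniform mid-gray", call. = FALSE)
    x <- matrix(127.5, nrow(x), ncol(x))
  } else {
    x <- (x - rng[1]) / (rng[2] - rng[1]) * 255
  }
  wr <- .bilinear_weights(nrow(x), target_height)
  wc <- .bilinear_weights(ncol(x), target_width)
  resized <- wr %*% x %*% t(wc)
  array(resized, dim = c(target_height, target_width, 3L))
}

#' Compute any of the eight representations by name
#'
#' Dispatcher used by the pipeline and command-line layer. The LM family is
#' chained from the Mel spectrogram automatically.
#'
#' @param clip An [audio_clip()].
#' @param representation One of `r paste(REPRESENTATIONS, collapse = ", ")`.
#' @param cfg A [rep_config()].
#' @param embedder Embedder used when `representation = "embedding"`;
#'   defaults to a seeded [make_stub_embedder()] matched to the clip's
#'   sample rate.
#' @return A [tf_image()].
#' @export
compute_representation <- function(clip, representation,
                                   cfg = rep_config(), embedder = NULL) {
  representation <- match.arg(representation, REPRESENTATIONS)
  switch(representation,
    spectrogram = compute_spectrogram(clip, cfg),
    mel = compute_mel_spectrogram(clip, cfg),
    lm = compute_lm(compute_mel_spectrogram(clip, cfg), cfg),
    l2m = compute_l2m(
      compute_lm(compute_mel_spectrogram(clip, cfg), cfg), cfg),
    l3m = compute_l3m(compute_l2m(
      compute_lm(compute_mel_spectrogram(clip, cfg), cfg), cfg), cfg),
    mfcc = compute_mfcc(clip, cfg),
    stockwell = compute_stockwell(clip, cfg),
    embedding = {
      if (is.null(embedder)) {
        embedder <- make_stub_embedder(
          seed = 1L,
          window_samples = min(2048L, length(clip$samples)),
          sample_rate_hz = clip$sample_rate_hz
        )
      }
      compute_embedding_image(clip, embedder)
    })
}

#' Export a time-frequency image as an 8-bit grayscale PNG
#'
#' Convenience for visual inspection; requires the `png` package.
#'
#' @param img A [tf_image()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
export_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the `png` package is required for PNG export", call. = FALSE)
  }
  x <- img$values
  rng <- range(x)
  x <- if (rng[1] == rng[2]) x * 0 + 0.5 else (x - rng[1]) / diff(rng)
  png::writePNG(x[rev(seq_len(nrow(x))), , drop = FALSE], path)
  invisible(path)
}
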
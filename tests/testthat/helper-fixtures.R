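# Shared fixtures and independent oracles. Expensive fixtures (the
# field-shaped synthetic dataset and its rendered images) are built once
# per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

# analysis settings matched to the 8 kHz desk-scale fixtures
fixture_rep_cfg <- function() {
  rep_config(window_length = 256L, hop_length = 128L, fft_length = 256L,
             n_mel_bands = 32L, n_mfcc = 13L)
}

# field-shaped dataset: 5 individuals x 4 day-groups x 4 bouts/day
fixture_dataset <- function(noise_snr_db = 25) {
  key <- paste0("ds_", noise_snr_db)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_dataset(
      sample_rate_hz = 8000L, noise_snr_db = noise_snr_db, seed = 101L
    )
  }
  .fixture_cache[[key]]
}

fixture_images <- function(representation = "lm", noise_snr_db = 25) {
  key <- paste0("img_", representation, "_", noise_snr_db)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- extract_images(
      fixture_dataset(noise_snr_db), representation, fixture_rep_cfg()
    )
  }
  .fixture_cache[[key]]
}

fixture_labels <- function(noise_snr_db = 25) {
  ds <- fixture_dataset(noise_snr_db)
  labs <- vapply(ds$samples, `[[`, character(1), "individual_id")
  names(labs) <- vapply(ds$samples, `[[`, character(1), "sample_id")
  labs
}

# direct O(N^2) DFT, the oracle for all FFT-based transforms
direct_dft <- function(x, inverse = FALSE) {
  n <- length(x)
  sgn <- if (inverse) 2i else -2i
  vapply(0:(n - 1L), function(k) {
    sum(x * exp(sgn * pi * k * (0:(n - 1L)) / n))
  }, complex(1))
}

# independently coded Hamming window (the package default)
oracle_hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# independently coded triangular Mel filterbank
oracle_mel_fb <- function(n_mel, nfft, sr, fmin, fmax) {
  m <- function(f) 2595 * log10(1 + f / 700)
  minv <- function(v) 700 * (10^(v / 2595) - 1)
  edges <- minv(seq(m(fmin), m(fmax), length.out = n_mel + 2))
  bins <- (0:(nfft %/% 2)) * sr / nfft
  fb <- matrix(0, n_mel, length(bins))
  for (k in seq_len(n_mel)) {
    fb[k, ] <- pmax(0, pmin((bins - edges[k]) / (edges[k + 1] - edges[k]),
                            (edges[k + 2] - bins) /
                              (edges[k + 2] - edges[k + 1])))
  }
  fb
}

# brute-force discrete Stockwell transform: per voice, a periodized
# Gaussian window of width sigma = N / voice, direct sums
oracle_stockwell <- function(x) {
  n <- length(x)
  out <- matrix(0, n %/% 2L, n)
  for (v in seq_len(n %/% 2L)) {
    sigma <- n / v
    for (j in seq_len(n)) {
      acc <- 0 + 0i
      for (k in seq_len(n)) {
        g <- sum(exp(-((k - j) + n * (-8:8))^2 / (2 * sigma^2))) /
          (sigma * sqrt(2 * pi))
        acc <- acc + x[k] * g * exp(-2i * pi * v * (k - 1) / n)
      }
      out[v, j] <- Mod(acc)
    }
  }
  out
}

# EER oracle: walk the pooled ROC curve over every distinct threshold and
# linearly interpolate the FAR/FRR crossing
oracle_eer <- function(genuine, impostor) {
  sc <- sort(unique(c(genuine, impostor)))
  mids <- if (length(sc) > 1) (sc[-1] + sc[-length(sc)]) / 2 else numeric(0)
  ts <- c(sc[1] - 1, mids, sc[length(sc)] + 1)
  far <- sapply(ts, function(t) mean(impostor >= t))
  frr <- sapply(ts, function(t) mean(genuine < t))
  d <- far - frr
  hit <- which(abs(d) < 1e-12)
  if (length(hit) > 0) return(100 * far[hit[1]])
  j <- which(d < 0)[1]
  i <- j - 1
  s <- d[i] / (d[i] - d[j])
  100 * (far[i] + s * (far[j] - far[i]))
}

# random grouping metadata with valid structure (no audio), for fold-plan
# property tests
random_manifest <- function(seed) {
  set.seed(seed)
  n_ind <- sample(2:5, 1)
  n_days <- sample(2:4, 1)
  bouts_per_day <- sample(1:3, 1)
  rows <- list()
  for (i in seq_len(n_ind)) {
    for (d in seq_len(n_days)) {
      for (b in seq_len(bouts_per_day)) {
        size <- sample(1:3, 1)
        for (k in seq_len(size)) {
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = sprintf("i%d_d%d_b%d_s%d", i, d, b, k),
            individual_id = sprintf("ind%d", i),
            day_id = sprintf("d%d", d),
            bout_id = sprintf("i%d_d%d_b%d", i, d, b),
            index_in_bout = k,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}

# wrap a manifest into a minimal roar_dataset (silent one-sample clips)
manifest_to_dataset <- function(m) {
  samples <- lapply(seq_len(nrow(m)), function(i) {
    list(clip = audio_clip(0, 8000L),
         sample_id = m$sample_id[i], individual_id = m$individual_id[i],
         day_id = m$day_id[i], bout_id = m$bout_id[i],
         index_in_bout = m$index_in_bout[i])
  })
  structure(
    list(samples = samples,
         class_labels = sort(unique(m$individual_id)),
         sample_rate_hz = 8000L),
    class = "roar_dataset"
  )
}

# nearest-centroid LOOCV on mean per-clip log power spectra: the
# separability oracle for the synthetic generator
nearest_centroid_loocv <- function(dataset) {
  cfg <- fixture_rep_cfg()
  feats <- t(vapply(dataset$samples, function(s) {
    sp <- compute_spectrogram(s$clip, cfg)$values
    log(rowMeans(sp) + 1e-16)
  }, numeric(cfg$fft_length %/% 2L + 1L)))
  labs <- vapply(dataset$samples, `[[`, character(1), "individual_id")
  correct <- 0L
  for (i in seq_len(nrow(feats))) {
    cents <- sapply(sort(unique(labs[-i])), function(cl) {
      colMeans(feats[-i, , drop = FALSE][labs[-i] == cl, , drop = FALSE])
    })
    pred <- colnames(cents)[which.min(colSums((cents - feats[i, ])^2))]
    correct <- correct + (pred == labs[i])
  }
  correct / nrow(feats)
}
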
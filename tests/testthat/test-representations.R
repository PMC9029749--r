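# The eight time-frequency representations, their oracles, scaling modes,
# and the network-image rendering.

test_that("spectrogram frame geometry and tone localization are exact", {
  sr <- 16000L
  clip <- audio_clip(sin(2 * pi * 1000 * (0:(sr - 1)) / sr), sr)
  cfg <- rep_config(window_length = 512L, hop_length = 256L,
                    fft_length = 512L)
  img <- compute_spectrogram(clip, cfg)
  expect_equal(nrow(img$values), 257L)
  expect_equal(ncol(img$values), 1L + (sr - 512L) %/% 256L)
  # 1000 Hz = bin 32 at 16 kHz / 512 -> row 33 (rows count from bin 0)
  expect_true(all(apply(img$values, 2L, which.max) == 33L))
})

test_that("an all-zero clip gives an all-zero spectrogram", {
  cfg <- rep_config(window_length = 64L, hop_length = 32L,
                    fft_length = 64L)
  img <- compute_spectrogram(audio_clip(numeric(256), 8000L), cfg)
  expect_true(all(img$values == 0))
})

test_that("spectrogram columns match a direct O(N^2) DFT oracle", {
  set.seed(7)
  x <- runif(256, -1, 1)
  cfg <- rep_config(window_length = 64L, hop_length = 32L,
                    fft_length = 64L)
  img <- compute_spectrogram(audio_clip(x, 8000L), cfg)
  w <- oracle_hamming(64L)
  for (j in c(1L, 3L, ncol(img$values))) {
    frame <- x[((j - 1L) * 32L + 1L):((j - 1L) * 32L + 64L)] * w
    ref <- Mod(direct_dft(frame))^2
    expect_equal(img$values[, j], ref[1:33], tolerance = 1e-8)
  }
})

test_that("the Mel scale matches its closed form and is monotone", {
  expect_identical(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2))
  f <- seq(0, 8000, by = 50)
  expect_true(all(diff(hz_to_mel(f)) > 0))
  expect_error(hz_to_mel(-1), ">= 0")
  expect_equal(mel_to_hz(hz_to_mel(440)), 440, tolerance = 1e-12)
})

test_that("Mel filterbank geometry: band-center tones excite their band", {
  sr <- 8000L
  cfg <- rep_config(window_length = 256L, hop_length = 128L,
                    fft_length = 256L, n_mel_bands = 16L)
  # probe a few interior bands at their center frequencies
  fb <- roarid:::.mel_filterbank(16L, 256L, sr, 0, sr / 2)
  centers <- attr(fb, "centers_hz")
  for (k in c(4L, 8L, 12L)) {
    clip <- audio_clip(sin(2 * pi * centers[k] * (0:2047) / sr), sr)
    img <- compute_mel_spectrogram(clip, cfg)
    expect_equal(unname(which.max(rowMeans(img$values))), k)
  }
})

test_that("Mel spectrogram of noise is positive everywhere, of silence zero", {
  set.seed(8)
  cfg <- rep_config(window_length = 256L, hop_length = 128L,
                    fft_length = 256L, n_mel_bands = 16L)
  noise <- compute_mel_spectrogram(audio_clip(runif(2048, -1, 1), 8000L),
                                   cfg)
  expect_true(all(noise$values > 0))
  silence <- compute_mel_spectrogram(audio_clip(numeric(2048), 8000L), cfg)
  expect_true(all(silence$values == 0))
  expect_error(
    compute_mel_spectrogram(audio_clip(runif(2048), 8000L),
                            rep_config(window_length = 256L,
                                       hop_length = 128L,
                                       fft_length = 256L,
                                       n_mel_bands = 200L)),
    "exceeds"
  )
})

test_that("LM is 100 log10 with exact landmark values", {
  cfg <- rep_config()
  base <- tf_image(matrix(c(1, 100, 10, 10), 2, 2), "mel", "mel")
  lm <- compute_lm(base, cfg)
  expect_equal(lm$values, matrix(c(0, 200, 100, 100), 2, 2))
  expect_identical(lm$representation, "lm")
  expect_error(compute_lm(lm, cfg), "Mel spectrogram")
})

test_that("L2M hand example, constant inputs, and offset invariance", {
  cfg <- rep_config()  # log_floor 1e-16
  lm <- tf_image(matrix(c(0, 100), 1, 2), "lm", "mel")
  l2m <- compute_l2m(lm, cfg)
  expect_equal(l2m$values, matrix(c(100 * log10(1e-16), 200), 1, 2))

  const <- compute_l2m(tf_image(matrix(7, 3, 3), "lm", "mel"), cfg)
  expect_true(all(const$values == 100 * log10(1e-16)))

  set.seed(9)
  x <- matrix(rnorm(24), 4, 6)
  a <- compute_l2m(tf_image(x, "lm", "mel"), cfg)
  b <- compute_l2m(tf_image(x + 123.45, "lm", "mel"), cfg)
  expect_equal(a$values, b$values)
  # chain order is enforced
  expect_error(compute_l3m(a, cfg), NA)
  expect_error(compute_l3m(tf_image(x, "lm", "mel"), cfg), "l2m")
  l3 <- compute_l3m(a, cfg)
  c2 <- compute_l3m(compute_l2m(tf_image(x + 5, "lm", "mel"), cfg), cfg)
  expect_equal(l3$values, c2$values)
})

test_that("MFCC matches a direct evaluation of its defining formula", {
  set.seed(10)
  x <- runif(256, -1, 1)
  sr <- 8000L
  cfg <- rep_config(window_length = 64L, hop_length = 32L,
                    fft_length = 64L, n_mel_bands = 12L, n_mfcc = 5L)
  img <- compute_mfcc(audio_clip(x, sr), cfg)
  expect_equal(nrow(img$values), 5L)

  w <- oracle_hamming(64L)
  fb <- oracle_mel_fb(12L, 64L, sr, 0, sr / 2)
  for (j in c(1L, 4L, ncol(img$values))) {
    frame <- x[((j - 1L) * 32L + 1L):((j - 1L) * 32L + 64L)] * w
    p <- as.numeric(fb %*% (Mod(direct_dft(frame))^2)[1:33])
    lp <- log(p + 1e-16)
    ceps <- Mod(direct_dft(lp, inverse = TRUE) / 12)^2
    expect_equal(img$values[, j], ceps[1:5], tolerance = 1e-8)
  }
})

test_that("MFCC of silence is column-constant; gain shifts spare coefficient 2", {
  cfg <- rep_config(window_length = 64L, hop_length = 32L,
                    fft_length = 64L, n_mel_bands = 12L, n_mfcc = 5L)
  img <- compute_mfcc(audio_clip(numeric(256), 8000L), cfg)
  expect_true(all(apply(img$values, 1L, function(r) diff(range(r)) == 0)))

  set.seed(11)
  x <- runif(512, -0.5, 0.5)
  a <- compute_mfcc(audio_clip(x, 8000L), cfg)
  b <- compute_mfcc(audio_clip(pmin(1, 2 * x), 8000L), cfg)
  expect_identical(order(a$values[2L, ]), order(b$values[2L, ]))
  expect_error(compute_mfcc(audio_clip(x, 8000L),
                            rep_config(n_mel_bands = 10L, n_mfcc = 11L)),
               "n_mfcc")
})

test_that("the fast Stockwell transform matches the brute-force definition", {
  set.seed(12)
  x <- rnorm(64)
  x <- x / max(abs(x))
  cfg <- rep_config(stockwell_decimation = 1L)
  fast <- compute_stockwell(audio_clip(x, 640L), cfg)$values
  brute <- oracle_stockwell(x)
  expect_equal(dim(fast), c(32L, 64L))
  expect_lt(max(abs(fast - brute)) / max(brute), 1e-6)
})

test_that("Stockwell localizes tones and handles degenerate inputs", {
  cfg <- rep_config(stockwell_decimation = 1L)
  tone <- audio_clip(sin(2 * pi * 10 * (0:63) / 64), 64L)
  img <- compute_stockwell(tone, cfg)$values
  expect_true(all(apply(img[, 16:48], 2L, which.max) == 10L))
  zero <- compute_stockwell(audio_clip(numeric(64), 64L), cfg)$values
  expect_true(all(zero == 0))
  expect_error(compute_stockwell(audio_clip(numeric(6), 64L), cfg), "short")
})

test_that("Stockwell path decimates by the configured factor", {
  clip <- audio_clip(sin(2 * pi * 30 * (0:7999) / 8000), 8000L)
  img <- compute_stockwell(clip, rep_config(stockwell_decimation = 10L))
  expect_equal(ncol(img$values), 800L)   # columns = decimated length
  expect_equal(nrow(img$values), 400L)
})

test_that("the stub embedder is deterministic with one column per window", {
  emb <- make_stub_embedder(seed = 4L, window_samples = 1024L,
                            sample_rate_hz = 8000L)
  clip <- audio_clip(sin(2 * pi * 200 * (0:4095) / 8000), 8000L)
  a <- compute_embedding_image(clip, emb)
  b <- compute_embedding_image(clip, emb)
  expect_identical(a, b)
  expect_equal(dim(a$values), c(128L, 4L))
  expect_error(
    compute_embedding_image(audio_clip(numeric(512), 8000L), emb),
    "short"
  )
})

test_that("embeddings separate different synthetic individuals", {
  emb <- make_stub_embedder(seed = 4L, window_samples = 1024L,
                            sample_rate_hz = 8000L)
  pa <- make_individual_profile(1L, "a", f0_range_hz = c(150, 170))
  pb <- make_individual_profile(1L, "b", f0_range_hz = c(230, 250))
  ca <- synthesize_roar(pa, 0.5, 8000L, Inf, seed = 1L)
  cb <- synthesize_roar(pb, 0.5, 8000L, Inf, seed = 1L)
  ma <- rowMeans(compute_embedding_image(ca, emb)$values)
  mb <- rowMeans(compute_embedding_image(cb, emb)$values)
  expect_gt(sqrt(sum((ma - mb)^2)), 0)
})

test_that("scaling modes hit their exact landmarks", {
  img <- tf_image(matrix(0:10, 1, 11), "mel", "mel")
  mm <- apply_scaling(img, "min_max")
  expect_equal(range(mm$values), c(0, 255))
  expect_equal(mm$values[1, 11], 255)
  # idempotence
  expect_equal(apply_scaling(mm, "min_max")$values, mm$values)

  zero <- apply_scaling(tf_image(matrix(0, 2, 2), "mel", "mel"), "db")
  expect_true(all(zero$values == -160))
  expect_error(
    apply_scaling(tf_image(matrix(c(-1, 1), 1, 2), "mel", "mel"), "db"),
    "nonnegative"
  )

  bx <- apply_scaling(img, "box_n", constant = 1000)
  expect_equal(range(bx$values), c(0, 1000))
  expect_error(apply_scaling(img, "box_n", constant = -1), "> 0")

  expect_warning(
    flat <- apply_scaling(tf_image(matrix(5, 2, 2), "mel", "mel"),
                          "min_max"),
    "constant"
  )
  expect_true(all(flat$values == 0))
})

test_that("every representation is finite under every scaling on generator output", {
  ds <- fixture_dataset()
  clip <- ds$samples[[1]]$clip
  cfg <- fixture_rep_cfg()
  emb <- make_stub_embedder(seed = 1L, window_samples = 1024L,
                            sample_rate_hz = clip$sample_rate_hz)
  for (rep_name in REPRESENTATIONS) {
    img <- compute_representation(clip, rep_name, cfg, embedder = emb)
    expect_true(all(is.finite(img$values)), label = rep_name)
    for (mode in c("min_max", "box_n")) {
      scaled <- apply_scaling(img, mode, constant = 1000)
      expect_true(all(is.finite(scaled$values)),
                  label = paste(rep_name, mode))
    }
    if (all(img$values >= 0)) {
      expect_true(all(is.finite(apply_scaling(img, "db")$values)),
                  label = paste(rep_name, "db"))
    }
  }
})

test_that("network-image rendering: identity, degenerate, and bilinear mean", {
  # already-target-sized image spanning [0, 255] passes through
  set.seed(13)
  m <- matrix(runif(64 * 64, 0, 255), 64, 64)
  m[1, 1] <- 0; m[64, 64] <- 255
  img <- tf_image(m, "mel", "mel")
  out <- to_network_image(img, 64L, 64L)
  expect_equal(out[, , 1], m, tolerance = 1e-12)
  expect_equal(out[, , 2], out[, , 1])
  expect_equal(out[, , 3], out[, , 1])

  expect_warning(
    flat <- to_network_image(tf_image(matrix(3, 4, 4), "mel", "mel"),
                             8L, 8L),
    "mid-gray"
  )
  expect_true(all(flat == 127.5))

  # 2x downsize averages each 2x2 block exactly
  big <- matrix(runif(64, 0, 255), 8, 8)
  big[1, 1] <- 0; big[8, 8] <- 255
  small <- to_network_image(tf_image(big, "mel", "mel"), 4L, 4L)[, , 1]
  ref <- 0.25 * (big[seq(1, 8, 2), seq(1, 8, 2)] +
                   big[seq(2, 8, 2), seq(1, 8, 2)] +
                   big[seq(1, 8, 2), seq(2, 8, 2)] +
                   big[seq(2, 8, 2), seq(2, 8, 2)])
  expect_equal(small, ref, tolerance = 1e-12)

  expect_error(to_network_image(tf_image(matrix(1:2, 1, 2), "mel", "mel")),
               "2 rows")
})
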
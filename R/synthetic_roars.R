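# Seeded synthesis of labelled roar datasets.
#
# The generator emulates the structure of a field dataset of male lion
# roars: a handful of individuals, each recorded over several days, with
# roars arriving in bouts of 1-3 samples. Individuals carry a low-F0
# harmonic "voice" (source-filter model: harmonic stack with -6 dB/octave
# rolloff shaped by 2-3 Gaussian formant resonances) so that identity is
# recoverable from the spectra, and samples within a bout share correlated
# pitch offsets so that group-wise cross-validation designs matter.

# run `code` under a temporary RNG state; the caller's stream is untouched
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# fold a character label into a 31-bit integer stream offset
.label_seed <- function(label) {
  codes <- utf8ToInt(as.character(label))
  s <- 0
  for (cc in codes) s <- (s * 131 + cc) %% 2147483647
  as.integer(s)
}

#' Draw an individual's vocal profile
#'
#' A profile parameterizes one synthetic individual's voice: a base
#' fundamental frequency (lions roar at low F0, by default in
#' \[150, 250\] Hz), an F0 contour (initial rise to a peak, then a power-law
#' fall), 2-3 formant resonance centers, a jitter fraction (slow random F0
#' wobble), and an amplitude envelope (attack fraction, decay exponent).
#'
#' @param seed Integer seed; the draw is deterministic in `(seed,
#'   individual_id)`.
#' @param individual_id Character label for the individual.
#' @param f0_range_hz Range the base F0 is drawn from (Hz).
#' @param formant_range_hz Range the formant centers are drawn from (Hz).
#' @return An object of class `individual_profile`.
#' @export
make_individual_profile <- function(seed, individual_id,
                                    f0_range_hz = c(150, 250),
                                    formant_range_hz = c(300, 900)) {
  .with_seed(seed + .label_seed(individual_id), {
    n_formants <- sample(2:3, 1L)
    structure(
      list(
        individual_id = as.character(individual_id),
        f0_base_hz = stats::runif(1, f0_range_hz[1], f0_range_hz[2]),
        f0_contour = c(
          rise_fraction = stats::runif(1, 0.10, 0.25),
          peak_multiplier = stats::runif(1, 1.02, 1.08),
          fall_exponent = stats::runif(1, 0.8, 1.6)
        ),
        formant_centers_hz = sort(stats::runif(n_formants,
                                               formant_range_hz[1],
                                               formant_range_hz[2])),
        formant_bw_hz = stats::runif(n_formants, 60, 120),
        jitter_fraction = stats::runif(1, 0.005, 0.03),
        amplitude_envelope = c(
          attack_fraction = stats::runif(1, 0.05, 0.2),
          decay_exponent = stats::runif(1, 0.8, 2.0)
        )
      ),
      class = "individual_profile"
    )
  })
}

#' Instantaneous fundamental frequency of a profile's contour
#'
#' The deterministic (jitter-free) F0 at time `t` of a roar of duration
#' `duration_s`: linear rise from the base F0 to `peak_multiplier` x base
#' over the first `rise_fraction` of the clip, then a power-law relaxation
#' back towards the base F0.
#'
#' @param profile An [make_individual_profile()] object.
#' @param t Time(s) in seconds, in \[0, duration_s\].
#' @param duration_s Roar duration in seconds.
#' @return F0 in Hz, vectorized over `t`.
#' @export
f0_at <- function(profile, t, duration_s) {
  rf <- profile$f0_contour[["rise_fraction"]]
  pm <- profile$f0_contour[["peak_multiplier"]]
  fe <- profile$f0_contour[["fall_exponent"]]
  u <- t / duration_s
  mult <- ifelse(
    u < rf,
    1 + (pm - 1) * u / rf,
    1 + (pm - 1) * pmax(0, (1 - (u - rf) / (1 - rf)))^fe
  )
  profile$f0_base_hz * mult
}

#' Synthesize one roar
#'
#' Additive harmonic synthesis: a stack of harmonics of the time-varying F0
#' contour (all harmonics up to 95 % of Nyquist, at least 10 when the
#' sample rate allows), with -6 dB/octave source rolloff shaped by the
#' profile's Gaussian formant resonances, multiplied by an attack/decay
#' amplitude envelope, plus additive white Gaussian noise at the requested
#' SNR. The peak amplitude is normalized to 0.95.
#'
#' @param profile An [make_individual_profile()] object.
#' @param duration_s Duration in seconds, in \[0.3, 5.0\].
#' @param sample_rate_hz Sample rate; must be >= 4 x the highest formant
#'   center.
#' @param noise_snr_db Signal-to-noise ratio in dB; `Inf` for no noise.
#' @param seed Integer seed; output is bit-identical for identical inputs.
#' @param jitter_seed Optional separate seed for the slow pitch-wobble
#'   realization (defaults to `seed`). Roars within one bout share a
#'   wobble realization — they are temporally adjacent repeats of the same
#'   vocal gesture — while their additive noise stays independent.
#' @return An [audio_clip()].
#' @export
synthesize_roar <- function(profile, duration_s, sample_rate_hz,
                            noise_snr_db = Inf, seed = 1L,
                            jitter_seed = NULL) {
  stopifnot(inherits(profile, "individual_profile"))
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      duration_s < 0.3 || duration_s > 5.0) {
    stop("`duration_s` must be in [0.3, 5.0] seconds", call. = FALSE)
  }
  fmax <- max(profile$formant_centers_hz)
  if (sample_rate_hz < 4 * fmax) {
    stop("`sample_rate_hz` must be >= 4 x the highest formant center (",
         4 * fmax, " Hz)", call. = FALSE)
  }
  .with_seed(seed, {
    sr <- as.integer(sample_rate_hz)
    n <- as.integer(round(duration_s * sr))
    t <- (seq_len(n) - 1L) / sr

    f0 <- f0_at(profile, t, duration_s)
    # slow multiplicative jitter: random knots every 50 ms, linearly
    # interpolated, scaled by the profile's jitter fraction
    if (profile$jitter_fraction > 0) {
      n_knots <- max(2L, as.integer(ceiling(duration_s / 0.05)) + 1L)
      knots <- if (is.null(jitter_seed)) stats::rnorm(n_knots)
               else .with_seed(jitter_seed, stats::rnorm(n_knots))
      wob <- stats::approx(seq(0, duration_s, length.out = n_knots), knots,
                           xout = t)$y
      f0 <- f0 * (1 + profile$jitter_fraction * wob)
    }
    phase <- 2 * pi * cumsum(f0) / sr

    f0_mean <- mean(f0)
    n_harm <- max(1L, floor(0.95 * (sr / 2) / max(f0)))
    hfreq <- f0_mean * seq_len(n_harm)
    # source rolloff (-6 dB/octave) times vocal-tract formant gains
    gain <- 1 / seq_len(n_harm)
    res <- rep(0.05, n_harm)
    for (j in seq_along(profile$formant_centers_hz)) {
      res <- res + exp(-(hfreq - profile$formant_centers_hz[j])^2 /
                         (2 * profile$formant_bw_hz[j]^2))
    }
    gain <- gain * res

    x <- numeric(n)
    for (h in seq_len(n_harm)) {
      x <- x + gain[h] * sin(h * phase)
    }

    env <- .roar_envelope(t, duration_s, profile$amplitude_envelope)
    x <- x * env

    if (is.finite(noise_snr_db)) {
      p_sig <- mean(x^2)
      p_noise <- p_sig / 10^(noise_snr_db / 10)
      x <- x + stats::rnorm(n, sd = sqrt(p_noise))
    }
    x <- 0.95 * x / max(abs(x))
    audio_clip(x, sr, source_id = profile$individual_id)
  })
}

.roar_envelope <- function(t, duration_s, env_pars) {
  af <- env_pars[["attack_fraction"]]
  de <- env_pars[["decay_exponent"]]
  u <- t / duration_s
  ifelse(u < af, u / af, pmax(0, (1 - u) / (1 - af))^de)
}

#' Generate a labelled synthetic roar dataset
#'
#' Builds a full dataset with the grouping structure of a multi-day field
#' study: `n_individuals` lions, each with `day_groups_per_individual`
#' recording days, each day holding `bouts_per_day` bouts whose sizes are
#' drawn uniformly from `1..max_bout_size`. Identity cues are stratified
#' (each individual's base F0 is drawn from its own band of `f0_range_hz`);
#' roars within a bout share a +/-2 % F0 offset plus one pitch-wobble
#' realization, and days carry a +/-4 % offset (day-to-day drift in the
#' animal's condition), so bout- and day-level correlation is present by
#' construction and grouped cross-validation designs are genuinely harder
#' than per-sample ones.
#'
#' The defaults emulate the shape of the motivating field study: 5 males x
#' 4 day-groups (20 (individual, day) groups) x 4 bouts/day with bout sizes
#' in \{1, 2, 3\}, about 160 samples in total.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param day_groups_per_individual Recording days per individual (>= 2).
#' @param bouts_per_day Bouts per (individual, day) group (>= 1).
#' @param max_bout_size Maximum roars kept per bout (1-3).
#' @param sample_rate_hz Sample rate of the synthesized audio.
#' @param noise_snr_db Additive-noise SNR in dB (`Inf` = clean).
#' @param seed Master seed; the whole dataset (metadata and audio) is a
#'   pure function of it.
#' @param duration_range_s Range roar durations are drawn from (seconds).
#' @param f0_range_hz Overall F0 range partitioned across individuals.
#' @return An object of class `roar_dataset`: list with `samples` (each a
#'   list with `clip`, `sample_id`, `individual_id`, `day_id`, `bout_id`,
#'   `index_in_bout`) and `class_labels`.
#' @export
generate_dataset <- function(n_individuals = 5L,
                             day_groups_per_individual = 4L,
                             bouts_per_day = 4L,
                             max_bout_size = 3L,
                             sample_rate_hz = 16000L,
                             noise_snr_db = 25,
                             seed = 1L,
                             duration_range_s = c(0.5, 0.9),
                             f0_range_hz = c(150, 250)) {
  if (n_individuals < 2L) stop("need >= 2 individuals", call. = FALSE)
  if (day_groups_per_individual < 2L) {
    stop("need >= 2 day groups per individual (day-wise cross-validation ",
         "would otherwise leave a class untrainable)", call. = FALSE)
  }
  if (bouts_per_day < 1L) stop("need >= 1 bout per day", call. = FALSE)
  if (max_bout_size < 1L || max_bout_size > 3L) {
    stop("`max_bout_size` must be in 1..3 (only the first three roars of ",
         "a bout are retained)", call. = FALSE)
  }

  ids <- sprintf("lion%02d", seq_len(n_individuals))
  # per-individual F0 band: stratify so identities stay separable
  band <- diff(f0_range_hz) / n_individuals
  profiles <- lapply(seq_len(n_individuals), function(i) {
    make_individual_profile(
      seed, ids[i],
      f0_range_hz = c(f0_range_hz[1] + (i - 1) * band,
                      f0_range_hz[1] + i * band)
    )
  })
  names(profiles) <- ids

  samples <- list()
  .with_seed(seed + 7919L, {
    for (i in seq_len(n_individuals)) {
      prof <- profiles[[i]]
      for (d in seq_len(day_groups_per_individual)) {
        day_id <- sprintf("day%02d", d)
        day_f0 <- 1 + stats::runif(1, -0.04, 0.04)
        for (b in seq_len(bouts_per_day)) {
          bout_id <- sprintf("%s_%s_bout%02d", ids[i], day_id, b)
          bout_f0 <- 1 + stats::runif(1, -0.02, 0.02)
          bout_size <- sample.int(max_bout_size, 1L)
          bout_dur <- stats::runif(1, duration_range_s[1],
                                   duration_range_s[2])
          bout_jitter_seed <- sample.int(2147483646L, 1L)
          for (k in seq_len(bout_size)) {
            dur <- bout_dur * stats::runif(1, 0.97, 1.03)
            clip_seed <- sample.int(2147483646L, 1L)
            prof_k <- prof
            prof_k$f0_base_hz <- prof$f0_base_hz * day_f0 * bout_f0
            clip <- synthesize_roar(prof_k, dur, sample_rate_hz,
                                    noise_snr_db, seed = clip_seed,
                                    jitter_seed = bout_jitter_seed)
            samples[[length(samples) + 1L]] <- list(
              clip = clip,
              sample_id = sprintf("%s_s%d", bout_id, k),
              individual_id = ids[i],
              day_id = day_id,
              bout_id = bout_id,
              index_in_bout = k
            )
          }
        }
      }
    }
  })

  structure(
    list(samples = samples, class_labels = ids,
         sample_rate_hz = as.integer(sample_rate_hz)),
    class = "roar_dataset"
  )
}

#' @export
print.roar_dataset <- function(x, ...) {
  m <- dataset_manifest(x)
  cat(sprintf(
    "<roar_dataset> %d samples, %d individuals, %d (individual, day) groups, %d bouts @ %d Hz\n",
    nrow(m), length(x$class_labels),
    nrow(unique(m[, c("individual_id", "day_id")])),
    length(unique(m$bout_id)), x$sample_rate_hz
  ))
  invisible(x)
}

#' Metadata manifest of a dataset
#'
#' @param dataset A [generate_dataset()] result.
#' @return A data.frame with one row per sample: `sample_id`,
#'   `individual_id`, `day_id`, `bout_id`, `index_in_bout`, `n_samples`,
#'   `duration_s`.
#' @export
dataset_manifest <- function(dataset) {
  stopifnot(inherits(dataset, "roar_dataset"))
  do.call(rbind, lapply(dataset$samples, function(s) {
    data.frame(
      sample_id = s$sample_id,
      individual_id = s$individual_id,
      day_id = s$day_id,
      bout_id = s$bout_id,
      index_in_bout = s$index_in_bout,
      n_samples = length(s$clip$samples),
      duration_s = length(s$clip$samples) / s$clip$sample_rate_hz,
      stringsAsFactors = FALSE
    )
  }))
}

#' Write a dataset to disk as WAV files plus a CSV manifest
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @param bit_depth PCM bit depth for the WAV files (8 or 16).
#' @return Path to the written manifest CSV, invisibly.
#' @export
write_dataset <- function(dataset, dir, bit_depth = 16L) {
  stopifnot(inherits(dataset, "roar_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- dataset_manifest(dataset)
  manifest$wav_path <- file.path("wav", paste0(manifest$sample_id, ".wav"))
  dir.create(file.path(dir, "wav"), showWarnings = FALSE)
  for (i in seq_along(dataset$samples)) {
    write_wav(dataset$samples[[i]]$clip,
              file.path(dir, manifest$wav_path[i]), bit_depth)
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset previously written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv` and the WAV files.
#' @return A `roar_dataset`.
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv under ", dir, call. = FALSE)
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    list(
      clip = read_wav(file.path(dir, manifest$wav_path[i])),
      sample_id = manifest$sample_id[i],
      individual_id = manifest$individual_id[i],
      day_id = manifest$day_id[i],
      bout_id = manifest$bout_id[i],
      index_in_bout = manifest$index_in_bout[i]
    )
  })
  sr <- samples[[1]]$clip$sample_rate_hz
  structure(
    list(samples = samples,
         class_labels = sort(unique(manifest$individual_id)),
         sample_rate_hz = sr),
    class = "roar_dataset"
  )
}

#' Check the structural invariants of a roar dataset
#'
#' Verifies that every sample's individual is a known class, no bout holds
#' more than three samples, all samples of a bout share one individual and
#' day, and every individual was recorded on at least two distinct days.
#'
#' @param dataset A `roar_dataset`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_dataset <- function(dataset) {
  m <- dataset_manifest(dataset)
  if (!all(m$individual_id %in% dataset$class_labels)) {
    stop("sample with unknown individual_id", call. = FALSE)
  }
  if (anyDuplicated(m$sample_id)) stop("duplicate sample_id", call. = FALSE)
  by_bout <- split(m, m$bout_id)
  for (b in by_bout) {
    if (nrow(b) > 3L) stop("bout with more than 3 samples: ", b$bout_id[1],
                           call. = FALSE)
    if (length(unique(b$individual_id)) != 1L ||
        length(unique(b$day_id)) != 1L) {
      stop("bout spanning individuals or days: ", b$bout_id[1],
           call. = FALSE)
    }
    if (anyDuplicated(b$index_in_bout)) {
      stop("duplicate index_in_bout in bout ", b$bout_id[1], call. = FALSE)
    }
  }
  days_per_ind <- tapply(m$day_id, m$individual_id,
                         function(d) length(unique(d)))
  if (any(days_per_ind < 2L)) {
    stop("individual with a single recording day: ",
         names(days_per_ind)[which(days_per_ind < 2L)[1]], call. = FALSE)
  }
  invisible(TRUE)
}
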
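---
title: "Methods: individual lion identification from roar acoustics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual lion identification from roar acoustics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Identifying *which* lion is roaring from audio alone is a biometric
verification problem on very small, very structured data. A realistic
field study yields on the order of 150–170 usable full-throated roars
from a handful of collared males, recorded over a few days per animal,
with roars arriving in bouts of 1–3 closely spaced repeats. Two
properties of such data drive everything in this package:

* **Few samples, many correlations.** Roars from the same bout are
  near-repeats of one vocal gesture; roars from the same day share the
  animal's momentary condition and the recording situation. Any
  evaluation that puts one roar of a bout in training and its sibling in
  test overstates accuracy.
* **Identity lives in the spectrum.** Male lions roar at low fundamental
  frequencies (roughly 150–250 Hz) with individually stable harmonic and
  resonance structure, which is why image classifiers on time–frequency
  renderings work at all.

The pipeline is: audio → time–frequency image → backbone classifier with
a replaced softmax head, trained per cross-validation fold → per-class
scores → optional sum-rule fusion of several members → grouped
leave-one-out accuracy and one-vs-many Equal Error Rate.

## Time–frequency representations

All short-time transforms share one framing convention: frames of
`window_length` samples every `hop_length` samples, **no padding and no
centering**, so a clip of *n* samples yields
`1 + floor((n − window_length)/hop_length)` columns. This is stated
explicitly because column counts are part of the tested contract.

* **Spectrogram** — one-sided power `|STFT|²` with a Hamming window
  (Hann and Gaussian are available). Defaults `window_length = 512`,
  `hop = 256`, `fft = 512`: at 16 kHz a 32 ms window, long enough to
  resolve a ~200 Hz fundamental while keeping a few dozen frames per
  roar. Exposed in `rep_config()` because no single setting suits all
  sample rates; the 8 kHz test fixtures use 256/128/256.
* **Mel spectrogram** — triangular filters spaced uniformly on
  m = 2595·log₁₀(1 + f/700) over `frequency_range_hz` (default: 0 to
  Nyquist), applied to the power spectrogram. `n_mel_bands = 32` and
  `n_mfcc = 13` follow common audio-toolbox defaults; both are config.
* **LM / L2M / L3M** — the iterated-log family. LM = 100·log₁₀(S)
  compresses the Mel spectrogram's dynamic range; each further step
  subtracts the image's global minimum (`minref`) before re-applying
  100·log₁₀, which makes L2M and L3M invariant to global additive
  offsets of their input. The subtraction lands exactly on zero at the
  minimum entry, where log₁₀ diverges, so a positive floor (`log_floor`,
  default 10⁻¹⁶, the same constant as the dB scaling) is applied inside
  *every* logarithm; the chain minimum is therefore
  100·log₁₀(10⁻¹⁶) = −1600. Chain order is enforced by representation
  tags (Mel → LM → L2M → L3M).
* **MFCC** — computed literally as `|F⁻¹(log(mel(|F(frame)|²)))|²`,
  i.e. an inverse DFT over the Mel-band axis with squared magnitude,
  truncated to `n_mfcc` coefficients. Note this is *not* the
  DCT-of-log-energies variant common elsewhere; the squared-magnitude
  inverse-transform form is the contract here, and tests pin it to a
  direct O(N²) evaluation.
* **Stockwell transform** — frequency-scaled Gaussian analysis windows
  (width inversely proportional to frequency), computed in the
  frequency-domain fast form: for voice *n*, the inverse DFT over *m* of
  `X[m + n]·exp(−2π²m²/n²)` with `X` the signal's DFT and *m* wrapped to
  [−N/2, N/2). This equals the time-domain definition with a
  *periodized* Gaussian window (Poisson summation), which is what the
  brute-force oracle in the tests implements. The transform is O(N²) in
  memory and time, so the input is decimated ×10 first
  (anti-aliased; see below). The zero-frequency voice — a pure mean —
  is dropped, and the magnitude is taken, since downstream consumers are
  image classifiers.
* **Embedding image** — 128-dimensional per-window embeddings stacked as
  columns. The production contract is any pretrained audio embedder; the
  shipped `make_stub_embedder()` is a deterministic *synthetic* stand-in
  (a seeded random projection of each window's log-Mel spectrogram). It
  preserves identity information linearly and keeps the representation
  testable offline, but carries no learned acoustic knowledge.

**Scalings.** `min_max` maps [min, max] affinely to [0, 255]; `db` is
10·log₁₀(x + 10⁻¹⁶); `box_n` maps to [0, C] (C = 1000 reproduces the
[0–1000] Mel normalization). A constant image has no range to map:
`min_max`/`box_n` return all-zeros with a warning rather than abort a
batch, and `to_network_image()` maps a constant image to mid-gray 127.5.
Bilinear resizing uses the half-pixel-center convention, under which a
2× downsize averages each 2×2 block exactly — a testable anchor.

**Decimation.** "Decimate" is read as *filtered* decimation: an order-4
Butterworth low-pass at 0.8× the new Nyquist, run forward and backward
(zero phase, effective magnitude order 8), then subsampling to
`floor(n/factor)` samples. Plain subsampling would alias broadband roar
energy into the Stockwell voices.

## Classifier

`tiny-scratch`, the built-in backbone, is two convolution blocks
(3×3 kernels, 8 filters, ReLU, 2×2 average pooling) whose weights are
drawn once from a fixed internal seed and then **frozen**, followed by a
multinomial softmax head trained by mini-batch SGD with momentum on the
cross-entropy loss with L2 weight decay. Design rationale:

* Freezing the trunk makes head training a convex problem: zero
  initialization is optimal-start deterministic (no symmetry to break),
  results are bit-reproducible given the shuffle seed, and a full
  20-fold day run completes in seconds on one CPU. Fixed random
  convolutional features are a long-studied, well-behaved feature map,
  and the frozen trunk plays exactly the role of a frozen pretrained
  trunk in the transfer-learning recipe: only the replaced final layer
  is retrained per task.
* Because the trunk never changes, trunk features are computed **once**
  per dataset and reused across folds; only the head is re-fit from
  scratch per fold (never warm-started — warm starts leak test
  information across folds). Per-fold seeds fan out deterministically
  from the master seed.
* Field-scale backbones (AlexNet/VGG-16/ResNet-50 classes) cannot ship
  with the package; they resolve at runtime via `register_backbone()`
  and fail with an instructive error when no plug-in is registered.
  Training hyperparameters for such backbones are deliberately plain
  config (`train_config()`): small-data transfer learning has no
  universal recipe.

Head defaults: 30 epochs, batch 16, learning rate 0.1, momentum 0.9,
weight decay 10⁻⁴. The learning rate is appropriate for a convex softmax
head on standardized features (features are centered/scaled by training
statistics); it is not a deep-net rate.

## Synthetic roar generator

Each individual is a source–filter "voice": a base F0 drawn from a
per-individual band of [150, 250] Hz, an F0 contour (fast rise to a
1.02–1.08× peak, power-law relaxation), 2–3 Gaussian formant resonances
in [300, 900] Hz, −6 dB/octave source rolloff, slow multiplicative pitch
jitter, an attack/decay envelope, and additive white noise at a
configured SNR. All draws are pure functions of the seed.

The grouping structure mirrors a multi-day field study and is the part
that matters for evaluation design:

* **Stratified identity**: base F0 bands partition the range across
  individuals so identities are separable in principle — verified by a
  nearest-centroid oracle (≥ 90 % LOOCV on mean log-spectra). Without
  this, downstream accuracy tests would be meaningless.
* **Day-level drift (±4 %)**: all roars of one (individual, day) share
  an F0 offset, modelling day-to-day changes in the animal's condition.
  This makes held-out days genuinely out-of-distribution. The value is a
  calibration: at ±1 % the grouped designs were indistinguishable from
  naive per-sample CV (the correlation the designs exist to respect was
  effectively absent), while at ±4 % the day-held-out task stays
  solvable (≥ 0.95 observed at 25 dB SNR) but naive per-sample CV now
  enjoys a real leakage advantage.
* **Bout-level correlation**: roars of one bout share a ±2 % F0 offset,
  one pitch-wobble realization, and a base duration (±3 % per sample) —
  they are temporally adjacent repeats of one vocal gesture. Only the
  additive noise is independent within a bout.

Default shape: 5 individuals × 4 day-groups × 4 bouts/day with bout
sizes uniform on {1, 2, 3} — 20 (individual, day) groups, ~75–85 bouts,
~160 samples, matching the motivating field study's published structure
(164 roars, 20 day folds, ~74 bout folds). Desk-scale runs synthesize at
8 kHz with 0.5–0.9 s clips (the precondition sample rate ≥ 4× the
highest formant holds, and ≥ 10 harmonics fit under Nyquist); the
generator default is 16 kHz, the bit rate of typical field loggers.

What the generator does **not** model: propagation and habitat
acoustics, moan/grunt bout phases, overlapping roars, anthropogenic
noise, or microphone variation. Passing the pipeline tests therefore
shows that the system recovers identity signal *that is present by
construction*; it does not certify performance on field recordings.

## Evaluation designs

* **Day scheme**: one fold per (individual, day) group. A "day" is an
  (individual, day-label) *pair*, not a calendar date shared across
  animals — five lions recorded 4–10 days each is what yields ~20
  groups. A class recorded on a single day is a degenerate design and
  raises an error naming the class (silent skipping would bias results).
* **Bout scheme**: one fold per bout (test size 1–3).
* **Naive per-sample scheme**: provided *only* to demonstrate leakage;
  its accuracy is expected to be ≥ the day scheme's on bout-correlated
  data, and the package's tests assert exactly that.
* **One-vs-many EER**: the target's roars become class 1, all others
  class 2. Per base-scheme group, one sample of the group's own class
  and one opposite-class sample (deterministic rotation over
  opposite-class groups) form the test pair; *both* samples' whole
  groups leave the training set, preserving group integrity. Genuine and
  impostor class-1 posteriors are pooled across folds per target, one
  EER is computed per target, and the mean over targets reported.
  Per-fold EERs on two-sample test sets would be meaningless, which is
  why pooling was chosen.

**EER computation.** FAR(t) = fraction of impostor scores ≥ t,
FRR(t) = fraction of genuine scores < t; thresholds sweep the midpoints
of adjacent distinct scores plus sentinels; at the FAR/FRR crossing the
value is linearly interpolated between bracketing thresholds when no
exact equality exists. The sweep is rank-based, so EER is invariant
under any joint strictly increasing transform of the scores.

**Accuracy.** Row-argmax prediction with ties broken toward the lowest
class index — an arbitrary but fixed and documented rule; pooled
accuracy is Σ correct / Σ tested, which equals the sample-weighted mean
of per-fold accuracies.

**Fusion.** Members are softmax posteriors (not logits) before
summation: posteriors put heterogeneous backbones on a common scale and
make the sum rule backbone-agnostic. Ensemble search is exhaustive over
all C(m, k) combinations, k ∈ {2, 3}, with lexicographic tie-breaks.
Selecting the best ensemble on the same split it is reported on is an
optimistic-selection hazard; the search therefore operates on declared
score stores, and `search_ensembles()` can be re-applied to a held-out
store to re-score a chosen ensemble.

## Numerical choices and degenerate inputs

* `log_floor = 1e-16` inside every logarithm (finiteness everywhere).
* Constant images: all-zero under `min_max`/`box_n` (with warning),
  mid-gray under network rendering — batch extraction never aborts.
* WAV I/O: integer PCM is rescaled by the symmetric full-scale value
  (e.g. ±32767 at 16-bit), so write→read round-trips stay within half a
  quantization step; 8-bit WAV uses offset-binary decoding per RIFF
  convention; multichannel input is averaged to mono. Amplitude
  normalization to [−1, 1] at load is this package's choice — field
  pipelines differ, so it is worth stating.
* Decimation requires ≥ 30 samples (zero-phase filter warm-up) and
  errors on shorter input rather than returning corrupt spectra.

## Problem sizes

Tests and the acceptance script run the full pipeline at desk scale:
~160-sample datasets at 8 kHz, 64×64 network images, 20 day folds,
~80 bout folds, ~160 naive folds, and 5 × ~20 EER folds; the complete
test suite and the acceptance script each finish in a few minutes on a
single CPU. These sizes are the package's chosen study conditions for
its synthetic experiments, matching the motivating field study's shape.

## Known limitations

* The acoustic model is additive and stationary per clip; real roars
  have nonstationary turbulence, amplitude-modulated subharmonics, and
  habitat reverberation.
* `tiny-scratch` trains only its head; it demonstrates and tests the
  pipeline, it is not a claim about attainable field accuracy, and
  reproducing published field-data accuracies is out of scope without
  the original recordings.
* The embedding stub is a linear sketch, not a learned embedding;
  conclusions about embedding-based members transfer to real pretrained
  embedders only qualitatively.
* No data augmentation and no denoising are provided by design; noisy
  field samples are expected to be excluded upstream rather than
  cleaned.
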
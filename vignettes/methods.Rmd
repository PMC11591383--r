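---
title: "Recognizing sheep feeding behavior from barn audio: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing sheep feeding behavior from barn audio: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sheep produce characteristic sounds while feeding: foraging (active
ingestion of hay) is a fast, regular train of broadband chewing
transients; rumination (re-chewing regurgitated feed) is a slower,
sustained rhythmic pattern in a lower band; everything else in a working
barn — bleats, coughs, panting, equipment, wind — is an acoustically
heterogeneous "other" class. `foldear` classifies short (1–3 s) mono
audio segments into these three classes by fusing two feature families
in a single early-fusion vector fed to a support vector machine:

1. **Hand-crafted acoustic features** — a 68-dimensional descriptor per
   segment (34 short-term features plus their first-order deltas,
   averaged over frames), filtered by SVM recursive feature elimination
   with cross-validation (RFECV).
2. **Deep spectrogram features** — activations tapped from the fully
   connected layers (FC1: 128 units, FC2: 3 logits) of SheepVGG-Lite, a
   shallow VGG-style CNN trained per spectrogram representation (STFT,
   constant-Q, or mel).

## Time–frequency transforms

All three transforms operate on Hann-windowed frames.

* **STFT**: window length $N = 2048$ samples, hop $N/4$; one-sided
  magnitude, $N/2 + 1 = 1025$ rows. The hop is a package choice (75%
  overlap is conventional and keeps adequate time resolution in the
  rendered image); the window length is the fixed analysis setting.
* **Constant-Q transform**: $K = 200$ bins at $B = 32$ bins per octave
  (6.25 octaves) from $f_\min = 22.05$ Hz, quality factor
  $Q = 1/(2^{1/B} - 1)$, per-bin kernel length
  $N_k = \lceil f_s Q / f_k \rceil$, evaluated directly from the
  definition
  $X_{CQT}(k, t) = \frac{1}{N_k}\left|\sum_n x(n + t\,h)\, w_{N_k}(n)\,
  e^{-2\pi i Q n / N_k}\right|$ through a cached kernel-matrix product.
  At $f_\min = 22.05$ Hz the low-bin kernels are longer than a 1–3 s
  segment, so kernels are truncated to the available signal length,
  keeping their original window shape, and renormalized by the actual
  kernel length; the signal is zero-padded past its end so every frame
  is defined. Truncation trades frequency resolution in the lowest bins
  for applicability to short segments; it leaves the argmax behavior of
  audible bins intact, which is what the classifier consumes. The
  22.05 Hz floor looks like a 44.1 kHz convention carried into 48 kHz
  material; it is kept as the fixed default.
* **Mel spectrogram**: the STFT magnitude pooled through 128 unit-peak
  triangular filters spaced uniformly in mel units
  ($\mathrm{mel}(f) = 2595\log_{10}(1 + f/700)$) between 0 Hz and the
  Nyquist frequency. 128 filters is a package default chosen to give a
  dense image before resizing.

Spectrograms are rendered for the CNN as 100×100×3 images: dB scale
($20\log_{10}(v + 10^{-10})$), clip to the top 80 dB, min-max normalize,
map through a fixed 256-entry color lookup table, and bilinearly resize
with half-pixel-centered sampling. dB scaling (rather than linear
magnitude) is a package decision; the 80 dB floor is the common display
convention. Every step is pinned — including the lookup table, which is
generated from fixed RGB anchors — so images are bit-reproducible across
installs, and the dB + min-max chain makes images invariant to input
gain. A constant (e.g. silent) spectrogram maps to the top table entry
by convention.

## Acoustic features

Frames are 50 ms with a 25 ms hop (a conventional short-term bioacoustic
framing; the analysis setting is not dictated by the classification
protocol). The 34 base features per frame are: zero-crossing rate,
energy, energy entropy (10 sub-blocks), spectral centroid, spread,
entropy, flux (squared difference of successive L2-normalized spectra),
90% roll-off, 13 MFCCs, 12 chroma energy fractions (A440 semitone
classes) and their standard deviation. First-order deltas
($\Delta f_t = f_t - f_{t-1}$, zero at the first frame) double this to
68; the segment vector is the per-column mean. Design notes:

* The base count is fixed at 34 so that base + delta = 68 exactly; "13
  chroma features" is realized as 12 pitch-class energies plus their
  standard deviation, the only decomposition consistent with 12-tone
  chroma and a count of 13.
* MFCCs use a 40-filter mel bank on the frame power spectrum, log with a
  $10^{-10}$ floor, and an orthonormal DCT-II keeping coefficients 1–13
  (the DC term is excluded; it measures overall level, which the energy
  feature already carries).
* Standardization is z-scoring with population (divisor $n$) standard
  deviations fitted on training rows only; zero-variance columns get
  scale 1 and map to zero.

## Feature selection

RFECV eliminates one feature per step. Elimination importance is the
squared linear-SVM weight summed over one-vs-rest class fits (the RBF
kernel used for final classification has no weight vector, so a linear
kernel with $C = 1$ drives both elimination and the cross-validated
curve). At each surviving count the mean support-weighted F1 over
stratified 5-fold cross-validation is recorded; the retained subset is
the count maximizing the curve, ties going to the smallest count
(parsimony). Permutation importance — the mean weighted-F1 drop over
seeded column permutations — is reported separately and does not drive
elimination.

## SheepVGG-Lite

The pinned architecture is 100×100×3 → conv 3×3 (3→16) → ReLU →
maxpool 2×2 → conv 3×3 (16→32) → ReLU → maxpool 2×2 → flatten (20,000)
→ FC1 (128, ReLU) → FC2 (3 logits): 2,565,603 parameters, about
10.26 MB at 32-bit precision. The conv kernel size (3×3, stride 1,
padding 1), one conv per block, and the FC1 width of 128 are package
decisions — chosen VGG-style and so that the serialized model stays
within an 11.7 MB compactness budget suited to collar-side deployment.

Training: Adam ($\beta = 0.9/0.999$), cross-entropy, batch 32, up to 50
epochs, learning rate interpolated linearly **per epoch** from 0.001 to
0.0001, a stratified 25% validation split of the training data, and
checkpointing on the best validation weighted F1 (earliest epoch on
ties). He-normal initialization, no data augmentation, single-threaded
deterministic kernels; weights are held at float32 precision so a
serialized model reloads to bit-identical logits. Class order is fixed
alphabetically (foraging, other, rumination) and recorded in every
artifact.

EigenCAM projects the last conv block's post-ReLU activations (25×25×32
after pooling) onto their first right singular vector, sign chosen so
the projected map's maximum is positive, clamps negatives, upsamples
bilinearly to 100×100 and min-max normalizes. For the non-negative
activations a ReLU network produces, the projection is essentially a
Perron component, so the sign convention is stable.

## Fusion and classification protocol

A stratified 80/20 train/test split (largest-remainder per-class
allocation, so class proportions are within one sample of the target)
is fixed first. Each requested representation's CNN is trained on the
training split only; FC taps are then computed for all segments. RFECV
runs on the train-standardized training rows of the acoustic matrix.
Blocks are concatenated in recipe order (e.g.
`CQT_FC1 + STFT_FC1 + ACOUSTIC` gives 128 + 128 + selected columns) and
a **single** standardizer fitted on the fused training rows scales the
whole vector — one consistent scheme, since deep and acoustic blocks
live on very different scales. The SVM hyperparameters come from a grid
search (linear and RBF kernels × $C \in \{0.1, 1, 10\}$, stratified
5-fold CV scored by support-weighted F1, gamma "auto" $= 1/D$); a fixed
RBF/$C = 1$ setting is available by turning the search off. Report
metrics follow the per-class accuracy/recall/precision/F1 confusion
formulas with support-weighted averaging; report-level accuracy is the
overall fraction correct, which equals weighted recall for any
full-coverage multiclass evaluation — the same identity visible in the
accuracy-equals-recall pattern such evaluations show. Zero-denominator
ratios are 0 by convention, with a warning.

## The synthetic barn corpus

The study's recordings are private, so the package ships a seeded
generator that emulates the structure the classifier assumes:

* foraging — band-passed noise bursts, 1–6 kHz, 40–80 ms, at 3–4
  events/s;
* rumination — 0.4–3 kHz bursts, 80–150 ms, at 1–1.5 events/s;
* other — a mixture of bleats (harmonic stack, f0 200–500 Hz, five 1/h
  harmonics, 2% vibrato at 3–5 Hz), coughs (one loud broadband burst),
  panting (~2 soft events/s) and noise-only clips, weighted
  0.4/0.2/0.2/0.2;

over a pink (1/f) background scaled to a 10 dB event-to-background SNR
by default, peak-normalized to 0.9. Events are placed by a jittered
periodic process (±20% of the period). Rates, bands and durations are
drawn uniformly per segment from the class ranges; all draws derive
from per-file seeds so the corpus is reproducible file by file.

What the generator does **not** emulate: room reverberation,
overlapping animals, microphone handling noise, diurnal nonstationarity,
and the within-class variability of real jaws. Passing the end-to-end
benchmark therefore demonstrates that the pipeline is wired correctly
and can recover class structure of the designed kind at realistic SNR —
not that any particular real-barn accuracy would be reproduced. The reference benchmark uses 60 segments per class at
16 kHz (the transform properties under test are rate-agnostic and the
smaller rate keeps a full run in minutes; 48 kHz is the recorder's
native rate and remains the generator default).

## Numerical choices and degenerate inputs

* Trailing partial frames are dropped, never padded; the frame count is
  $\lfloor (n - L)/h \rfloor + 1$.
* Segmentation energy is the mean square per frame (scale-free in the
  frame length); runs of above-threshold frames are cut back to sample
  ranges.
* Silence: zero spectrograms render to a uniform image; zero
  activations give a zero heatmap; zero spectra give zero centroid,
  spread, entropy and roll-off.
* Ties: max-pooling takes the first maximum in scan order; grid search
  takes the first best row (linear before RBF, ascending C); RFECV
  curve ties go to the smallest count; checkpoint ties to the earliest
  epoch.
* Multi-channel WAV input is averaged to mono; integer PCM scales by
  the encoding's full-scale value; no resampling is ever performed
  implicitly.

## A worked example

```{r}
library(foldear)

spec <- corpus_spec(n_per_class = 60, sample_rate = 16000, seed = 7)
corpus <- generate_corpus_segments(spec)

bank <- build_feature_bank(corpus, kinds = c("stft", "cqt"), seed = 7)
fused <- run_experiment(NULL, "CQT_FC1+STFT_FC1+ACOUSTIC", seed = 7,
                        bank = bank)
summary(fused)

# inspect what the CNN attends to
img <- spectrogram_image(corpus[[1]], "stft")
heat <- eigencam(bank$cnns$stft, img)
```

## Known limitations

* The constant-Q transform tops out at
  $22.05 \cdot 2^{199/32} \approx 1.6$ kHz under the pinned
  configuration, so the CQT branch mostly sees the lower half of the
  foraging band; the STFT and acoustic branches carry the higher bands,
  which is one reason fusion helps.
* RFECV with one-feature steps is $O(p^2)$ SVM fits; fine at $p = 68$,
  slow for much wider feature sets.
* The direct-evaluation CQT is exact but memory-hungry for long
  segments at 48 kHz (the kernel matrix scales with the longest
  kernel); segments beyond a few seconds should be cut first.
* Training is CPU-only and single-threaded by design (reproducibility
  over speed); a full 50-epoch training on 180 images takes a few
  minutes.
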
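---
title: "Heart-sound screening with heartkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-sound screening with heartkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartkit)
```

## The problem

A phonocardiogram (PCG) is an audio recording of heart sounds captured at
the chest wall. Each cardiac cycle contains two dominant transients — S1
(closure of the atrioventricular valves, opening systole) and S2 (closure
of the semilunar valves, opening diastole). Pathology shows up as extra
acoustic structure: murmurs are noise-like turbulence between S1 and S2,
and extrasystoles are premature beats that disrupt the inter-beat rhythm.

heartkit implements a screening pipeline that classifies recordings as
normal, murmur or extrasystole at the level of *single heart cycles*:

1. **Denoise** with a zero-phase IIR (Butterworth) bandpass filter.
2. **Segment** the recording into single cycles, using a
   Daubechies-wavelet low-frequency reconstruction, a Shannon-energy
   envelope, and unbiased-autocorrelation (UACF) period estimation.
3. **Describe** each cycle by mel-frequency cepstral coefficients (MFCC),
   optionally rendered as fixed-size 480x640 RGB spectrogram images.
4. **Screen out** noisy cycles by fitting a two-component Gaussian
   mixture to per-cycle feature vectors with EM and discarding the
   minority cluster.
5. **Classify** the kept cycles under a stratified, recording-grouped
   k-fold protocol, reporting per-class and micro (class-averaged)
   accuracy, sensitivity (TPR), precision (PPV) and specificity (TNR).

A deterministic synthetic PCG generator with ground-truth beat
annotations makes every stage testable without external corpora.

## Denoising

Heart sounds carry most of their energy at roughly 25–120 Hz; murmurs
extend to several hundred Hz; below ~20 Hz live breathing and contact
rumble, above lies hiss. The default `filter_spec()` is a 4th-order
Butterworth bandpass, 25–600 Hz, applied forward–backward (zero phase) at
the native rate so the filter doubles as anti-alias protection before the
2 kHz downsampling. The literature this pipeline follows names only "an
IIR filter", so family, order and cutoffs are documented package choices
and fully configurable. Note that zero-phase application squares the
magnitude response, effectively doubling the attenuation slope.

## Segmentation

### Wavelet low-frequency extraction

The working-rate (2 kHz) signal is decomposed to 5 levels with a
Daubechies-6 wavelet (periodized, orthogonal; the approximation band is
then roughly 0–31 Hz and the first detail bands cover the S1/S2 range).
Each subband is thresholded with the adaptive rule

$$\mathrm{thr} = \mu(|C|) + f\,\sigma(|C|), \qquad f = 1 \text{ by default},$$

computed per band with the population standard deviation, and the signal
is reconstructed. `keep_mode` decides which side of the threshold
survives:

* `"above"` (default) zeroes the sub-threshold coefficients — the
  standard wavelet-denoising convention. It preserves the strong S1/S2
  transient coefficients and suppresses the diffuse noise floor.
* `"below"` zeroes the *large* coefficients instead.

The source description of this step is self-contradictory, and we
verified both readings on the synthetic corpus: keep-below deletes
exactly the coefficients that carry S1 and S2, after which envelope peaks
land on secondary structure and the period estimator locks onto multiples
of the true cycle. Keep-above recovers S1 positions to ~10 ms and is
therefore the default; keep-below remains available for comparison.

### Shannon-energy envelope

Per 40-sample frame (20 ms at 2 kHz, hop 20 samples — enough to resolve
a 70 ms S1 while smoothing intra-transient oscillation), the envelope is

$$SE = -\tfrac{1}{N}\sum_j e_j \log e_j, \qquad e_j = x_j^2,$$

with $0\log 0 := 0$. The energy convention keeps the log argument
non-negative (raw samples can be negative). The transform deliberately
emphasizes medium intensities — but $-e\log e$ *decreases* again for
$e > 1/e$, so a full-scale S1 ($x \to 1$) would be scored *below* a
softer S2. Before the envelope is computed the pipeline therefore
references the low-frequency signal to half full scale
($|x| \le 0.5 \Rightarrow e \le 0.25 < 1/e$), keeping the transform
monotone in amplitude over its whole input range while still compressing
the dynamic range. The framed envelope is then standardized to zero mean
and unit standard deviation.

### Period estimation and cycle cutting

The unbiased autocorrelation of the standardized envelope,
$r(\tau) = \frac{1}{L-\tau}\sum_t x_t x_{t+\tau}$, is searched for its
highest positive local maximum with the period window 0.4–1.6 s
(37–150 bpm). Because a periodic envelope correlates equally well at the
period and its multiples (and the unbiased normalization slightly favors
long lags in noise), the estimator takes the *earliest* local maximum
whose height reaches 85% of the global one. The 0.85 fraction separates
two regimes: true sub-multiples of the winning lag score essentially as
high as the winner (~0.9+), while the spurious S1-to-S2 peak scores far
lower (~0.3–0.5 on the synthetic corpus); any value between those two
regimes behaves the same.

S1 anchors are local envelope maxima above 0 (standardized scale),
greedily thinned highest-first with a minimum spacing of 0.6 periods
(equal peaks resolve to the earlier one). Each cycle spans
`[onset, onset + period)` in 0-based half-open sample coordinates,
truncated at the next onset, and a trailing fragment shorter than half a
period is dropped.

## MFCC features and spectrogram images

Cycles are cut into Hamming-windowed frames of 1024 samples (hop 512).
Per frame: DFT amplitude spectrum, log (floored at 1e-10), smoothing by a
26-filter triangular mel filterbank spanning 0–Nyquist, then a type-II
DCT of which the first 13 coefficients are kept. Two conventions are
worth flagging:

* The log is taken *before* the mel filterbank — the five-step recipe
  this pipeline follows applies the amplitude-spectrum logarithm first
  and uses the filterbank as a spectrum smoother. (Classic speech MFCCs
  apply the filterbank to the power spectrum and then the log; both are
  fixed cepstral-like transforms, and the downstream clustering and
  classifiers are agnostic to the choice.) The mel filters are unit-sum
  normalized so the bank is a weighted moving average on the log
  spectrum.
* At 2 kHz a 1024-sample window is 512 ms — long relative to a heart
  cycle, giving few frames per cycle. It is kept because the window
  length is the one parameter the recipe fixes; it is configurable.

Segments shorter than one window are zero-padded rather than rejected.
For image-based backends the coefficient matrix is min–max mapped onto a
fixed 256-level viridis colormap, rendered coefficient-by-time and
nearest-neighbor resized to exactly 480x640x3 (8-bit). A single-valued
matrix maps to uniform mid-gray (128) by convention. Rendering is
deterministic, so identical inputs give byte-identical PNGs.

## Segment selection by mixture biclustering

Per-cycle feature vectors (the concatenated per-coefficient means and
population standard deviations, 26 dimensions) are z-scored per dimension
and clustered with a two-component Gaussian mixture (diagonal
covariances) fitted by EM:

* Estimation: $t(i,k) \propto \pi_k N(x_i\,|\,\mu_k, \sigma_k^2)$,
  normalized per item (computed with log-sum-exp).
* Maximization: $\pi_k = \bar t_k$, responsibility-weighted means and
  variances.

Initialization is k-means++-style seeding from the run seed with 5
restarts, keeping the best final log-likelihood; convergence is a 1e-6
log-likelihood tolerance with at most 200 iterations. Diagonal rather
than full covariances because 26 dimensions against typical per-class
segment counts (tens to a few hundred) makes full covariance estimates
ill-conditioned. A component collapsing below the variance floor is
re-seeded once, then reported as an error; dimensions that are globally
constant are clamped, not treated as collapse.

The working hypothesis of the selection step: most cycles from a class
are mutually consistent, so the *smaller* cluster is the noise. All
segments of the larger cluster are kept; an exact size tie keeps the
cluster with the higher total log-density under its own component.
Clustering pools segments per class across the corpus by default
(matching the per-class accounting the method reports); per-recording
clustering is available. On very small corpora (3–4 recordings per
class) the bicluster can align with recording identity instead of noise
and discard a whole recording's cycles — at that scale selection should
be disabled, and the pipeline exposes `selection$enabled` for exactly
this reason.

## Classification protocol

Folds are stratified by class and *grouped by recording*: all cycles of
one recording stay on one side of each train/validation split. The
source protocol does not state its fold construction; cycle-level splits
would leak recording identity across folds and inflate every metric, so
the leakage-safe choice is made here.

Backends:

* `logistic_baseline` — multinomial logistic regression
  (`nnet::multinom`) on the summary feature vectors; the default for
  desk-scale runs and the end-to-end tests.
* `small_cnn` — the reference head (global average pooling, dense 1024,
  dense 512, softmax) on a desk-scale trunk: one 3x3 stride-2
  convolution with ReLU over images downscaled to 48x64, trained by
  mini-batch SGD. The published configuration fine-tunes large
  ImageNet-pretrained trunks with learning rate 1e-4, batch 5, 100
  epochs; those trunks (and their GPUs) are out of scope here, and an
  `external_pretrained` adapter hook is provided instead. With the tiny
  randomly-initialized trunk a learning rate around 0.05 is appropriate
  (used by the capacity tests); 1e-4 remains the config default because
  it is the published value.
* "Default momentum" in the reference setup is recorded as momentum = 0.

Metrics follow the one-vs-rest layout: per class accuracy, TPR, PPV and
TNR; a ratio with a zero denominator is reported as absent (`NA`) rather
than 0 so it cannot silently bias an average. Micro metrics are the
unweighted mean over classes; fold aggregation averages folds first, then
classes. The plain multiclass accuracy (trace over total) is reported
separately.

## The synthetic generator

`synth_recording()` emulates exactly the structure the pipeline exploits:

* S1: Gaussian-windowed 40 Hz cosine, 70 ms wide, peak amplitude 1,
  centered on the beat onset grid; S2: 60 Hz, 50 ms, amplitude 0.7 at
  35% of the cycle (textbook timing and softness ratio).
* Murmur class: band-limited (120–400 Hz) noise, tapered over the
  S1-to-S2 interval, peak amplitude 0.4.
* Extrasystole class: each inter-beat interval is halved with
  probability 0.25 per beat; the early beat is annotated.
* Additive white noise at a configurable SNR (default 20 dB); corpus
  generation jitters heart rate uniformly over 60–100 bpm and SNR over
  15–25 dB per recording.
* A beat is emitted only when its full cycle fits, so a recording of
  duration $d$ at rate $b$ bpm carries exactly
  $\lfloor d\,b/60 \rfloor$ beats (plus inserted extrasystoles).

What it does *not* model: respiration and friction-rub artifacts,
amplitude variation across beats, S3/S4 sounds, diastolic murmurs,
sensor nonlinearity, or the heavy inter-recording variability of real
stethoscope corpora. Passing tests on this generator demonstrate that
the algorithms recover the structure they assume; they do not certify
clinical performance on real data, which in the published experiments
required large pretrained networks and the external corpora.

## Numerical choices and degenerate inputs

* Thresholding uses strict `<` / `>` comparisons, as specified.
* Population (divisor $n$) standard deviations in the adaptive threshold
  and the feature summaries; the envelope standardization uses the
  sample convention so the reported sd is exactly 1.
* `0 log 0 := 0` in the Shannon transform; all-zero frames score 0.
* Silent recordings are rejected (`SilentSignal`) rather than normalized.
* A constant envelope has no variance to standardize and no periodicity
  to estimate; both raise classed errors.
* Integer PCM is scaled by $1/2^{\mathrm{bits}-1}$; multichannel audio is
  averaged to mono (stethoscope recordings are effectively single-point).
* Resampling is polyphase anti-aliased conversion to
  `round(n * target / native)` samples; recordings already at the target
  rate are returned unchanged, and upsampling warns unless explicitly
  allowed.
* One global pipeline seed fans out by fixed offsets (selection +101,
  training +202) so each stage is reproducible from a single knob.

## Problem sizes used by the tests

The validation suites run at desk scale, chosen to exercise the claims
while staying quick: 50 synthetic recordings of 10 s for cycle-recovery
statistics (median period error, beat-count recovery), 100 seeded
signals for the envelope invariants, 20 seeds x (80 clean + 20
corrupted) single-beat segments for selection efficacy, 100 seeded EM
runs for the monotonicity property, and a 15-recording corpus for the
deterministic end-to-end run with the logistic baseline.

## Known limitations

* The UACF octave guard resolves period doubling for quasi-periodic
  rhythms; strongly arrhythmic recordings (dense extrasystoles) have no
  single period, and the estimator returns the dominant one.
* Segment selection assumes noise is the minority; a majority-corrupted
  recording set inverts the rule.
* The small CNN is a capacity demonstration of the classification head,
  not a substitute for the published pretrained-trunk results.
* The WAV codec covers PCM 8/16/24/32-bit and IEEE float mono/multichannel
  RIFF files; exotic chunks are skipped, compressed formats are not read.
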
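# heartkit

Heart-sound (phonocardiogram, PCG) screening in R: cut a chest-wall audio
recording into single cardiac cycles, turn each cycle into mel-cepstral
(MFCC) spectrogram features, weed out noisy cycles by unsupervised mixture
clustering, and classify cycles as **normal**, **murmur** or
**extrasystole** with per-class and micro sensitivity / precision /
specificity under a recording-grouped 3-fold protocol.

The package is aimed at biomedical-signal researchers and engineers who
need a fully scripted, deterministic PCG pipeline — every stage is an
exported R function, a synthetic PCG generator with ground-truth beat
annotations stands in for external corpora, and a thin CLI wraps the whole
chain.

## The method

For a recording $S(t)$:

1. **Denoise** — zero-phase Butterworth bandpass (default 4th order,
   25–600 Hz), then downsample to 2 kHz and normalize
   $NS(t) = S(t)/\max|S(t)|$.
2. **Segment** — decompose with a Daubechies-6 wavelet (5 levels),
   threshold each subband at $\mathrm{thr} = \mu(|C|) + f\,\sigma(|C|)$,
   reconstruct the low-frequency heart sound; frame-wise Shannon energy
   $SE = -\frac{1}{N}\sum e_j \log e_j$ (with $e_j = x_j^2$), standardized
   to zero mean / unit sd; cycle period from the unbiased autocorrelation
   $r(\tau) = \frac{1}{L-\tau}\sum_t x_t x_{t+\tau}$ searched over
   0.4–1.6 s; cycles cut at envelope peaks, one period long.
3. **Features** — per cycle, Hamming-windowed frames (1024 samples, hop
   512): DFT amplitude → log → triangular mel-filterbank smoothing →
   DCT-II, 13 coefficients; optionally rendered as 480×640×3 spectrogram
   PNGs.
4. **Select** — two-component Gaussian mixture (diagonal covariances)
   fitted by EM on per-cycle feature summaries,
   $t(i,k) \propto \pi_k N(x_i|\mu_k,\sigma_k^2)$; the minority cluster is
   discarded as noise.
5. **Classify** — multinomial logistic baseline on feature summaries, or a
   small CNN (global average pooling + dense 1024 + dense 512 + softmax
   head) on the spectrogram images; stratified recording-grouped k-fold
   evaluation with one-vs-rest TPR / PPV / TNR and their class averages.

See `vignettes/heartkit-methods.Rmd` for the full model description,
parameter rationale and design decisions.

## Worked example

```r
library(heartkit)

# a 10 s murmur recording at 75 bpm with 20 dB SNR, then the full chain
cfg <- synth_config(duration = 10, bpm = 75, snr_db = 20, seed = 42)
out <- synth_recording(cfg, "murmur")
rec <- normalize_amplitude(resample_recording(iir_denoise(out$recording), 2000))
sp  <- segment_pipeline(rec)
sp$cycle$period_seconds     # 0.800  -> 75.0 bpm recovered exactly
sp$cycle$confidence         # 0.97   -> r(period)/r(0), near-perfect rhythm
length(sp$segments)         # 12     -> 12 complete cycles found

sp$segments[[1]]
#> <heart_cycle_segment synth_murmur_42 [20, 1620) murmur>

f <- summarize_segment_features(mfcc(sp$segments[[1]]))
round(f[1:4], 3)
#>  mean_1  mean_2  mean_3  mean_4
#> -41.828  27.276 -10.685   4.357
```

End to end on a balanced 15-recording synthetic corpus (5 per class),
with mixture selection and the logistic baseline:

```r
ds  <- make_dataset(5, synth_config(duration = 10, extrasystole_prob = 0.35),
                    seed = 77)
res <- run_pipeline(validate_config(list(seed = 31, out_dir = NULL)),
                    ds$recordings)
res$report
#> Evaluation report ( 3 folds )
#>         class accuracy   tpr   ppv   tnr
#>  extrasystole    0.982 0.956 1.000 1.000
#>        murmur    0.982 0.972 0.970 0.988
#>        normal    0.981 1.000 0.943 0.973
#> Classes avg: accuracy=0.982  tpr=0.976  ppv=0.971  tnr=0.987
res$stage_counts
#> recordings 15, segments_produced 184, kept 146, ignored 38
```

The per-class rows are one-vs-rest metrics averaged over the three folds;
the "Classes avg" row is their unweighted mean (the micro metrics). The
stage counts always satisfy `kept + ignored = produced`.

The same run from the shell:

```sh
Rscript inst/cli/heartkit.R synth --n 5 --seed 77 --out data/
Rscript inst/cli/heartkit.R pipeline --manifest data/manifest.csv --out run/
```

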
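# ocuclean

Removal of ocular artifacts (eye blinks and slow eye movements) from
single-channel sleep EEG, with a fully synthetic benchmark so every stage can
be tested without clinical data.

Eye activity leaks into frontal EEG as high-amplitude, low-frequency
transients that corrupt sleep staging. Multichannel recordings can be cleaned
by blind source separation, but a single channel offers too few observations —
so this package first *manufactures* a multichannel view of the signal and
then unmixes it:

1. **Detection.** The recording is cut into 10 s segments; time-domain
   (skewness, kurtosis, Hjorth parameters), spectral (Welch band powers in
   delta/theta/alpha/beta) and nonlinear features (Shannon entropy, composite
   multiscale sample entropy, dispersion entropy, Katz fractal dimension,
   Lempel–Ziv complexity, Hurst exponent) feed an mRMR-selected RBF-SVM that
   flags contaminated segments. Clean segments are never touched.
2. **Decomposition.** Each flagged segment is split by variational mode
   decomposition (VMD) into k band-limited modes u_k with centre frequencies
   ω_k, solved by ADMM in the frequency domain. The pair (k, α) — mode count
   and bandwidth penalty — can be tuned per segment by a binary-coded genetic
   algorithm whose fitness is the minimum approximate entropy across modes;
   the fixed default is (k, α) = (4, 120).
3. **Unmixing.** The k modes are stacked as a k-channel observation and
   separated by second-order blind identification (SOBI): whitening followed
   by joint approximate diagonalization of time-lagged covariance matrices
   D(ρ) = E[W(t+ρ)W(t)ᵀ], ρ = 1..20.
4. **Rejection.** Each source is scored with approximate entropy
   (m = 2, r = 0.15·SD, self-matches counted). Stereotyped ocular waveforms
   are regular (ApEn < 0.4) while cortical activity is irregular (ApEn > 0.4);
   sources below the 0.4 threshold are zeroed.
5. **Reconstruction.** Inverse SOBI rebuilds the mode stack and the cleaned
   segment is the mode sum (inverse VMD), spliced back into the recording.

The package also ships the semi-simulated evaluation framework: seeded
generators for surrogate clean EEG and EOG, the mixing model
`mix = pure + θ·eog` with θ chosen so that `RMS(pure)/RMS(θ·eog)` equals a
requested SNR, and the usual quality indices (CC, RRMSE, MSE, PSNR, per-band
ΔPSD, and precision/recall/F1/accuracy/macro-F1/weighted-F1 for sleep-staging
evaluations).

## Worked example

```r
library(ocuclean)

# a 10 s clean segment, an ocular artifact, and their mixture at SNR 1
pure <- gen_pure_eeg(10, fs = 200, seed = 1)
eog  <- gen_eog(10, fs = 200, seed = 2)
mix  <- mix_eeg_eog(pure, eog, snr = 1)
round(mix$spec$theta, 3)
#> [1] 1

# denoise it and compare against the known truth
d <- denoise_segment(mix$mixture, fs = 200)
round(d$record$apen[[1]], 3)
#> [1] 0.222 0.673 0.904 1.378
d$record$rejected[[1]]
#> [1] 1
round(c(cc_mixed = cc(pure, mix$mixture), cc_cleaned = cc(pure, d$cleaned)), 3)
#>   cc_mixed cc_cleaned
#>      0.707      0.716
```

The first SOBI source (ApEn 0.22, under the 0.4 threshold) is the
blink/drift component and is removed. Single-segment gains vary; the
SNR-sweep benchmark below is the meaningful aggregate (at SNR 0.5 the mean
correlation with the clean reference rises from ≈ 0.47 to ≈ 0.66). At the
recording level, `denoise_recording()` applies a trained classifier first,
so only flagged windows are modified:

```r
rec  <- eeg_recording(gen_pure_eeg(60, 200, seed = 3), fs = 200)
clf  <- train_classifier(gen_corpus(100, 100, seed = 4))
out  <- denoise_recording(rec, 1, clf)
identical(out$recording$data[[1]], rec$data[[1]])
#> [1] TRUE   # all-clean recording passes through bit-identical
```

A thin command-line front end with `simulate` / `train` / `denoise` /
`evaluate` subcommands is installed under `inst/cli/ocuclean`.

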
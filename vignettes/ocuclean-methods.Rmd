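---
title: "Ocular artifact removal in single-channel sleep EEG: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ocular artifact removal in single-channel sleep EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocuclean)
```

## The problem

Blinks and slow eye movements produce potentials an order of magnitude larger
than cortical EEG, concentrated below a few hertz, and they leak heavily into
frontal EEG derivations. In sleep studies this matters twice over: ocular
activity is both a nuisance (it biases delta-band power, the main marker of
deep sleep) and intermittent (most 10 s windows are clean, so aggressive
whole-record filtering destroys information needlessly). The design here
follows a *detect-then-repair* philosophy: an SVM flags contaminated windows,
and only those are decomposed, unmixed, pruned and rebuilt.

## The repair chain and its model assumptions

A single channel cannot be unmixed directly — blind source separation needs
more observations than sources. The chain therefore builds observations out
of one channel:

**VMD.** The segment is modelled as a sum of k band-limited modes; the
decomposition minimises the summed bandwidths of the analytic-signal
spectra subject to (softly) reconstructing the input, solved by ADMM in the
frequency domain with Wiener-filter mode updates and power-centroid updates
of the centre frequencies. We mirror-extend the segment by half its length
on each side, and by default use the penalty-only variant (`tau = 0`), which
does not force broadband noise into the modes. An important *structural*
property, verified empirically in the tests: the competitive mode updates
partition the spectrum — energy at a given frequency ends up almost wholly
in one mode, whatever the overlap of the nominal Wiener filters. The VMF
stack is therefore a spectral partition of the segment, not a redundant
filter bank.

**SOBI.** The k modes are treated as a k-channel instantaneous mixture.
After whitening (eigendecomposition of the zero-lag covariance), one
orthogonal matrix is sought that jointly near-diagonalises the symmetrised
lagged covariances (lags 1–20 samples, i.e. up to 100 ms at 200 Hz), by
closed-form Jacobi rotation sweeps. Sources with distinct autocovariance
signatures — oscillations vs pulse trains vs drifts — separate; Gaussianity
is irrelevant. The estimated mixing matrix is the pseudo-inverse of the
whitener times the diagonaliser.

**ApEn rejection.** Each source is scored by approximate entropy with
embedding dimension m = 2 and radius r = 0.15 times the source SD,
self-matches included (so the statistic is defined for any input and
non-negative up to floating-point, which we clip at zero). Ocular waveforms
are stereotyped and score low; cortical activity scores high. Sources below
0.4 are zeroed. We note an inconsistency a careful reader will find in the
method's usual presentation: prose sometimes claims ocular activity is the
*more* complex process, but the threshold logic and the empirical entropy
distributions say the opposite; this package removes the *low*-entropy
sources, which is the only direction consistent with the 0.4 cutoff.

**Reconstruction.** Inverse SOBI rebuilds the (pruned) mode stack; the
cleaned segment is the sum of the cleaned modes. We deliberately do *not*
add back the VMD residual `x − Σ u_k`: doing so re-introduces the rejected
source's uncorrelated high-band content into the output and can *increase*
alpha/beta power, which is exactly what a targeted artifact remover must not
do. With mode-sum reconstruction, rejection can only remove band power.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| window length | 10 | s | classification and repair granularity |
| k (modes) | 4 | — | operating point of the method (see below) |
| α (penalty) | 120 | — | wide, overlapping modes (see below) |
| GA ranges | k 2–10, α 100–5000 | — | search space; pop 10, 30 generations |
| SOBI lags | 1–20 | samples | autocovariance signatures up to 100 ms |
| ApEn m, r | 2, 0.15·SD | — | universal ApEn conventions |
| ApEn threshold | 0.4 | — | empirical EEG/EOG entropy separation |
| Welch | 2 s Hann, 50% overlap | — | 0.5 Hz resolution at 200 Hz |
| bands | δ 0.5–4, θ 4–8, α 8–13, β 13–30 | Hz | conventional band edges |

The `(k, α) = (4, 120)` default deserves comment, because it is the point
where the method is self-consistent. Low α means wide modes, so the SOBI
sources stay relatively broadband and their entropies stay above the 0.4
threshold for clean EEG — the guard against false rejection. Large k or
large α produce narrowband modes; a narrowband process is smooth and
regular at 200 Hz, so even *clean* EEG then yields sub-threshold sources and
gets damaged. The GA's min-ApEn fitness actively prefers those narrow-mode
configurations (a maximally regular mode is its optimum), so per-segment GA
optimisation, although implemented and exposed (`use_ga`, `ga_mode`), is off
by default; the fixed operating point is safer on clean data.

## The synthetic benchmark

`gen_pure_eeg()` draws stationary Gaussian surrogates: independent
band-limited processes for the four conventional bands with band powers
proportional to the integral of 1/f over each band, plus a flat wideband
component (12% of power) standing in for the broadband cortical noise floor.
Everything is normalised to unit SD, so amplitudes are in EEG-SD units. The
wideband fraction is what keeps the approximate entropy of every 10 s
surrogate above 0.4 (measured ≈ 1.6–1.7 across 500 seeds) — the entropy
separation the rejection rule relies on.

`gen_eog()` superposes Poisson-timed blinks (squared-sine pulses, 200–400 ms,
3–10 EEG-SD, 15/min) on a sub-0.5 Hz drift of unit SD standing in for slow
eye movements. Its ApEn stays below 0.13 and ≥ 99% of its power lies below
5 Hz. `mix_eeg_eog()` scales the artifact so the RMS ratio equals a requested
SNR exactly, and `gen_corpus()` emits labelled (segment, label, θ, seed)
tables for classifier training.

What the surrogates do **not** emulate: non-stationarity across sleep
stages, spindle/K-complex morphology, muscle and cardiac artifacts, and
electrode drift. Passing tests on this benchmark therefore demonstrate the
pipeline's mechanics — separation, thresholding, splicing, bookkeeping — not
clinical performance on real polysomnograms.

## Numerical choices and degenerate inputs

* VMD: uniform centre-frequency initialisation starting at 0 (a seeded
  random initialisation is available); convergence at summed relative mode
  change `1e-7`, capped at 500 iterations; an all-zero segment returns zero
  modes immediately.
* Joint diagonalization: rotation angles below `1e-8` rad stop a sweep;
  100 sweeps maximum; matrices are symmetrised before use.
* Whitening refuses rank-deficient inputs and names the constant or
  duplicated channels responsible.
* ApEn of a constant series is 0 by convention; Katz FD of a constant is 1;
  Hurst of a constant is 0.5; skew/kurtosis of a constant are 0.
* Segmentation drops trailing partial windows (every downstream operator
  assumes full windows); splicing validates bounds and overlap and leaves
  untouched samples bit-identical.
* Segments classified clean are never processed at all — the output samples
  are the input samples, not a near-identical reconstruction.

## Problem sizes

The shipped tests and the acceptance script use 10 s segments at 200 Hz
(2000 samples), 50 segments per SNR level for the end-to-end benchmark,
500 surrogates per class for the entropy-separation check, 400 + 400
training and 100 + 100 held-out segments for the classifier, and 20 random
mixing matrices for the SOBI recovery check. These sizes give stable means
(Monte-Carlo SE well under the asserted margins) while keeping a full run
in the minutes range on a single core.

## Known limitations

1. **Spectral overlap bounds separation.** Because VMD partitions the
   spectrum, the mode stack carries no diversity *within* a band: blink
   energy and delta-band EEG that share 0.5–3 Hz largely live in the same
   slow mode, and SOBI can only apportion what the partition resolves. The
   practical consequence, visible in the SNR sweep: removal is strongly
   beneficial when contamination dominates the slow band (SNR 0.5: CC with
   the clean reference rises from ≈ 0.47 to ≈ 0.66) and becomes a wash or a
   small net loss at light contamination (SNR 2), where the rejected slow
   source is about half cortical. Pooled over the sweep the denoiser
   improves both CC and RRMSE, and cleaned-signal quality is monotone in
   SNR; the per-level gain at high SNR is the method's weak spot. This is
   one reason the classifier gate matters: lightly contaminated windows
   that the SVM does not flag are left alone.
2. **Threshold specificity tail.** The 0.4 cutoff is estimated from
   full-band segment entropies, but applied to band-limited sources. For a
   few percent of genuinely clean segments the slowest source scores
   marginally below 0.4 and is removed, costing ≈ 30% of the segment's
   correlation with its true waveform. At the defaults this affects ≈ 3% of
   clean segments forced through the repair chain (and none that the
   classifier gate passes through untouched).
3. **Single-channel scope.** Channels are processed independently; no
   cross-channel information is used even when several channels exist.
4. **Hard splicing.** Repaired windows are written back without cross-fade;
   discontinuities at window boundaries are possible when a repair changes
   the local mean. (The windows are long relative to the transition, and
   sleep-staging features are window-internal, so this was left simple.)
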
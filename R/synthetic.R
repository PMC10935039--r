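# Run expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr on the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Gaussian process with amplitude spectrum shaped by `shape(f)` over
# [f_lo, f_hi], synthesized in the frequency domain from one white draw.
band_noise <- function(n, fs, f_lo, f_hi, shape = function(f) 1 / sqrt(f)) {
  z <- fft(rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  mask <- rep(0, n)
  sel <- f >= f_lo & f <= f_hi
  mask[sel] <- shape(pmax(f[sel], f_lo))
  x <- Re(fft(z * mask, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x / s else x
}

#' Generate a surrogate pure-EEG segment
#'
#' A stationary Gaussian surrogate for clean sleep EEG: independent
#' band-limited processes for the delta, theta, alpha and beta bands, each
#' with a 1/f amplitude profile inside its band, combined with band powers
#' proportional to the integral of a 1/f power spectrum over the band, plus
#' a small flat wideband component representing the broadband cortical
#' noise floor that real EEG always carries. Output is normalised to unit
#' standard deviation, so amplitudes elsewhere in the package are expressed
#' in EEG-SD units.
#'
#' The wideband fraction is calibrated so that the approximate entropy
#' (m = 2, r = 0.15 sd) of every generated 10 s segment exceeds the 0.4
#' artifact threshold, matching the empirical separation between EEG and
#' ocular activity that motivates that threshold.
#'
#' @param duration_s Segment length in seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed; identical seeds give identical segments.
#' @return Numeric vector of `round(duration_s * fs)` samples, SD 1.
#' @export
gen_pure_eeg <- function(duration_s = 10, fs = 200, seed = NULL) {
  if (duration_s <= 0) abort("duration_s must be positive.")
  n <- round(duration_s * fs)
  with_seed(seed, {
    bands <- eeg_bands()
    # band powers ~ integral of 1/f over the band
    w <- vapply(bands, function(b) log(b[2] / b[1]), numeric(1))
    w <- w / sum(w)
    x <- rep(0, n)
    for (i in seq_along(bands)) {
      b <- bands[[i]]
      x <- x + sqrt(w[i]) * band_noise(n, fs, b[1], b[2])
    }
    # broadband floor up to 0.45 * fs; 12% of total power
    floor_frac <- 0.12
    x <- sqrt(1 - floor_frac) * x / sd(x) +
      sqrt(floor_frac) * band_noise(n, fs, 0.5, 0.45 * fs,
                                    shape = function(f) rep(1, length(f)))
    x / sd(x)
  })
}

#' Generate a surrogate EOG (ocular artifact) segment
#'
#' Eye blinks are modelled as Poisson-timed squared-sine pulses of
#' 200--400 ms duration and 3--10 EEG-SD amplitude, superposed on a slow
#' (< 1 Hz) eye-movement drift. The result is a stereotyped, low-frequency,
#' high-amplitude signal: at least 90% of its spectral power lies below
#' 5 Hz and its approximate entropy falls well below the 0.4 threshold that
#' separates it from cortical activity.
#'
#' @param duration_s Segment length in seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @param blink_rate Expected blinks per minute (Poisson); 0 disables blinks.
#' @param drift_sd Standard deviation of the slow drift component in EEG-SD
#'   units; 0 disables the drift.
#' @return Numeric vector of `round(duration_s * fs)` samples.
#' @export
gen_eog <- function(duration_s = 10, fs = 200, seed = NULL,
                    blink_rate = 15, drift_sd = 1) {
  if (duration_s <= 0) abort("duration_s must be positive.")
  if (blink_rate < 0) abort("blink_rate must be >= 0.")
  n <- round(duration_s * fs)
  with_seed(seed, {
    x <- rep(0, n)
    if (drift_sd > 0) {
      x <- x + drift_sd * band_noise(n, fs, 0.05, 0.45,
                                     shape = function(f) 1 / f)
    }
    n_blinks <- rpois(1, blink_rate * duration_s / 60)
    if (n_blinks > 0) {
      t <- seq_len(n) / fs
      starts <- runif(n_blinks, 0, duration_s)
      widths <- runif(n_blinks, 0.2, 0.4)
      amps <- runif(n_blinks, 3, 10)
      for (b in seq_len(n_blinks)) {
        inside <- t >= starts[b] & t <= starts[b] + widths[b]
        x[inside] <- x[inside] +
          amps[b] * sin(pi * (t[inside] - starts[b]) / widths[b])^2
      }
    }
    x
  })
}

#' Mix pure EEG with an ocular artifact at a target SNR
#'
#' Implements the semi-simulated mixing model `mix = pure + theta * eog`,
#' with the weight chosen so that the ratio of root-mean-square amplitudes
#' `RMS(pure) / RMS(theta * eog)` equals the requested SNR exactly. Lower
#' SNR means heavier contamination.
#'
#' @param pure Numeric vector, clean EEG samples.
#' @param eog Numeric vector of the same length, artifact samples.
#' @param snr Target RMS signal-to-noise ratio (> 0).
#' @return List with `mixture` (numeric vector) and `spec`, a one-row
#'   tibble (`snr`, `theta`, `rms_pure`, `rms_eog`).
#' @export
mix_eeg_eog <- function(pure, eog, snr) {
  if (length(pure) != length(eog)) abort("pure and eog must be equal length.")
  if (snr <= 0) abort("snr must be positive.")
  r_eog <- rms(eog)
  if (r_eog == 0) abort("Cannot mix: the artifact signal has zero RMS.")
  theta <- rms(pure) / (snr * r_eog)
  list(mixture = pure + theta * eog,
       spec = tibble(snr = snr, theta = theta,
                     rms_pure = rms(pure), rms_eog = r_eog))
}

#' Generate a labelled corpus of clean and contaminated segments
#'
#' Emits the training/evaluation fixture for the artifact classifier and
#' the end-to-end pipeline: clean surrogate EEG segments (label 0) and
#' semi-simulated mixtures (label 1) whose contamination weight follows the
#' mixing model of [mix_eeg_eog()]. Every segment is generated from its own
#' sub-seed, so any single row can be regenerated in isolation.
#'
#' @param n_clean,n_contaminated Segment counts per class.
#' @param duration_s,fs Segment geometry.
#' @param snr Either a single SNR for all contaminated segments or a range
#'   `c(lo, hi)` sampled uniformly per segment.
#' @param seed Master seed.
#' @param blink_rate,drift_sd Passed to [gen_eog()].
#' @return Tibble with one row per segment: `id`, `label` (0 clean /
#'   1 contaminated), `snr`, `theta`, `seed`, and list-columns `samples`
#'   (the mixture, or the clean EEG for label 0) and `pure` (ground-truth
#'   clean EEG).
#' @export
gen_corpus <- function(n_clean = 100, n_contaminated = 100, duration_s = 10,
                       fs = 200, snr = c(0.5, 2), seed = 1,
                       blink_rate = 15, drift_sd = 1) {
  n_tot <- n_clean + n_contaminated
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max / 2, n_tot))
  snr_draw <- with_seed(seed + 1, if (length(snr) == 2) {
    runif(n_contaminated, snr[1], snr[2])
  } else rep(snr, n_contaminated))
  rows <- purrr::map(seq_len(n_tot), function(i) {
    s <- sub_seeds[i]
    pure <- gen_pure_eeg(duration_s, fs, seed = s)
    if (i <= n_clean) {
      tibble(id = i, label = 0L, snr = Inf, theta = 0, seed = s,
             samples = list(pure), pure = list(pure))
    } else {
      eog <- gen_eog(duration_s, fs, seed = s + 1,
                     blink_rate = blink_rate, drift_sd = drift_sd)
      mx <- mix_eeg_eog(pure, eog, snr_draw[i - n_clean])
      tibble(id = i, label = 1L, snr = mx$spec$snr, theta = mx$spec$theta,
             seed = s, samples = list(mx$mixture), pure = list(pure))
    }
  })
  dplyr::bind_rows(rows)
}

#' Write a generated corpus to disk as CSV segments plus a manifest
#'
#' @param corpus Tibble from [gen_corpus()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble (`file`, `label`, `snr`, `theta`,
#'   `seed`), also written to `manifest.csv` in `dir`.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("segment_%04d.csv", corpus$id)
  purrr::walk2(corpus$samples, files, function(x, f) {
    utils::write.csv(data.frame(eeg = x), file.path(dir, f),
                     row.names = FALSE)
  })
  manifest <- tibble(file = files, label = corpus$label, snr = corpus$snr,
                     theta = corpus$theta, seed = corpus$seed)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
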
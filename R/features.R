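#' Time-domain features of one segment
#'
#' Skewness, excess kurtosis and the three Hjorth parameters. Ocular
#' artifacts are high-amplitude asymmetric transients, so they move the
#' moment statistics and the activity (variance) sharply while lowering
#' mobility (they are slow waves).
#'
#' @param x Numeric vector of samples (length >= 3).
#' @return One-row tibble: `skewness`, `kurtosis` (excess), `hjorth_activity`
#'   (variance), `hjorth_mobility` (`sqrt(var(diff(x)) / var(x))`),
#'   `hjorth_complexity` (mobility of the first difference over mobility of
#'   the signal). A constant signal maps to zeros (and mobility 0).
#' @export
time_features <- function(x) {
  if (length(x) < 3) abort("time_features() needs length >= 3.")
  v <- var(x)
  if (v == 0) {
    return(tibble(skewness = 0, kurtosis = 0, hjorth_activity = 0,
                  hjorth_mobility = 0, hjorth_complexity = 0))
  }
  d1 <- diff(x)
  d2 <- diff(d1)
  mob <- sqrt(var(d1) / v)
  mob_d <- if (var(d1) > 0) sqrt(var(d2) / var(d1)) else 0
  tibble(
    skewness = e1071::skewness(x),
    kurtosis = e1071::kurtosis(x),
    hjorth_activity = v,
    hjorth_mobility = mob,
    hjorth_complexity = if (mob > 0) mob_d / mob else 0
  )
}

#' Band-power features of one segment
#'
#' Absolute and relative Welch band powers in the conventional EEG bands.
#' Ocular contamination inflates delta-band power, so these are the
#' workhorse features for artifact detection.
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate, Hz.
#' @param bands Named list of `c(lo, hi)` ranges; defaults to delta
#'   0.5--4, theta 4--8, alpha 8--13, beta 13--30 Hz.
#' @return One-row tibble with `psd_<band>` (absolute power) and
#'   `psd_rel_<band>` (fraction of total power in the union of the bands)
#'   per band. A zero signal returns all zeros.
#' @export
psd_features <- function(x, fs, bands = eeg_bands()) {
  hi <- max(vapply(bands, `[`, numeric(1), 2))
  if (fs <= 2 * hi) abort("Sampling rate must exceed twice the highest band edge.")
  if (all(x == 0)) {
    out <- as.list(rep(0, 2 * length(bands)))
    names(out) <- c(paste0("psd_", names(bands)),
                    paste0("psd_rel_", names(bands)))
    return(as_tibble(out))
  }
  p <- welch_psd(x, fs)
  abs_p <- vapply(bands, function(b) band_power(p, b[1], b[2]), numeric(1))
  tot <- sum(abs_p)
  rel_p <- if (tot > 0) abs_p / tot else rep(0, length(abs_p))
  out <- as.list(c(abs_p, rel_p))
  names(out) <- c(paste0("psd_", names(bands)),
                  paste0("psd_rel_", names(bands)))
  as_tibble(out)
}

# Shannon entropy (nats) of a 16-bin amplitude histogram.
shannon_entropy <- function(x, bins = 16) {
  if (sd(x) == 0) return(0)
  h <- tabulate(cut(x, breaks = bins, labels = FALSE), nbins = bins)
  p <- h[h > 0] / length(x)
  -sum(p * log(p))
}

# Composite multiscale sample entropy: mean over scales of the mean
# per-offset sample entropy of the coarse-grained series (m = 2,
# r = 0.15 * sd of the original signal).
cmse <- function(x, m = 2, r_coef = 0.15, scales = 1:3) {
  s <- sd(x)
  if (s == 0) return(0)
  r <- r_coef * s
  per_scale <- vapply(scales, function(tau) {
    vals <- vapply(seq_len(tau), function(off) {
      y <- x[off:length(x)]
      nb <- floor(length(y) / tau)
      if (nb <= m + 1) return(NA_real_)
      cg <- colMeans(matrix(y[seq_len(nb * tau)], nrow = tau))
      ba <- sampen_counts_cpp(cg, as.integer(m), r)
      if (ba[1] == 0 || ba[2] == 0) return(NA_real_)
      -log(ba[2] / ba[1])
    }, numeric(1))
    if (all(is.na(vals))) 0 else mean(vals, na.rm = TRUE)
  }, numeric(1))
  mean(per_scale)
}

# Dispersion entropy: normal-CDF mapping into c classes, embedded
# dispersion patterns of length m, normalised Shannon entropy of the
# pattern distribution.
dispersion_entropy <- function(x, m = 2, n_classes = 6) {
  s <- sd(x)
  if (s == 0) return(0)
  z <- stats::pnorm(x, mean(x), s)
  d <- pmin(pmax(ceiling(z * n_classes), 1), n_classes)
  n <- length(d) - m + 1
  pat <- rep(0, n)
  for (j in seq_len(m)) pat <- pat * n_classes + d[j:(j + n - 1)]
  p <- table(pat) / n
  -sum(p * log(p)) / log(n_classes^m)
}

# Katz fractal dimension of the sample path.
katz_fd <- function(x) {
  L <- sum(abs(diff(x)))
  d <- max(abs(x - x[1]))
  if (L == 0 || d == 0) return(1)
  n <- length(x) - 1
  log10(n) / (log10(n) + log10(d / L))
}

# Normalised Lempel-Ziv complexity of the median-binarised sequence;
# a computable stand-in for Kolmogorov complexity.
lz_complexity <- function(x) {
  if (sd(x) == 0) return(0)
  b <- as.integer(x > median(x))
  n <- length(b)
  lz76_cpp(b) * log2(n) / n
}

# Rescaled-range (R/S) Hurst exponent: slope of log(R/S) on log(window)
# over dyadic window sizes. 0.5 for uncorrelated noise; constant input
# maps to 0.5 by convention.
hurst_rs <- function(x) {
  if (sd(x) == 0) return(0.5)
  n <- length(x)
  sizes <- unique(floor(n / 2^(seq(0, floor(log2(n / 8))))))
  sizes <- sizes[sizes >= 8]
  if (length(sizes) < 2) return(0.5)
  rs <- vapply(sizes, function(w) {
    nw <- floor(n / w)
    vals <- vapply(seq_len(nw), function(i) {
      seg <- x[((i - 1) * w + 1):(i * w)]
      z <- cumsum(seg - mean(seg))
      r <- max(z) - min(z)
      s <- sd(seg)
      if (s == 0) NA_real_ else r / s
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2) return(0.5)
  unname(coef(stats::lm(log(rs[ok]) ~ log(sizes[ok])))[2])
}

#' Nonlinear features of one segment
#'
#' Shannon entropy of the amplitude histogram (16 bins), composite
#' multiscale sample entropy (m = 2, r = 0.15 sd, scales 1--3, averaged),
#' dispersion entropy (m = 2, 6 classes, normal-CDF mapping), Katz fractal
#' dimension, normalised Lempel--Ziv complexity of the median-binarised
#' sequence (a Kolmogorov-complexity estimate), and the rescaled-range
#' Hurst exponent. Blink waveforms are regular and strongly persistent, so
#' they depress the entropies and raise the Hurst exponent relative to EEG.
#'
#' @param x Numeric vector (length >= 100).
#' @return One-row tibble: `shannon_entropy`, `cmse`, `dispersion_entropy`,
#'   `katz_fd`, `lz_complexity`, `hurst`.
#' @export
nonlinear_features <- function(x) {
  if (length(x) < 100) abort("nonlinear_features() needs length >= 100.")
  tibble(
    shannon_entropy = shannon_entropy(x),
    cmse = cmse(x),
    dispersion_entropy = dispersion_entropy(x),
    katz_fd = katz_fd(x),
    lz_complexity = lz_complexity(x),
    hurst = hurst_rs(x)
  )
}

#' Full feature set for a table of segments
#'
#' Binds the time-domain, band-power and nonlinear features for every
#' segment. Deterministic: identical samples give identical rows.
#'
#' @param segments Tibble with a `samples` list-column (as produced by
#'   [segment_signal()] or [gen_corpus()]) and either an `fs` column or the
#'   `fs` argument; alternatively a bare list of numeric vectors.
#' @param fs Sampling rate, used when `segments` carries none.
#' @return Tibble with one feature row per segment, in input order.
#' @export
extract_features <- function(segments, fs = NULL) {
  if (is.data.frame(segments)) {
    xs <- segments$samples
    if (is.null(fs) && "fs" %in% names(segments)) fs <- segments$fs[1]
  } else {
    xs <- segments
  }
  if (is.null(fs)) abort("Supply fs either as a column or as an argument.")
  purrr::map(xs, function(x) {
    dplyr::bind_cols(time_features(x), psd_features(x, fs),
                     nonlinear_features(x))
  }) |> dplyr::bind_rows()
}
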
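#' Denoising quality metrics against a known clean reference
#'
#' @description
#' Scalar indices comparing a cleaned signal with the ground-truth clean
#' signal of a semi-simulated mixture:
#'
#' * `cc()` — Pearson correlation; 1 means the cleaned signal preserves the
#'   EEG waveform perfectly.
#' * `rrmse()` — relative root-mean-square error
#'   `RMS(pure - clean) / RMS(pure)`; 0 is perfect, 1 is as bad as
#'   returning zeros.
#' * `mse()` — mean squared error.
#' * `psnr()` — peak signal-to-noise ratio `10 log10((2^m - 1)^2 / MSE)` in
#'   dB with `m` amplitude bits (8 by default); identical signals give
#'   `Inf`.
#'
#' @param x_pure Numeric vector, the clean reference.
#' @param x_clean Numeric vector of equal length, the denoised signal.
#' @param m_bits Bit depth for the PSNR peak value.
#' @return A scalar.
#' @name sim_metrics
NULL

#' @rdname sim_metrics
#' @export
cc <- function(x_pure, x_clean) {
  if (length(x_pure) != length(x_clean)) abort("Lengths must match.")
  if (length(x_pure) < 2) abort("Need at least two samples.")
  if (sd(x_pure) == 0 || sd(x_clean) == 0) {
    abort("cc() is undefined for a constant signal.")
  }
  cor(x_pure, x_clean)
}

#' @rdname sim_metrics
#' @export
rrmse <- function(x_pure, x_clean) {
  if (length(x_pure) != length(x_clean)) abort("Lengths must match.")
  r <- rms(x_pure)
  if (r == 0) abort("rrmse() is undefined for a zero-RMS reference.")
  rms(x_pure - x_clean) / r
}

#' @rdname sim_metrics
#' @export
mse <- function(x_pure, x_clean) {
  if (length(x_pure) != length(x_clean)) abort("Lengths must match.")
  mean((x_pure - x_clean)^2)
}

#' @rdname sim_metrics
#' @export
psnr <- function(x_pure, x_clean, m_bits = 8) {
  e <- mse(x_pure, x_clean)
  if (e == 0) return(Inf)
  10 * log10((2^m_bits - 1)^2 / e)
}

#' Collect all reference-based metrics in one row
#'
#' @inheritParams sim_metrics
#' @return One-row tibble with `cc`, `rrmse`, `mse`, `psnr`.
#' @export
sim_metrics <- function(x_pure, x_clean, m_bits = 8) {
  tibble(cc = cc(x_pure, x_clean), rrmse = rrmse(x_pure, x_clean),
         mse = mse(x_pure, x_clean), psnr = psnr(x_pure, x_clean, m_bits))
}

#' Band-power change before vs after denoising
#'
#' For real recordings with no clean reference, artifact removal is judged
#' by the per-band power drop `delta_p = P_before - P_after` (Welch band
#' powers). Targeted ocular-artifact removal shows a large positive change
#' in the delta band and a near-zero change in the beta band; a negative
#' value means the processing added power.
#'
#' @param x_pre,x_post Numeric vectors of equal length.
#' @param fs Sampling rate, Hz.
#' @param bands Named list of band edges, see [eeg_bands()].
#' @return Tibble with one row per band: `band`, `p_pre`, `p_post`,
#'   `delta_p`.
#' @export
delta_psd <- function(x_pre, x_post, fs, bands = eeg_bands()) {
  if (length(x_pre) != length(x_post)) abort("Lengths must match.")
  hi <- max(vapply(bands, `[`, numeric(1), 2))
  if (fs <= 2 * hi) abort("Band edge above the Nyquist frequency.")
  p1 <- welch_psd(x_pre, fs)
  p2 <- welch_psd(x_post, fs)
  tibble(
    band = names(bands),
    p_pre = vapply(bands, function(b) band_power(p1, b[1], b[2]), numeric(1)),
    p_post = vapply(bands, function(b) band_power(p2, b[1], b[2]), numeric(1))
  ) |> dplyr::mutate(delta_p = .data$p_pre - .data$p_post)
}

#' Sleep-staging classification metrics
#'
#' Per-class one-vs-rest precision, recall and F1 plus overall accuracy,
#' macro-F1 (unweighted class mean) and weighted-F1 (support-weighted
#' mean), the standard scores for 5-class sleep staging (W, N1, N2, N3,
#' REM). A class never predicted gets precision 0 by convention.
#'
#' @param y_true,y_pred Vectors of stage labels (character or factor) of
#'   equal length.
#' @return List with `per_class` (tibble: `class`, `support`, `precision`,
#'   `recall`, `f1`) and `overall` (one-row tibble: `accuracy`, `macro_f1`,
#'   `weighted_f1`).
#' @export
staging_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) abort("Empty input.")
  if (length(y_true) != length(y_pred)) abort("Lengths must match.")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  per <- purrr::map(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble(class = cl, support = tp + fn, precision = prec,
           recall = rec, f1 = f1)
  }) |> dplyr::bind_rows()
  overall <- tibble(
    accuracy = mean(y_true == y_pred),
    macro_f1 = mean(per$f1),
    weighted_f1 = sum(per$f1 * per$support) / sum(per$support)
  )
  list(per_class = per, overall = overall)
}
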
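#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with Hann windows. Defaults (2 s windows,
#' 50% overlap) give 0.5 Hz resolution at 200 Hz, enough to resolve the
#' delta band edge at 0.5 Hz.
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length in seconds.
#' @param overlap Fractional overlap between consecutive windows.
#' @return Tibble with `freq` (Hz) and `psd` (power per Hz, one-sided).
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  n <- length(x)
  L <- min(round(window_s * fs), n)
  if (L < 8) abort("Signal too short for a Welch estimate.")
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, n - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))   # Hann
  scale <- fs * sum(w^2)
  nf <- floor(L / 2) + 1
  acc <- rep(0, nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / scale
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even L)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (L %% 2 == 0) dbl[nf] <- 1
  tibble(freq = (seq_len(nf) - 1) * fs / L, psd = psd * dbl)
}

# Integrated band power from a welch_psd() table: sum(psd) * df over
# freq in [lo, hi).
band_power <- function(psd_tbl, lo, hi) {
  df <- psd_tbl$freq[2] - psd_tbl$freq[1]
  sel <- psd_tbl$freq >= lo & psd_tbl$freq < hi
  sum(psd_tbl$psd[sel]) * df
}
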
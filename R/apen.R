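#' Approximate entropy of a time series
#'
#' Regularity statistic computed by Chebyshev-distance template matching:
#' the negative average log conditional probability that sequences close for
#' `m` points remain close at the next point. Self-matches are included in
#' the counts, so the statistic is always defined and non-negative in
#' expectation; the rare small negative values from finite precision are
#' clipped to zero. Low values mean the series is regular/predictable
#' (sinusoids, blink waveforms); irregular broadband activity scores high.
#'
#' @param x Numeric vector, length > m + 1.
#' @param m Embedding dimension (default 2).
#' @param r_coef Similarity radius as a fraction of `sd(x)` (default 0.15).
#' @return Non-negative scalar. A constant series returns 0.
#' @examples
#' approximate_entropy(rnorm(500)) # irregular, well above 0.4
#' approximate_entropy(sin(2 * pi * 5 * (1:500) / 200)) # regular, near 0
#' @export
approximate_entropy <- function(x, m = 2, r_coef = 0.15) {
  n <- length(x)
  if (n <= m + 1) abort("approximate_entropy() needs length > m + 1.")
  if (m < 1) abort("m must be >= 1.")
  if (r_coef <= 0 || r_coef >= 1) abort("r_coef must lie in (0, 1).")
  s <- sd(x)
  if (s == 0) return(0)
  apen_cpp(as.numeric(x), as.integer(m), r_coef * s)
}

#' Flag SOBI sources as ocular artifacts by approximate entropy
#'
#' Scores every source with [approximate_entropy()] and marks sources whose
#' score falls below `threshold` as artifact (to be removed). EEG activity
#' is irregular and scores above the threshold, while blink and eye-movement
#' waveforms are stereotyped, low-entropy signals.
#'
#' @param sources Numeric matrix, one source per row (as in
#'   [sobi_separate()]), or a numeric vector for a single source.
#' @param threshold ApEn cutoff; sources below it are rejected (default 0.4).
#' @param m,r_coef Passed to [approximate_entropy()].
#' @return A tibble with one row per source: `source`, `apen`, `keep`.
#'   If every source is rejected (or none is) a warning is emitted, since
#'   either outcome usually signals an upstream problem.
#' @export
classify_components <- function(sources, threshold = 0.4, m = 2,
                                r_coef = 0.15) {
  if (is.vector(sources)) sources <- matrix(sources, nrow = 1)
  if (nrow(sources) < 1) abort("classify_components() needs >= 1 source.")
  apen <- apply(sources, 1, approximate_entropy, m = m, r_coef = r_coef)
  keep <- apen >= threshold
  if (!any(keep)) {
    warn("All sources fell below the ApEn threshold; everything is removed.")
  } else if (all(keep)) {
    warn("No source fell below the ApEn threshold; nothing is removed.")
  }
  tibble(source = seq_along(apen), apen = unname(apen), keep = unname(keep))
}

#' Zero rejected sources and reconstruct the observations
#'
#' @param res A `sobi_result` from [sobi_separate()].
#' @param mask Tibble from [classify_components()], or a logical vector of
#'   per-source keep flags.
#' @return Numeric matrix of cleaned multichannel samples (channels x time).
#' @export
remove_components <- function(res, mask) {
  keep <- if (is.data.frame(mask)) mask$keep else as.logical(mask)
  if (length(keep) != nrow(res$S)) {
    abort("Mask length must equal the number of sources.")
  }
  s_mod <- res$S
  s_mod[!keep, ] <- 0
  sobi_reconstruct(res, s_mod)
}
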
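# Shared fixtures, built once per test run.

make_tone <- function(f, fs = 200, duration_s = 10, phase = 0) {
  sin(2 * pi * f * seq_len(round(fs * duration_s)) / fs + phase)
}

seeded_noise <- function(n, seed = 1) {
  withr::with_seed(seed, rnorm(n))
}

# FFT brick-wall band-pass, the oracle filter for VMD mode checks.
fft_bandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X <- stats::fft(x)
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# A small labelled corpus and a classifier trained on it, computed lazily
# and reused across test files.
.fixture_env <- new.env(parent = emptyenv())

small_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    .fixture_env$corpus <- gen_corpus(25, 25, seed = 42)
  }
  .fixture_env$corpus
}

small_classifier <- function() {
  if (is.null(.fixture_env$clf)) {
    .fixture_env$clf <- train_classifier(small_corpus(), fs = 200)
  }
  .fixture_env$clf
}

# Four temporally distinct sources and a well-conditioned mixing matrix,
# for SOBI ground-truth recovery tests.
make_sobi_case <- function(seed, n = 2000, fs = 200) {
  withr::with_seed(seed, {
    t <- seq_len(n) / fs
    S <- rbind(sin(2 * pi * 5 * t), sin(2 * pi * 23 * t),
               as.numeric(stats::arima.sim(list(ar = 0.9), n)),
               as.numeric(stats::arima.sim(list(ar = -0.6), n)))
    repeat {
      A <- matrix(rnorm(16), 4)
      if (kappa(A) < 20) break
    }
    list(S = S, A = A, X = A %*% S)
  })
}
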
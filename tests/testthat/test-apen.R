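# Plain-R transcription of the ApEn template-matching definition, kept
# deliberately naive as an independent oracle for the compiled kernel.
apen_oracle <- function(x, m = 2, r_coef = 0.15) {
  r <- r_coef * sd(x)
  if (r == 0) return(0)
  phi <- vapply(c(m, m + 1), function(mm) {
    n <- length(x) - mm + 1
    emb <- sapply(seq_len(mm), function(k) x[k:(k + n - 1)])
    counts <- vapply(seq_len(n), function(i) {
      d <- apply(abs(sweep(emb, 2, emb[i, ], function(a, b) a - b)), 1, max)
      sum(d < r)
    }, numeric(1))
    mean(log(counts / n))
  }, numeric(1))
  max(phi[1] - phi[2], 0)
}

test_that("the compiled ApEn matches a naive R transcription", {
  for (s in 1:3) {
    x <- seeded_noise(150, s)
    expect_equal(approximate_entropy(x), apen_oracle(x), tolerance = 1e-12)
  }
  x <- make_tone(5, 200, 1)
  expect_equal(approximate_entropy(x), apen_oracle(x), tolerance = 1e-12)
})

test_that("ApEn conventions and canonical orderings hold", {
  expect_identical(approximate_entropy(rep(2.5, 300)), 0)

  x <- seeded_noise(1000, 51)
  s <- make_tone(5, 200, 5)
  expect_gt(approximate_entropy(x), approximate_entropy(s))

  # period-2 determinism: alternating sequence scores ~0
  alt <- rep(c(1, -1), 500)
  expect_lt(abs(approximate_entropy(alt)), 0.02)

  expect_error(approximate_entropy(c(1, 2, 3), m = 2), "length")
})

test_that("ApEn is scale-invariant and non-negative", {
  for (s in 1:5) {
    x <- seeded_noise(400, 60 + s)
    a <- approximate_entropy(x)
    expect_gte(a, 0)
    expect_equal(approximate_entropy(3.7 * x), a, tolerance = 1e-10)
    expect_equal(approximate_entropy(-x), a, tolerance = 1e-10)
  }
})

test_that("ApEn agrees with an established implementation", {
  x <- seeded_noise(800, 55)
  expect_equal(approximate_entropy(x),
               pracma::approx_entropy(x, edim = 2, r = 0.15 * sd(x)),
               tolerance = 1e-8)
})

test_that("component classification applies the 0.4 threshold", {
  sources <- rbind(make_tone(5, 200, 5),      # regular: ApEn below 0.4
                   seeded_noise(1000, 52),    # irregular
                   seeded_noise(1000, 53))
  mask <- classify_components(sources)
  expect_equal(mask$keep, c(FALSE, TRUE, TRUE))
  expect_lt(mask$apen[1], 0.4)
  expect_gt(min(mask$apen[2:3]), 0.4)

  expect_warning(classify_components(sources[2:3, ]), "Nothing|nothing")
  expect_warning(classify_components(sources[c(1, 1), ] + 0), "removed")

  # monotone threshold property: a higher cutoff never rescues a source
  m_lo <- suppressWarnings(classify_components(sources, threshold = 0.2))
  m_hi <- suppressWarnings(classify_components(sources, threshold = 1.0))
  expect_true(all(which(!m_lo$keep) %in% which(!m_hi$keep)))
})

test_that("component removal zeroes exactly the rejected sources", {
  case <- make_sobi_case(4)
  X <- case$X - rowMeans(case$X)      # exactly centred channels
  res <- sobi_separate(X)

  all_keep <- tibble::tibble(source = 1:4, apen = rep(1, 4),
                             keep = rep(TRUE, 4))
  out <- remove_components(res, all_keep)
  expect_lt(max(abs(out - X)) / max(abs(X)), 1e-6)

  none_keep <- dplyr::mutate(all_keep, keep = FALSE)
  out0 <- remove_components(res, none_keep)
  expect_lt(max(abs(out0)), 1e-10)

  expect_error(remove_components(res, c(TRUE, FALSE)), "length")
})
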
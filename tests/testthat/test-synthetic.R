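test_that("rms matches its definition", {
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_equal(rms(rep(-2, 10)), 2)
  expect_equal(rms(rep(0, 5)), 0)
  expect_error(rms(numeric(0)), "non-empty")
})

test_that("generators are deterministic per seed", {
  expect_identical(gen_pure_eeg(10, 200, seed = 5), gen_pure_eeg(10, 200, seed = 5))
  expect_identical(gen_eog(10, 200, seed = 5), gen_eog(10, 200, seed = 5))
  expect_false(identical(gen_pure_eeg(10, 200, seed = 5),
                         gen_pure_eeg(10, 200, seed = 6)))
  # the caller's RNG stream is untouched
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(gen_pure_eeg(1, 200, seed = 9))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("surrogate EEG has the intended spectral and entropy character", {
  x <- gen_pure_eeg(10, 200, seed = 8)
  expect_length(x, 2000)
  expect_equal(sd(x), 1, tolerance = 1e-9)
  pf <- psd_features(x, 200)
  expect_gt(pf$psd_rel_alpha, 0)
  expect_lt(pf$psd_rel_alpha, 1)
  expect_gt(pf$psd_rel_delta, pf$psd_rel_beta)  # 1/f weighting

  # entropy separation from ocular surrogates (small batch; the full-size
  # check runs in the acceptance suite)
  ae_eeg <- vapply(1:30, function(s) approximate_entropy(gen_pure_eeg(10, 200, s)),
                   numeric(1))
  ae_eog <- vapply(1:30, function(s) approximate_entropy(gen_eog(10, 200, s)),
                   numeric(1))
  expect_gt(min(ae_eeg), 0.4)
  expect_lt(max(ae_eog), 0.4)
})

test_that("surrogate EOG is slow, high-amplitude and optional-blink", {
  e <- gen_eog(10, 200, seed = 7)
  p <- welch_psd(e, 200)
  df <- p$freq[2] - p$freq[1]
  frac_slow <- sum(p$psd[p$freq < 5]) / sum(p$psd)
  expect_gte(frac_slow, 0.9)

  z <- gen_eog(10, 200, seed = 7, blink_rate = 0, drift_sd = 0)
  expect_true(all(z == 0))

  # blinks reach well above the unit EEG scale
  many <- gen_eog(30, 200, seed = 10, blink_rate = 30)
  expect_gt(max(abs(many)), 2.5)
})

test_that("mixing hits the requested SNR exactly", {
  p <- gen_pure_eeg(10, 200, seed = 11)
  e <- gen_eog(10, 200, seed = 12)
  mx <- mix_eeg_eog(p, e, snr = 1)
  expect_equal(rms(p), rms(mx$spec$theta * e), tolerance = 1e-9)
  expect_equal(mx$mixture, p + mx$spec$theta * e)

  # inverse proportionality of the weight
  th_half <- mix_eeg_eog(p, e, 0.5)$spec$theta
  th_one <- mix_eeg_eog(p, e, 1)$spec$theta
  expect_equal(th_half, 2 * th_one, tolerance = 1e-12)

  # linearity: common scaling leaves theta unchanged
  mx2 <- mix_eeg_eog(3 * p, 3 * e, snr = 1)
  expect_equal(mx2$spec$theta, th_one, tolerance = 1e-12)
  expect_equal(mx2$mixture, 3 * mx$mixture, tolerance = 1e-12)

  expect_error(mix_eeg_eog(p, rep(0, 2000), 1), "zero RMS")
  expect_error(mix_eeg_eog(p, e[1:10], 1), "length")
})

test_that("the labelled corpus encodes contamination in theta and label", {
  corp <- gen_corpus(6, 6, seed = 13)
  expect_equal(nrow(corp), 12)
  expect_true(all((corp$theta > 0) == (corp$label == 1)))
  expect_true(all(is.infinite(corp$snr[corp$label == 0])))
  # clean rows are their own ground truth; contaminated rows differ from it
  expect_identical(corp$samples[[1]], corp$pure[[1]])
  expect_gt(rms(corp$samples[[7]] - corp$pure[[7]]), 0)
  expect_identical(gen_corpus(6, 6, seed = 13), corp)
})

test_that("a corpus written to disk round-trips through its manifest", {
  dir <- withr::local_tempdir()
  corp <- gen_corpus(3, 3, seed = 14)
  man <- write_corpus(corp, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(man), 6)
  seg <- utils::read.csv(file.path(dir, man$file[1]))
  expect_equal(seg$eeg, corp$samples[[1]], tolerance = 1e-12)
})

test_that("long records segment into stationary pieces", {
  long <- eeg_recording(gen_pure_eeg(60, 200, seed = 15), fs = 200)
  segs <- segment_signal(long, window_s = 10)
  sds <- vapply(segs$samples, sd, numeric(1))
  expect_true(all(sds > 0.7 & sds < 1.3))
})
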
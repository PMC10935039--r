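test_that("text recordings round-trip and require a sampling rate", {
  rec <- eeg_recording(list(F3 = seeded_noise(2000, 1),
                            C3 = seeded_noise(2000, 2)), fs = 200)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path, fs_override = 200)
  expect_equal(back$labels, c("F3", "C3"))
  expect_equal(back$data$F3, rec$data$F3, tolerance = 1e-12)

  # single column, no header
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(format(seeded_noise(2000, 3), digits = 10), p2)
  r2 <- read_recording(p2, fs_override = 200)
  expect_length(r2$data, 1)
  expect_length(r2$data[[1]], 2000)

  expect_error(read_recording(p2), "fs_override")
  expect_error(read_recording("no/such/file.csv"), "not found")
})

test_that("EDF recordings round-trip through the 16-bit container", {
  rec <- eeg_recording(list(F3 = 50 * make_tone(7, 200, 60),
                            C3 = 20 * seeded_noise(12000, 4)), fs = 200)
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$fs, 200)
  expect_equal(back$labels, c("F3", "C3"))
  expect_length(back$data$F3, 12000)
  # 16-bit quantisation: errors bounded by one digital step
  step <- diff(range(rec$data$C3)) / 65535
  expect_lt(max(abs(back$data$C3 - rec$data$C3)), 1.01 * step)
})

test_that("segmentation drops trailing partial windows", {
  rec60 <- eeg_recording(seeded_noise(12000, 5), fs = 200)
  segs <- segment_signal(rec60, window_s = 10)
  expect_equal(nrow(segs), 6)
  expect_true(all(lengths(segs$samples) == 2000))
  expect_equal(segs$start_index, (0:5) * 2000)

  rec65 <- eeg_recording(seeded_noise(13000, 6), fs = 200)
  expect_equal(nrow(segment_signal(rec65, window_s = 10)), 6)

  rec5 <- eeg_recording(seeded_noise(1000, 7), fs = 200)
  expect_warning(s0 <- segment_signal(rec5, window_s = 10), "shorter")
  expect_equal(nrow(s0), 0)

  expect_error(segment_signal(rec60, channel = "nope"), "channel")
})

test_that("splicing replaces exactly the listed windows", {
  rec <- eeg_recording(seeded_noise(12000, 8), fs = 200)
  segs <- segment_signal(rec, window_s = 10)

  # empty cleaned list: bit-identical output
  out <- splice_segments(rec, 1, segs[0, ])
  expect_identical(out$data[[1]], rec$data[[1]])

  # replace one window with zeros: only those samples change
  repl <- segs[2, ]
  repl$samples <- list(rep(0, 2000))
  out <- splice_segments(rec, 1, repl)
  expect_equal(out$data[[1]][2001:4000], rep(0, 2000))
  expect_identical(out$data[[1]][-(2001:4000)], rec$data[[1]][-(2001:4000)])

  # segment then splice everything back unmodified: identity
  out <- splice_segments(rec, 1, segs)
  expect_identical(out$data[[1]], rec$data[[1]])

  # overlap and range errors
  bad <- segs[1:2, ]
  bad$start_index <- c(0, 1000)
  expect_error(splice_segments(rec, 1, bad), "overlap")
  far <- segs[1, ]
  far$start_index <- 11999
  expect_error(splice_segments(rec, 1, far), "outside")
})

test_that("recording invariants are enforced", {
  expect_error(eeg_recording(list(a = 1:10, b = 1:5), fs = 200), "equal length")
  expect_error(eeg_recording(1:10, fs = 0), "fs")
})
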
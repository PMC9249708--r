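test_that("Welch PSD satisfies Parseval for tones and white noise", {
  srate <- 256
  t <- seq(0, 30 - 1 / srate, 1 / srate)
  A <- 20
  ps <- welch_psd(A * sin(2 * pi * 13 * t), srate)
  df <- ps$freq[2] - ps$freq[1]
  total <- sum(ps$psd) * df
  expect_lt(abs(total - A^2 / 2) / (A^2 / 2), 0.05)
  # energy concentrated in fast sigma
  sig_band <- trapz_band(ps$freq, ps$psd, 12, 15)
  expect_gt(sig_band / total, 0.95)
  # 14 Hann segments per 30-s epoch at 4 s and 50% overlap
  expect_equal(length(seq(1, length(t) - 4 * srate + 1, by = 2 * srate)),
               14L)
  # zero in, zero out
  expect_equal(welch_psd(0 * t, srate)$psd, rep(0, length(ps$psd)))
  # white-noise variance recovered (50 epochs averaged)
  set.seed(12)
  tot <- replicate(50, {
    p <- welch_psd(rnorm(length(t), sd = 3), srate)
    sum(p$psd) * df
  })
  expect_lt(abs(mean(tot) - 9) / 9, 0.10)
  expect_error(welch_psd(rnorm(100), srate), "parameter error")
})

test_that("relative band powers partition the analysis range to 100%", {
  sim <- generate_eeg(eeg_sim_config(seed = 6))
  mask <- rep(TRUE, length(sim$hypnogram$stages))
  bp <- stage_band_power(sim$recording, sim$hypnogram, mask)
  parts <- bp[bp$band != "total", ]
  sums <- tapply(parts$rel_pct,
                 interaction(parts$stage, parts$channel, drop = TRUE), sum)
  expect_true(all(abs(sums - 100) < 1e-6))
  expect_true(all(parts$abs_uv2 >= 0))
})

test_that("a pure 13-Hz tone in S2 puts >95% of relative power in fast
           sigma", {
  srate <- 128
  n_ep <- 4
  t <- seq(1 / srate, n_ep * 30, 1 / srate)
  rec <- make_recording(list(C3 = 30 * sin(2 * pi * 13 * t),
                             C4 = 30 * sin(2 * pi * 13 * t)), srate)
  hyp <- uniform_hypnogram("S2", n_ep)
  bp <- stage_band_power(rec, hyp, rep(TRUE, n_ep))
  fast <- bp[bp$channel == "C3" & bp$band == "fast_sigma" &
               bp$stage == "S2", ]
  expect_gt(fast$rel_pct, 95)
})

test_that("scaling the signal scales absolute power by c^2 and leaves
           relative power unchanged", {
  sim <- generate_eeg(eeg_sim_config(
    stage_sequence = data.frame(stage = "S2", minutes = 2), seed = 10))
  mask <- rep(TRUE, length(sim$hypnogram$stages))
  bp1 <- stage_band_power(sim$recording, sim$hypnogram, mask,
                          stages = "S2")
  rec2 <- sim$recording
  rec2$signal <- rec2$signal * 3
  bp2 <- stage_band_power(rec2, sim$hypnogram, mask, stages = "S2")
  expect_equal(bp2$abs_uv2, 9 * bp1$abs_uv2, tolerance = 1e-10)
  expect_equal(bp2$rel_pct, bp1$rel_pct, tolerance = 1e-10)
})

test_that("S2 band power ignores what happens in S3 epochs", {
  srate <- 128
  stages <- c("S2", "S3", "S2", "S3")
  t_ep <- 30 * srate
  set.seed(31)
  x <- rnorm(4 * t_ep, sd = 10)
  rec <- make_recording(list(C3 = x), srate)
  hyp <- hypnogram(stages)
  mask <- rep(TRUE, 4)
  bp1 <- stage_band_power(rec, hyp, mask, stages = "S2")
  x2 <- x
  x2[(t_ep + 1):(2 * t_ep)] <- 500 * sin(2 * pi * 13 *
                                           seq_len(t_ep) / srate)
  bp2 <- stage_band_power(make_recording(list(C3 = x2), srate), hyp,
                          mask, stages = "S2")
  expect_equal(bp1$abs_uv2, bp2$abs_uv2)
})

test_that("pair-average rows equal the arithmetic mean of their members", {
  sim <- generate_eeg(eeg_sim_config(
    stage_sequence = data.frame(stage = "S2", minutes = 3), seed = 13))
  mask <- rep(TRUE, length(sim$hypnogram$stages))
  bp <- stage_band_power(sim$recording, sim$hypnogram, mask,
                         stages = "S2")
  for (band in unique(bp$band)) {
    f3 <- bp$abs_uv2[bp$channel == "F3" & bp$band == band]
    f4 <- bp$abs_uv2[bp$channel == "F4" & bp$band == band]
    fm <- bp$abs_uv2[bp$channel == "F" & bp$band == band]
    expect_equal(fm, (f3 + f4) / 2, tolerance = 1e-12)
  }
})

test_that("a stage without artifact-free epochs yields flagged NA rows", {
  sim <- generate_eeg(eeg_sim_config(
    stage_sequence = data.frame(stage = c("S2", "S3"), minutes = c(1, 1)),
    seed = 2))
  mask <- sim$hypnogram$stages != "S3"   # every S3 epoch marked artifact
  bp <- stage_band_power(sim$recording, sim$hypnogram, mask)
  s3 <- bp[bp$stage == "S3", ]
  expect_true(all(is.na(s3$abs_uv2)))
  expect_true(all(s3$n_epochs == 0))
  expect_true(all(!is.na(bp$abs_uv2[bp$stage == "S2"])))
})
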
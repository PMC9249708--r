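test_that("EDF round trip preserves samples to 16-bit quantisation", {
  sim <- generate_eeg(eeg_sim_config(
    stage_sequence = data.frame(stage = "S2", minutes = 1), seed = 4))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(sim$recording, f)
  back <- read_edf(f)
  expect_identical(back$labels, sim$recording$labels)
  expect_identical(unname(back$roles), unname(sim$recording$roles))
  expect_equal(back$srate, sim$recording$srate)
  expect_equal(ncol(back$signal), ncol(sim$recording$signal))
  qstep <- max(apply(sim$recording$signal, 1,
                     function(x) diff(range(x)))) / 65535
  expect_lt(max(abs(back$signal - sim$recording$signal)), qstep)
})

test_that("truncated or malformed EDF files raise format errors", {
  sim <- generate_eeg(eeg_sim_config(
    stage_sequence = data.frame(stage = "S2", minutes = 1), seed = 4))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(sim$recording, f)
  raw <- readBin(f, "raw", file.size(f))
  f2 <- withr::local_tempfile(fileext = ".edf")
  writeBin(raw[1:3000], f2)
  expect_error(read_edf(f2), "format error")
  f3 <- withr::local_tempfile(fileext = ".edf")
  writeBin(raw[1:100], f3)
  expect_error(read_edf(f3), "format error")
  expect_error(read_edf(file.path(tempdir(), "absent.edf")), "not found")
})

test_that("contralateral-mastoid re-referencing follows hemisphere rules", {
  n <- 100
  rec <- make_recording(list(
    C3 = rep(5, n), C4 = rep(10, n), Fz = rep(8, n),
    A1 = rep(4, n), A2 = rep(0, n)
  ), srate = 100)
  out <- rereference_contralateral_mastoid(rec)
  expect_equal(out$signal["C3", ], rep(5, n))        # left - A2(=0)
  expect_equal(out$signal["C4", ], rep(10 - 4, n))   # right - A1
  expect_equal(out$signal["Fz", ], rep(8 - 2, n))    # midline - mean
  expect_equal(out$signal["A1", ], rec$signal["A1", ])
  # applying twice with freshly zeroed mastoids equals applying once
  zeroed <- out
  zeroed$signal["A1", ] <- 0
  zeroed$signal["A2", ] <- 0
  again <- rereference_contralateral_mastoid(zeroed)
  expect_equal(again$signal["C4", ], out$signal["C4", ])
  # missing mastoid
  rec2 <- make_recording(list(C3 = rep(1, n), A1 = rep(0, n)), srate = 100)
  expect_error(rereference_contralateral_mastoid(rec2), "missing-channel")
})

test_that("band-pass keeps the passband and crushes drift and EMG-range
           tones", {
  srate <- 256
  t <- seq(0, 60 - 1 / srate, 1 / srate)
  mk <- function(x) make_recording(list(C3 = x, A1 = 0 * x, A2 = 0 * x),
                                   srate)
  mid <- (length(t) %/% 4):(3 * length(t) %/% 4)
  # 10-Hz tone passes within 5%
  out <- bandpass_filter(mk(sin(2 * pi * 10 * t)))
  expect_gt(max(abs(out$signal["C3", mid])), 0.95)
  # 0.01-Hz drift reduced by at least 90%
  out <- bandpass_filter(mk(50 * sin(2 * pi * 0.01 * t)))
  expect_lt(max(abs(out$signal["C3", mid])), 5)
  # 45-Hz tone attenuated at least 20 dB
  out <- bandpass_filter(mk(sin(2 * pi * 45 * t)))
  expect_lt(max(abs(out$signal["C3", mid])), 0.1)
  # zero in, zero out; length and rate preserved
  out <- bandpass_filter(mk(0 * t))
  expect_equal(out$signal["C3", ], 0 * t)
  expect_equal(ncol(out$signal), length(t))
  expect_error(bandpass_filter(mk(t), high_hz = 200), "Nyquist")
})

test_that("artifact epochs are flagged by the +/-200 uV out-of-bounds
           test on the high-passed signal", {
  srate <- 128
  n_ep <- 4
  x <- rep(0, n_ep * 30 * srate)
  x[2 * 30 * srate + 100] <- 250          # epoch 3 (index 2): one bad sample
  rec <- make_recording(list(C3 = x), srate)
  hyp <- uniform_hypnogram("S2", n_ep)
  mask <- mark_artifact_epochs(rec, hyp)
  expect_identical(mask, c(TRUE, TRUE, FALSE, TRUE))
  # a 199-uV excursion survives
  y <- rep(0, n_ep * 30 * srate)
  y[100:110] <- 199
  expect_true(all(mark_artifact_epochs(make_recording(list(C3 = y), srate),
                                       hyp)))
})

test_that("sleep architecture matches hand-counted epochs", {
  hyp <- hypnogram(rep("S2", 20), lights_out_epoch = 0,
                   lights_on_epoch = 20)
  a <- sleep_architecture(hyp)
  expect_equal(a$TST_min, 10)
  expect_equal(a$SE_pct, 100)
  expect_equal(a$WASO_min, 0)

  hyp2 <- hypnogram(c("Wake", "Wake", "S1", "S2", "Wake", "S2"),
                    lights_out_epoch = 0, lights_on_epoch = 6)
  a2 <- sleep_architecture(hyp2)
  expect_equal(a2$SL_min, 1.0)
  expect_equal(a2$WASO_min, 0.5)
  expect_equal(a2$TST_min, 1.5)
  expect_equal(a2$SE_pct, 50)

  a3 <- sleep_architecture(hypnogram(rep("Wake", 10)))
  expect_equal(a3$TST_min, 0)
  expect_equal(a3$SE_pct, 0)
  expect_true(is.na(a3$SL_min))
})

test_that("SE identity and stage-minute accounting hold on random
           hypnograms", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(10:80, 1)
    hyp <- hypnogram(sample(c("Wake", "S1", "S2", "S3", "REM"), n,
                            replace = TRUE),
                     lights_out_epoch = 0, lights_on_epoch = n)
    a <- sleep_architecture(hyp)
    expect_equal(a$SE_pct, 100 * a$TST_min / a$TIB_min)
    expect_equal(sum(a$stage_minutes), a$TIB_min)
    expect_true(all(a$stage_minutes >= 0))
    expect_true(a$WASO_min >= 0)
  }
})

test_that("hypnogram CSV round trip preserves stages", {
  hyp <- hypnogram(c("Wake", "S1", "S2", "S3", "REM", "S2"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram_csv(hyp, f)
  back <- read_hypnogram_csv(f)
  expect_identical(back$stages, hyp$stages)
  expect_error(hypnogram(c("S2", "banana")), "unknown stage")
})
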
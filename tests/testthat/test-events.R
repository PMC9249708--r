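test_that("flat signals contain no detectable events", {
  srate <- 128
  n_ep <- 4
  x <- rep(0, n_ep * 30 * srate)
  rec <- make_recording(list(C3 = x), srate)
  hyp <- uniform_hypnogram("S2", n_ep)
  mask <- rep(TRUE, n_ep)
  expect_equal(nrow(detect_spindles(rec, hyp, mask)), 0L)
  expect_equal(nrow(detect_slow_oscillations(rec, hyp, mask)), 0L)
})

test_that("a single high-SNR sigma burst in 1/f noise yields exactly one
           spindle with the peak inside the burst", {
  srate <- 256
  mins <- 10
  set.seed(14)
  sim <- generate_eeg(eeg_sim_config(
    stage_sequence = data.frame(stage = "S2", minutes = mins),
    spindle_density_per_min = 0, so_density_per_min = 0, seed = 14))
  x <- sim$recording$signal["C3", ]
  sigma_rms <- sd(zerophase_bandpass(x, srate, 9, 15))
  tc <- 300                       # burst centre, seconds
  idx <- round((tc - 0.5) * srate):round((tc + 0.5) * srate)
  tt <- idx / srate - tc
  x[idx] <- x[idx] + 5 * sigma_rms * exp(-tt^2 / (2 * 0.25^2)) *
    sin(2 * pi * 13 * tt)
  rec <- make_recording(list(C3 = x), srate)
  mask <- rep(TRUE, length(sim$hypnogram$stages))
  sp <- detect_spindles(rec, sim$hypnogram, mask)
  expect_equal(nrow(sp), 1L)
  expect_gt(sp$peak_s, tc - 0.5)
  expect_lt(sp$peak_s, tc + 0.5)
  expect_true(sp$start_s < sp$peak_s && sp$peak_s < sp$end_s)
})

test_that("raising the threshold factor never increases the spindle
           count", {
  sim <- generate_eeg(eeg_sim_config(
    stage_sequence = data.frame(stage = "S2", minutes = 5),
    spindle_density_per_min = 2, so_density_per_min = 0, seed = 17))
  mask <- rep(TRUE, length(sim$hypnogram$stages))
  counts <- vapply(c(2, 3, 4, 5, 6), function(tf) {
    nrow(detect_spindles(sim$recording, sim$hypnogram, mask,
                         detector_config(threshold_factor = tf)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("spindles are confined to artifact-free NREM epochs", {
  sim <- generate_eeg(eeg_sim_config(
    stage_sequence = data.frame(stage = c("S2", "S2"), minutes = c(3, 3)),
    spindle_density_per_min = 2, so_density_per_min = 0, seed = 23))
  n_ep <- length(sim$hypnogram$stages)
  mask <- rep(TRUE, n_ep)
  mask[1:6] <- FALSE   # first 3 minutes artifactual
  sp <- detect_spindles(sim$recording, sim$hypnogram, mask)
  expect_true(all(sp$peak_s >= 6 * 30))
  # all-artifact night warns and returns nothing
  expect_warning(
    out <- detect_spindles(sim$recording, sim$hypnogram, rep(FALSE, n_ep)),
    "no artifact-free")
  expect_equal(nrow(out), 0L)
})

test_that("slow-oscillation detector equals the brute-force oracle on
           random low-frequency signals", {
  srate <- 128
  cfg <- detector_config()
  set.seed(41)
  n_signals <- 30
  n_events <- 0
  for (i in seq_len(n_signals)) {
    x <- random_slow_signal(120 * srate, srate)
    rec <- make_recording(list(C3 = x), srate)
    hyp <- uniform_hypnogram("S2", 4)
    so <- detect_slow_oscillations(rec, hyp, rep(TRUE, 4), cfg)
    xf <- zerophase_bandpass(x, srate, cfg$so_filter_low_hz,
                             cfg$so_filter_high_hz, cfg$so_filter_order)
    orc <- so_oracle(xf, srate, cfg)
    expect_equal(nrow(so), nrow(orc))
    if (nrow(so)) {
      expect_equal(so$zc_down1_s, orc$t1, tolerance = 1e-9)
      expect_equal(so$zc_up_s, orc$t2, tolerance = 1e-9)
      expect_equal(so$zc_down2_s, orc$t3, tolerance = 1e-9)
      expect_equal(so$trough_amp_uv, orc$trough, tolerance = 1e-9)
      expect_equal(so$peak_amp_uv, orc$peak, tolerance = 1e-9)
      n_events <- n_events + nrow(so)
    }
  }
  expect_gt(n_events, 5)  # the random family must actually exercise hits
})

test_that("slow-oscillation criteria boundaries behave as specified", {
  srate <- 256
  cfg <- detector_config()
  scan_amp <- function(amp) {
    nrow(so_criteria_scan(boundary_so_signal(srate, amp), srate, cfg))
  }
  expect_equal(scan_amp(100), 1L)
  expect_equal(scan_amp(80), 1L)      # trough exactly -80 uV is retained
  expect_equal(scan_amp(79.9), 0L)    # -79.9 uV is rejected
  # up-state bound: peak must stay under 140 uV
  expect_equal(nrow(so_criteria_scan(
    boundary_so_signal(srate, 100, up_amp = 150), srate, cfg)), 0L)
  # down-state duration bounds (+/- ~2 ms interpolation tolerance, so
  # probes sit 5 ms inside / 10 ms outside the bounds)
  scan_dur <- function(d) {
    nrow(so_criteria_scan(boundary_so_signal(srate, 100, down_dur = d),
                          srate, cfg))
  }
  expect_equal(scan_dur(0.305), 1L)
  expect_equal(scan_dur(0.995), 1L)
  expect_equal(scan_dur(0.29), 0L)
  expect_equal(scan_dur(1.01), 0L)
  # maximum event length: stretch the up state past 10 s total
  long <- boundary_so_signal(srate, 100, up_dur = 9.8)
  expect_equal(nrow(so_criteria_scan(long, srate, cfg)), 0L)
})

test_that("coupling window admits offsets within +/-1.25 s and pairing is
           per slow oscillation", {
  cfg <- detector_config()
  sos <- data.frame(channel = "C3", trough_s = 100, stage = "S2")
  mk_sp <- function(pk) data.frame(channel = "C3", peak_s = pk)
  offs <- c(-1.5, -1.25, 0, 1.25, 1.5)
  got <- vapply(offs, function(o) {
    nrow(couple_so_spindles(sos, mk_sp(100 + o), cfg)) == 1L
  }, logical(1))
  expect_identical(got, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  # 1.0 s after the trough couples; 1.5 s does not
  expect_equal(nrow(couple_so_spindles(sos, mk_sp(101), cfg)), 1L)
  expect_equal(nrow(couple_so_spindles(sos, mk_sp(101.5), cfg)), 0L)
  # different channel never couples
  expect_equal(nrow(couple_so_spindles(
    sos, data.frame(channel = "C4", peak_s = 100), cfg)), 0L)
  # empty inputs
  expect_equal(nrow(couple_so_spindles(sos[0, ], mk_sp(100), cfg)), 0L)
  # one spindle inside two SO windows couples to both
  sos2 <- data.frame(channel = "C3", trough_s = c(99.5, 100.5),
                     stage = "S2")
  expect_equal(nrow(couple_so_spindles(sos2, mk_sp(100), cfg)), 2L)
})

test_that("time reversal negates coupling offsets and preserves the pair
           count", {
  set.seed(55)
  cfg <- detector_config()
  T_end <- 600
  sos <- data.frame(channel = "C3", trough_s = sort(runif(20, 10, 590)),
                    stage = "S2")
  sp <- data.frame(channel = "C3", peak_s = sort(runif(30, 10, 590)))
  fwd <- couple_so_spindles(sos, sp, cfg)
  rsos <- data.frame(channel = "C3", trough_s = T_end - sos$trough_s,
                     stage = "S2")
  rsp <- data.frame(channel = "C3", peak_s = T_end - sp$peak_s)
  rev <- couple_so_spindles(rsos, rsp, cfg)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(rev$offset_s), sort(-fwd$offset_s), tolerance = 1e-12)
})

test_that("event density divides stage-matched counts by stage minutes", {
  hyp <- hypnogram(rep(c("S2", "S3"), times = c(80, 20)))  # 40 + 10 min
  ev <- data.frame(stage = c(rep("S2", 20), rep("S3", 5)),
                   channel = "C3")
  expect_equal(event_density(ev, hyp, "S2"), 0.5)
  expect_equal(event_density(ev, hyp, "S3"), 0.5)
  expect_equal(event_density(ev[0, ], hyp, "S2"), 0)
  expect_warning(d <- event_density(ev, hyp, "REM"), "undefined")
  expect_true(is.na(d))
})

test_that("ground-truth spindle density recovers the configured rate on a
           30-minute night", {
  cfg <- eeg_sim_config(
    stage_sequence = data.frame(stage = c("S2", "S3"),
                                minutes = c(20, 10)),
    spindle_density_per_min = 2, seed = 77)
  sim <- generate_eeg(cfg)
  gt <- sim$ground_truth$spindles
  for (st in c("S2", "S3")) {
    dens <- event_density(gt, sim$hypnogram, st)
    expect_lt(abs(dens - 2) / 2, 0.10)
  }
})
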
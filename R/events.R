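#' Detect sleep spindles by wavelet thresholding
#'
#' Per channel, the signal is transformed with a complex Morlet wavelet
#' centred in the sigma band; the detection statistic is the squared
#' wavelet magnitude smoothed with a 100-ms moving average.  A spindle is
#' one contiguous excursion of this statistic above
#' `threshold_factor` times its mean — the mean taken over all
#' artifact-free samples of the searched NREM stages of that channel, so
#' the threshold is a stable per-channel, per-night baseline.  Excursions
#' are kept when their duration lies within the configured bounds and the
#' epoch containing the peak is an artifact-free epoch of a searched
#' stage.
#'
#' @param rec an [eeg_recording()].
#' @param hyp the aligned [hypnogram()].
#' @param mask logical artifact-free epoch mask.
#' @param cfg a [detector_config()].
#' @return data.frame of spindle events: `channel`, `start_s`, `end_s`,
#'   `peak_s`, `peak_amplitude` (wavelet-envelope microvolts), `stage`.
#'   Zero rows (with a `no_nrem` attribute set) when no artifact-free
#'   NREM sleep exists.
#' @export
detect_spindles <- function(rec, hyp, mask, cfg = detector_config()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(hyp, "hypnogram"))
  empty <- data.frame(channel = character(), start_s = numeric(),
                      end_s = numeric(), peak_s = numeric(),
                      peak_amplitude = numeric(), stage = character(),
                      stringsAsFactors = FALSE)
  chans <- rec$labels[rec$roles == cfg$channel_role]
  spe <- round(hyp$epoch_len_s * rec$srate)
  good_ep <- hyp$stages %in% cfg$stages & mask
  sample_ok <- sample_mask_from_epochs(good_ep, spe, ncol(rec$signal))
  if (!any(sample_ok)) {
    warning("no artifact-free NREM samples; no spindles detectable",
            call. = FALSE)
    attr(empty, "no_nrem") <- TRUE
    return(empty)
  }
  out <- list()
  for (ch in chans) {
    amp <- morlet_amplitude(rec$signal[ch, ], rec$srate,
                            cfg$wavelet_f0_hz, cfg$wavelet_sigma_t_s)
    stat <- if (cfg$threshold_stat == "power") amp^2 else amp
    trace <- moving_average(stat, round(cfg$ma_window_s * rec$srate))
    baseline <- mean(trace[sample_ok])
    if (!is.finite(baseline) || baseline <= 0) next
    thr <- cfg$threshold_factor * baseline
    runs <- contiguous_runs(trace > thr)
    if (!nrow(runs)) next
    for (k in seq_len(nrow(runs))) {
      i0 <- runs$start[k]; i1 <- runs$end[k]
      dur <- (i1 - i0 + 1L) / rec$srate
      if (dur < cfg$spindle_min_dur_s || dur > cfg$spindle_max_dur_s) next
      seg <- trace[i0:i1]
      ipk <- i0 + which.max(seg) - 1L
      ep <- epoch_at_time(hyp, (ipk - 1L) / rec$srate) + 1L
      if (ep < 1L || ep > length(good_ep) || !good_ep[ep]) next
      out[[length(out) + 1L]] <- data.frame(
        channel = ch,
        start_s = (i0 - 1L) / rec$srate,
        end_s = (i1 - 1L) / rec$srate,
        peak_s = (ipk - 1L) / rec$srate,
        peak_amplitude = if (cfg$threshold_stat == "power")
          sqrt(trace[ipk]) else trace[ipk],
        stage = hyp$stages[ep],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$channel, res$peak_s), , drop = FALSE]
}

#' Detect slow oscillations by zero-crossing criteria
#'
#' The channel is band-pass filtered (zero phase, default 0.1-4 Hz) and
#' scanned for consecutive zero-crossing triples of pattern
#' down / up / down (positive-to-negative, negative-to-positive,
#' positive-to-negative, with sub-sample crossing times by linear
#' interpolation).  A triple is retained as a slow oscillation when
#' \enumerate{
#'   \item the down-state duration (first down crossing to up crossing)
#'     lies within `[so_down_dur_min_s, so_down_dur_max_s]`,
#'   \item the whole event is shorter than `so_max_len_s`,
#'   \item the trough between the first two crossings reaches
#'     `-so_down_amp_min_uv` or below, and
#'   \item the up-state peak stays below `+so_up_amp_max_uv`.
#' }
#' Events are restricted to artifact-free epochs of the searched stages
#' (stage taken at the trough).
#'
#' @inheritParams detect_spindles
#' @return data.frame of SO events: `channel`, `zc_down1_s`, `zc_up_s`,
#'   `zc_down2_s`, `trough_s`, `trough_amp_uv` (negative),
#'   `peak_amp_uv` (positive), `stage`.
#' @export
detect_slow_oscillations <- function(rec, hyp, mask,
                                     cfg = detector_config()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(hyp, "hypnogram"))
  chans <- rec$labels[rec$roles == cfg$channel_role]
  good_ep <- hyp$stages %in% cfg$stages & mask
  out <- list()
  for (ch in chans) {
    xf <- zerophase_bandpass(rec$signal[ch, ], rec$srate,
                             cfg$so_filter_low_hz, cfg$so_filter_high_hz,
                             cfg$so_filter_order)
    ev <- so_criteria_scan(xf, rec$srate, cfg)
    if (!nrow(ev)) next
    ep <- epoch_at_time(hyp, ev$trough_s) + 1L
    keep <- ep >= 1L & ep <= length(good_ep)
    keep[keep] <- good_ep[ep[keep]]
    ev <- ev[keep, , drop = FALSE]
    if (!nrow(ev)) next
    ev$stage <- hyp$stages[ep[keep]]
    ev$channel <- ch
    out[[length(out) + 1L]] <- ev
  }
  if (!length(out)) {
    return(data.frame(channel = character(), zc_down1_s = numeric(),
                      zc_up_s = numeric(), zc_down2_s = numeric(),
                      trough_s = numeric(), trough_amp_uv = numeric(),
                      peak_amp_uv = numeric(), stage = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("channel", "zc_down1_s", "zc_up_s", "zc_down2_s", "trough_s",
          "trough_amp_uv", "peak_amp_uv", "stage")]
}

#' Apply the slow-oscillation criteria to an already-filtered signal
#'
#' The criteria core of [detect_slow_oscillations()], exposed so the
#' zero-crossing logic can be exercised on constructed signals without a
#' recording container (and compared against brute-force enumeration).
#'
#' @param xf numeric vector, the band-pass filtered signal in microvolts.
#' @param srate sampling rate in Hz.
#' @param cfg a [detector_config()].
#' @return data.frame with zero-crossing times, trough and peak
#'   amplitudes and times (no stage/channel columns).
#' @export
so_criteria_scan <- function(xf, srate, cfg = detector_config()) {
  empty <- data.frame(zc_down1_s = numeric(), zc_up_s = numeric(),
                      zc_down2_s = numeric(), trough_s = numeric(),
                      trough_amp_uv = numeric(), peak_amp_uv = numeric())
  zc <- zero_crossings(xf, srate)
  if (nrow(zc) < 3L) return(empty)
  out <- list()
  for (i in seq_len(nrow(zc) - 2L)) {
    if (zc$dir[i] != "down" || zc$dir[i + 1L] != "up" ||
        zc$dir[i + 2L] != "down") next
    t1 <- zc$t[i]; t2 <- zc$t[i + 1L]; t3 <- zc$t[i + 2L]
    down_dur <- t2 - t1
    if (down_dur < cfg$so_down_dur_min_s ||
        down_dur > cfg$so_down_dur_max_s) next
    if (t3 - t1 >= cfg$so_max_len_s) next
    # sample i has time (i - 1) / srate; take samples strictly after the
    # first crossing up to and including the second
    rng <- function(ta, tb) {
      i0 <- max(1L, floor(ta * srate + 1) + 1L)
      i1 <- min(length(xf), floor(tb * srate + 1))
      if (i1 < i0) integer(0) else i0:i1
    }
    idx_down <- rng(t1, t2)
    idx_up <- rng(t2, t3)
    if (!length(idx_down) || !length(idx_up)) next
    trough <- min(xf[idx_down])
    if (trough > -cfg$so_down_amp_min_uv) next
    peak <- max(xf[idx_up])
    if (peak >= cfg$so_up_amp_max_uv) next
    itr <- idx_down[which.min(xf[idx_down])]
    out[[length(out) + 1L]] <- data.frame(
      zc_down1_s = t1, zc_up_s = t2, zc_down2_s = t3,
      trough_s = (itr - 1L) / srate,
      trough_amp_uv = trough, peak_amp_uv = peak
    )
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# Sign-change zero crossings with linearly interpolated sub-sample times.
# Returns data.frame(t, dir) with dir "down" (+ to -) or "up" (- to +),
# times in seconds with t = 0 at the first sample.
zero_crossings <- function(x, srate) {
  s <- sign(x)
  # treat exact zeros as belonging to the previous sign regime
  for (i in which(s == 0)) s[i] <- if (i > 1L) s[i - 1L] else 1
  ch <- which(s[-1L] != s[-length(s)])
  if (!length(ch)) {
    return(data.frame(t = numeric(), dir = character(),
                      stringsAsFactors = FALSE))
  }
  frac <- x[ch] / (x[ch] - x[ch + 1L])
  frac[!is.finite(frac)] <- 0
  data.frame(t = (ch - 1L + frac) / srate,
             dir = ifelse(s[ch + 1L] < 0, "down", "up"),
             stringsAsFactors = FALSE)
}

# Contiguous TRUE runs of a logical vector as data.frame(start, end).
contiguous_runs <- function(flag) {
  r <- rle(as.vector(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# TRUE per sample when the sample lies in a TRUE epoch.
sample_mask_from_epochs <- function(epoch_flags, spe, n_samples) {
  m <- rep(rep(epoch_flags, each = spe), length.out = n_samples)
  if (length(m) < n_samples) m <- c(m, rep(FALSE, n_samples - length(m)))
  m
}

#' Pair slow oscillations with coupled spindles
#'
#' A spindle counts as coupled to a slow oscillation when its envelope
#' peak falls within `coupling_window_s` (default 1.25 s) before or after
#' the SO down-state (trough) time, on the same channel.  Pairing is
#' exhaustive per SO: a spindle lying inside the windows of two SOs
#' yields two coupled events.
#'
#' @param sos data.frame from [detect_slow_oscillations()].
#' @param spindles data.frame from [detect_spindles()].
#' @param cfg a [detector_config()].
#' @return data.frame of coupled events: `channel`, `so_trough_s`,
#'   `spindle_peak_s`, `offset_s` (spindle peak minus SO trough), `stage`
#'   (of the SO), plus row indices `so_row` / `spindle_row` into the
#'   inputs.
#' @export
couple_so_spindles <- function(sos, spindles, cfg = detector_config()) {
  empty <- data.frame(channel = character(), so_trough_s = numeric(),
                      spindle_peak_s = numeric(), offset_s = numeric(),
                      stage = character(), so_row = integer(),
                      spindle_row = integer(), stringsAsFactors = FALSE)
  if (!nrow(sos) || !nrow(spindles)) return(empty)
  out <- list()
  for (i in seq_len(nrow(sos))) {
    same <- which(spindles$channel == sos$channel[i])
    if (!length(same)) next
    off <- spindles$peak_s[same] - sos$trough_s[i]
    hit <- which(abs(off) <= cfg$coupling_window_s)
    for (h in hit) {
      out[[length(out) + 1L]] <- data.frame(
        channel = sos$channel[i],
        so_trough_s = sos$trough_s[i],
        spindle_peak_s = spindles$peak_s[same[h]],
        offset_s = off[h],
        stage = if ("stage" %in% names(sos)) sos$stage[i] else NA_character_,
        so_row = i,
        spindle_row = same[h],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Event density per minute of a sleep stage
#'
#' Number of events whose `stage` column matches, divided by the minutes
#' spent in that stage (all epochs of the stage in the hypnogram).
#'
#' @param events data.frame with a `stage` column (and optionally
#'   `channel`).
#' @param hyp a [hypnogram()].
#' @param stage stage label, e.g. `"S2"`.
#' @param channel optional channel label to restrict the count.
#' @return events per minute, or `NA` (with a warning) when the stage has
#'   zero minutes.
#' @export
event_density <- function(events, hyp, stage, channel = NULL) {
  mins <- sum(hyp$stages == stage) * hyp$epoch_len_s / 60
  if (mins <= 0) {
    warning("undefined density: zero minutes in stage ", stage,
            call. = FALSE)
    return(NA_real_)
  }
  n <- if (nrow(events) == 0) 0L else {
    sel <- events$stage == stage
    if (!is.null(channel)) sel <- sel & events$channel == channel
    sum(sel)
  }
  n / mins
}
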
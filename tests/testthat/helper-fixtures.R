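# Fixture builders and independent oracles shared across test files.
# Everything is generated in code; no data files.

# Recording with the given channel vectors (list label -> numeric vector).
make_recording <- function(channels, srate, roles = NULL) {
  sig <- do.call(rbind, channels)
  rownames(sig) <- names(channels)
  eeg_recording(sig, srate, labels = names(channels), roles = roles)
}

# Single-central-channel recording wrapping one signal vector.
single_channel_recording <- function(x, srate, label = "C3") {
  make_recording(stats::setNames(list(x), label), srate)
}

# Hypnogram of n_epochs identical stages.
uniform_hypnogram <- function(stage, n_epochs, epoch_len_s = 30) {
  hypnogram(rep(stage, n_epochs), epoch_len_s = epoch_len_s)
}

# Random low-frequency test signal: a sum of sinusoids with frequencies,
# amplitudes and phases drawn wide enough that some zero-crossing triples
# qualify as slow oscillations and many near-misses violate one criterion.
random_slow_signal <- function(n, srate) {
  k <- sample(3:6, 1)
  f <- stats::runif(k, 0.15, 2.5)
  a <- stats::runif(k, 20, 90)
  ph <- stats::runif(k, 0, 2 * pi)
  t <- (0:(n - 1)) / srate
  rowSums(vapply(seq_len(k),
                 function(i) a[i] * sin(2 * pi * f[i] * t + ph[i]),
                 numeric(n)))
}

# ---------------------------------------------------------------------------
# Brute-force slow-oscillation oracle: literal reading of the five criteria
# applied to an already-filtered signal, written as plain loops so it shares
# no scanning code with the package implementation.
so_oracle <- function(xf, srate, cfg = detector_config()) {
  n <- length(xf)
  s <- sign(xf)
  for (i in which(s == 0)) s[i] <- if (i > 1) s[i - 1] else 1
  cross_t <- c(); cross_dir <- c()
  for (i in 1:(n - 1)) {
    if (s[i] != s[i + 1]) {
      frac <- xf[i] / (xf[i] - xf[i + 1])
      if (!is.finite(frac)) frac <- 0
      cross_t <- c(cross_t, (i - 1 + frac) / srate)
      cross_dir <- c(cross_dir, if (s[i + 1] < 0) "down" else "up")
    }
  }
  hits <- list()
  if (length(cross_t) >= 3) {
    for (i in 1:(length(cross_t) - 2)) {
      # criterion 1: down, then up, then down zero-crossing
      if (cross_dir[i] != "down") next
      if (cross_dir[i + 1] != "up") next
      if (cross_dir[i + 2] != "down") next
      t1 <- cross_t[i]; t2 <- cross_t[i + 1]; t3 <- cross_t[i + 2]
      # criterion 2: down-state duration within bounds
      if (t2 - t1 < cfg$so_down_dur_min_s) next
      if (t2 - t1 > cfg$so_down_dur_max_s) next
      # criterion 3: maximum event length
      if (t3 - t1 >= cfg$so_max_len_s) next
      i_dn <- max(1, floor(t1 * srate + 1) + 1):min(n, floor(t2 * srate + 1))
      i_up <- max(1, floor(t2 * srate + 1) + 1):min(n, floor(t3 * srate + 1))
      # criterion 4: down-state amplitude
      trough <- min(xf[i_dn])
      if (!(trough <= -cfg$so_down_amp_min_uv)) next
      # criterion 5: up-state amplitude
      peak <- max(xf[i_up])
      if (!(peak < cfg$so_up_amp_max_uv)) next
      hits[[length(hits) + 1]] <- c(t1 = t1, t2 = t2, t3 = t3,
                                    trough = trough, peak = peak)
    }
  }
  if (!length(hits)) {
    return(data.frame(t1 = numeric(), t2 = numeric(), t3 = numeric(),
                      trough = numeric(), peak = numeric()))
  }
  as.data.frame(do.call(rbind, hits))
}

# Brute-force Holm decision: for each sorted prefix check the whole
# step-down schedule explicitly.
holm_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject_sorted <- logical(m)
  for (i in seq_len(m)) {
    ok <- TRUE
    for (j in seq_len(i)) {
      if (p[ord[j]] > alpha / (m - j + 1)) ok <- FALSE
    }
    reject_sorted[i] <- ok
  }
  out <- logical(m)
  out[ord] <- reject_sorted
  out
}

# A clean piecewise slow-wave for boundary testing: positive lead lobe,
# down lobe of depth `down_amp` and duration `down_dur`, up lobe of height
# `up_amp`, then a shallow trailing dip to provide the closing down
# crossing.  Sampling is aligned so the down lobe's trough falls exactly
# on a sample.
boundary_so_signal <- function(srate, down_amp, up_amp = 40,
                               down_dur = 0.5, lead = 1.0, up_dur = 0.8) {
  t_lead <- seq(1 / srate, lead, by = 1 / srate)
  lead_lobe <- 5 * sin(pi * t_lead / lead)
  t_dn <- seq(1 / srate, down_dur, by = 1 / srate)
  down_lobe <- -down_amp * sin(pi * t_dn / down_dur)
  t_up <- seq(1 / srate, up_dur, by = 1 / srate)
  up_lobe <- up_amp * sin(pi * t_up / up_dur)
  t_tail <- seq(1 / srate, 1.0, by = 1 / srate)
  tail_lobe <- -5 * sin(pi * t_tail / 1.0)
  c(lead_lobe, down_lobe, up_lobe, tail_lobe, rep(0, srate))
}

# Spindle-vs-truth matching at a time tolerance, per channel.
event_recall_precision <- function(detected, truth, tol = 0.5,
                                   det_time = "peak_s",
                                   tru_time = "peak_s") {
  recall <- mean(vapply(seq_len(nrow(truth)), function(i) {
    any(detected$channel == truth$channel[i] &
          abs(detected[[det_time]] - truth[[tru_time]][i]) <= tol)
  }, logical(1)))
  precision <- mean(vapply(seq_len(nrow(detected)), function(i) {
    any(truth$channel == detected$channel[i] &
          abs(truth[[tru_time]] - detected[[det_time]][i]) <= tol)
  }, logical(1)))
  c(recall = recall, precision = precision)
}
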
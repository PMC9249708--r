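#' Generate a staged synthetic sleep-EEG recording with ground truth
#'
#' Builds a multi-channel recording of 1/f background noise, injects sleep
#' spindles and slow oscillations into the configured NREM stages, and
#' returns the exact times of every injected event as ground truth for
#' detector validation.  With a fixed configuration (including its `seed`)
#' the output is bit-identical across calls.
#'
#' Event counts follow the configured densities exactly:
#' `round(density * minutes)` events are injected per eligible stage.
#' Events are placed uniformly within epochs of their stage, at least
#' `min_separation_s` apart from same-type events, and entirely inside a
#' contiguous block of that stage.  Coupled spindles are centred at
#' `coupling_offset_s` after the trough of a randomly chosen slow
#' oscillation on the same channel.
#'
#' @param config an [eeg_sim_config()].
#' @return list with elements `recording` ([eeg_recording()]),
#'   `hypnogram` ([hypnogram()]) and `ground_truth` (list of data.frames
#'   `spindles`, `slow_oscillations`, `coupled_pairs`).
#' @export
generate_eeg <- function(config) {
  if (!inherits(config, "eeg_sim_config")) {
    stop("config must be an eeg_sim_config", call. = FALSE)
  }
  set.seed(config$seed)
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  if (n <= 0) stop("invalid config: zero duration", call. = FALSE)

  stages <- rep(config$stage_sequence$stage,
                times = round(config$stage_sequence$minutes * 2))
  hyp <- hypnogram(stages, epoch_len_s = 30,
                   lights_out_epoch = 0L,
                   lights_on_epoch = length(stages))

  labels <- names(config$channels)
  sig <- matrix(0, nrow = length(labels), ncol = n, dimnames = list(labels))
  for (i in seq_along(labels)) {
    rms <- if (config$channels[i] == "mastoid") {
      config$noise_rms_uv / 3  # references are comparatively quiet
    } else {
      config$noise_rms_uv
    }
    sig[i, ] <- oneoverf_noise(n, fs, config$noise_exponent, rms)
  }

  # events ride on the central channels (where spindle/SO detection looks)
  event_channels <- labels[config$channels == "central"]
  if (!length(event_channels)) {
    event_channels <- labels[config$channels %in%
                               c("frontal", "parietal", "occipital")][1]
  }
  if (!length(event_channels) || anyNA(event_channels)) {
    stop("invalid config: no scalp channel available for event injection",
         call. = FALSE)
  }

  # ---- slow oscillations ------------------------------------------------
  so_len <- config$so_down_dur_s * (1 + config$so_down_amp_uv /
                                      config$so_up_amp_uv)
  sos <- place_events(hyp, config$event_stages, config$so_density_per_min,
                      half_width_s = so_len / 2 + 0.1,
                      min_sep_s = config$min_separation_s,
                      duration_s = config$duration_s)
  so_truth <- NULL
  if (nrow(sos)) {
    sos$channel <- sample(event_channels, nrow(sos), replace = TRUE)
    for (k in seq_len(nrow(sos))) {
      ch <- match(sos$channel[k], labels)
      wav <- so_waveform(fs, config$so_down_amp_uv, config$so_up_amp_uv,
                         config$so_down_dur_s)
      start <- round((sos$center_s[k] - so_len / 2) * fs) + 1L
      idx <- start:(start + length(wav) - 1L)
      ok <- idx >= 1L & idx <= n
      sig[ch, idx[ok]] <- sig[ch, idx[ok]] + wav[ok]
    }
    so_truth <- data.frame(
      channel = sos$channel,
      trough_s = sos$center_s - so_len / 2 + config$so_down_dur_s / 2,
      down_amp_uv = config$so_down_amp_uv,
      up_amp_uv = config$so_up_amp_uv,
      stage = sos$stage,
      stringsAsFactors = FALSE
    )
  } else {
    so_truth <- data.frame(channel = character(), trough_s = numeric(),
                           down_amp_uv = numeric(), up_amp_uv = numeric(),
                           stage = character(), stringsAsFactors = FALSE)
  }

  # ---- spindles ---------------------------------------------------------
  sp_counts <- stage_event_counts(hyp, config$event_stages,
                                  config$spindle_density_per_min)

  coupled_pairs <- data.frame(so_index = integer(), spindle_index = integer(),
                              offset_s = numeric())
  sp_list <- list()
  # coupled spindles ride on SOs of the same stage; allocation is per stage
  # so the bookkeeping count round(density * minutes) holds stage by stage
  for (r in seq_len(nrow(sp_counts))) {
    st <- sp_counts$stage[r]
    n_coupled_st <- round(config$coupled_fraction * sp_counts$count[r])
    elig <- which(so_truth$stage == st)
    pick <- if (length(elig) <= n_coupled_st) elig else
      sort(sample(elig, n_coupled_st))
    for (j in pick) {
      peak <- so_truth$trough_s[j] + config$coupling_offset_s
      sp_list[[length(sp_list) + 1L]] <- data.frame(
        channel = so_truth$channel[j], peak_s = peak,
        stage = st, so_index = j,
        stringsAsFactors = FALSE
      )
    }
  }
  # remaining spindles placed uniformly per stage
  for (r in seq_len(nrow(sp_counts))) {
    st <- sp_counts$stage[r]
    already <- sum(vapply(sp_list, function(d) d$stage == st, logical(1)))
    need <- sp_counts$count[r] - already
    if (need <= 0) next
    placed <- place_events(hyp, st, density_per_min = NULL, n_events = need,
                           half_width_s = config$spindle_dur_s / 2,
                           min_sep_s = config$min_separation_s,
                           duration_s = config$duration_s,
                           avoid = vapply(sp_list, function(d) d$peak_s,
                                          numeric(1)))
    if (nrow(placed)) {
      placed$channel <- sample(event_channels, nrow(placed), replace = TRUE)
      for (k in seq_len(nrow(placed))) {
        sp_list[[length(sp_list) + 1L]] <- data.frame(
          channel = placed$channel[k], peak_s = placed$center_s[k],
          stage = placed$stage[k], so_index = NA_integer_,
          stringsAsFactors = FALSE
        )
      }
    }
  }

  sp_truth <- data.frame(channel = character(), start_s = numeric(),
                         end_s = numeric(), peak_s = numeric(),
                         stage = character(), stringsAsFactors = FALSE)
  if (length(sp_list)) {
    sp <- do.call(rbind, sp_list)
    sp <- sp[order(sp$peak_s), ]
    rownames(sp) <- NULL
    sigma <- config$spindle_dur_s / 4
    for (k in seq_len(nrow(sp))) {
      ch <- match(sp$channel[k], labels)
      idx0 <- round((sp$peak_s[k] - 2 * sigma) * fs)
      idx1 <- round((sp$peak_s[k] + 2 * sigma) * fs)
      idx <- max(1L, idx0):min(n, idx1)
      tt <- idx / fs - sp$peak_s[k]
      sig[ch, idx] <- sig[ch, idx] +
        config$spindle_amp_uv * exp(-tt^2 / (2 * sigma^2)) *
        sin(2 * pi * config$spindle_freq_hz * tt)
    }
    sp_truth <- data.frame(
      channel = sp$channel,
      start_s = sp$peak_s - config$spindle_dur_s / 2,
      end_s = sp$peak_s + config$spindle_dur_s / 2,
      peak_s = sp$peak_s,
      stage = sp$stage,
      stringsAsFactors = FALSE
    )
    cp <- which(!is.na(sp$so_index))
    if (length(cp)) {
      coupled_pairs <- data.frame(
        so_index = sp$so_index[cp],
        spindle_index = cp,
        offset_s = sp$peak_s[cp] - so_truth$trough_s[sp$so_index[cp]]
      )
    }
  }

  rec <- eeg_recording(sig, fs, labels = labels, roles = config$channels)
  list(recording = rec,
       hypnogram = hyp,
       ground_truth = list(spindles = sp_truth,
                           slow_oscillations = so_truth,
                           coupled_pairs = coupled_pairs))
}

# One-cycle asymmetric slow wave: half-sine down state of depth -down_amp
# and duration down_dur, followed by a half-sine up state whose duration is
# stretched so the waveform integrates to zero (up_dur = down_dur *
# down_amp / up_amp).  Zero net area keeps the shape stable under
# subsequent high-pass filtering.
so_waveform <- function(fs, down_amp, up_amp, down_dur) {
  up_dur <- down_dur * down_amp / up_amp
  t <- seq(1 / fs, down_dur + up_dur, by = 1 / fs)
  ifelse(t <= down_dur,
         -down_amp * sin(pi * t / down_dur),
         up_amp * sin(pi * (t - down_dur) / up_dur))
}

# Events to inject per stage: round(density * minutes in stage).
stage_event_counts <- function(hyp, stages, density_per_min) {
  mins <- vapply(stages, function(st)
    sum(hyp$stages == st) * hyp$epoch_len_s / 60, numeric(1))
  data.frame(stage = stages, minutes = mins,
             count = round(density_per_min * mins),
             stringsAsFactors = FALSE)
}

# Place events uniformly inside contiguous blocks of the given stage(s),
# respecting a minimum separation and keeping each event (half_width_s)
# fully inside its block.  Returns data.frame(center_s, stage).
place_events <- function(hyp, stages, density_per_min = NULL,
                         n_events = NULL, half_width_s, min_sep_s,
                         duration_s, avoid = numeric(0)) {
  out <- list()
  for (st in stages) {
    n_target <- if (is.null(n_events)) {
      mins <- sum(hyp$stages == st) * hyp$epoch_len_s / 60
      round(density_per_min * mins)
    } else n_events
    if (n_target <= 0) next
    # contiguous blocks of this stage, in seconds
    r <- rle(hyp$stages == st)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    blocks <- cbind((starts[r$values] - 1L) * hyp$epoch_len_s,
                    ends[r$values] * hyp$epoch_len_s)
    blocks[, 1L] <- blocks[, 1L] + half_width_s
    blocks[, 2L] <- pmin(blocks[, 2L], duration_s) - half_width_s
    blocks <- blocks[blocks[, 2L] > blocks[, 1L], , drop = FALSE]
    if (!nrow(blocks)) next
    widths <- blocks[, 2L] - blocks[, 1L]
    accepted <- numeric(0)
    guard <- 0L
    while (length(accepted) < n_target && guard < 5000L * n_target) {
      guard <- guard + 1L
      b <- sample.int(nrow(blocks), 1L, prob = widths)
      cand <- stats::runif(1L, blocks[b, 1L], blocks[b, 2L])
      if (all(abs(cand - c(accepted, avoid)) >= min_sep_s)) {
        accepted <- c(accepted, cand)
      }
    }
    if (length(accepted) < n_target) {
      warning("could only place ", length(accepted), " of ", n_target,
              " events in stage ", st, call. = FALSE)
    }
    if (length(accepted)) {
      out[[length(out) + 1L]] <- data.frame(center_s = sort(accepted),
                                            stage = st,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(center_s = numeric(), stage = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
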
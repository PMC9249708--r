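#' Configuration for the synthetic sleep-EEG generator
#'
#' Defines the staged night the generator emulates: a 1/f background per
#' channel plus stage-gated sleep spindles (Gaussian-windowed sigma bursts)
#' and slow oscillations (one-cycle asymmetric slow waves) injected at known
#' times, which become the detector ground truth.
#'
#' Spindles and slow oscillations are injected into every stage named in
#' `event_stages` at `spindle_density_per_min` / `so_density_per_min`
#' events per minute of that stage.  `spindle_dur_s` is the full width of
#' the Gaussian envelope at its +/- 2 sigma support.  A fraction
#' `coupled_fraction` of the spindles is placed at a fixed lag
#' `coupling_offset_s` after a slow-oscillation trough on the same channel,
#' giving ground-truth coupled pairs.
#'
#' @param stage_sequence data.frame with columns `stage` and `minutes`
#'   describing the night from lights out onward.  The default is a
#'   desk-scale 30-minute night (2 Wake, 3 S1, 12 S2, 8 S3, 5 REM).
#' @param sampling_rate_hz sampling rate; default 256 Hz (configurable up
#'   to clinical rates).
#' @param channels named character vector, role by label.
#' @param noise_exponent 1/f power-spectral slope of the background.
#' @param noise_rms_uv background RMS per channel in microvolts.
#' @param spindle_density_per_min spindle events per minute in each stage of
#'   `event_stages`.
#' @param spindle_freq_hz spindle carrier frequency in \[9, 15\] Hz.
#' @param spindle_amp_uv peak envelope amplitude of injected spindles.
#' @param spindle_dur_s spindle duration (+/- 2 sigma Gaussian support).
#' @param so_density_per_min slow-oscillation events per minute per stage.
#' @param so_down_amp_uv down-state (trough) amplitude, positive number.
#' @param so_up_amp_uv up-state (peak) amplitude.
#' @param so_down_dur_s duration of the injected down state in seconds.
#' @param coupled_fraction fraction of spindles coupled to a slow
#'   oscillation, in \[0, 1\].
#' @param coupling_offset_s lag of a coupled spindle peak after the SO
#'   trough, in \[-1.25, 1.25\] s.
#' @param min_separation_s minimum separation between same-type injected
#'   events (default 2 s).
#' @param event_stages stages receiving injected events.
#' @param seed integer RNG seed; generation is bit-reproducible given the
#'   configuration.
#' @return a list of class `eeg_sim_config`.
#' @export
eeg_sim_config <- function(stage_sequence = default_stage_sequence(),
                           sampling_rate_hz = 256,
                           channels = c(F3 = "frontal", F4 = "frontal",
                                        C3 = "central", C4 = "central",
                                        A1 = "mastoid", A2 = "mastoid"),
                           noise_exponent = 1,
                           noise_rms_uv = 15,
                           spindle_density_per_min = 2,
                           spindle_freq_hz = 13,
                           spindle_amp_uv = 25,
                           spindle_dur_s = 1.0,
                           so_density_per_min = 3,
                           so_down_amp_uv = 100,
                           so_up_amp_uv = 50,
                           so_down_dur_s = 0.6,
                           coupled_fraction = 0.5,
                           coupling_offset_s = 0.4,
                           min_separation_s = 2,
                           event_stages = c("S2", "S3"),
                           seed = 1L) {
  stage_sequence <- as.data.frame(stage_sequence)
  stopifnot(all(c("stage", "minutes") %in% names(stage_sequence)))
  duration_s <- sum(stage_sequence$minutes) * 60
  if (duration_s <= 0) {
    stop("invalid config: total duration must be positive", call. = FALSE)
  }
  if (spindle_density_per_min < 0 || so_density_per_min < 0) {
    stop("invalid config: densities must be >= 0", call. = FALSE)
  }
  if (coupled_fraction < 0 || coupled_fraction > 1) {
    stop("invalid config: coupled_fraction must be in [0, 1]", call. = FALSE)
  }
  if (spindle_freq_hz < 9 || spindle_freq_hz > 15) {
    stop("invalid config: spindle_freq_hz must lie in [9, 15]", call. = FALSE)
  }
  if (abs(coupling_offset_s) > 1.25) {
    stop("invalid config: coupling_offset_s must lie in [-1.25, 1.25]",
         call. = FALSE)
  }
  structure(
    list(stage_sequence = stage_sequence,
         duration_s = duration_s,
         sampling_rate_hz = sampling_rate_hz,
         channels = channels,
         noise_exponent = noise_exponent,
         noise_rms_uv = noise_rms_uv,
         spindle_density_per_min = spindle_density_per_min,
         spindle_freq_hz = spindle_freq_hz,
         spindle_amp_uv = spindle_amp_uv,
         spindle_dur_s = spindle_dur_s,
         so_density_per_min = so_density_per_min,
         so_down_amp_uv = so_down_amp_uv,
         so_up_amp_uv = so_up_amp_uv,
         so_down_dur_s = so_down_dur_s,
         coupled_fraction = coupled_fraction,
         coupling_offset_s = coupling_offset_s,
         min_separation_s = min_separation_s,
         event_stages = event_stages,
         seed = as.integer(seed)),
    class = "eeg_sim_config"
  )
}

#' @rdname eeg_sim_config
#' @export
default_stage_sequence <- function() {
  data.frame(stage = c("Wake", "S1", "S2", "S3", "REM"),
             minutes = c(2, 3, 12, 8, 5))
}

#' Configuration for the synthetic recognition-memory generator
#'
#' Emulates a two-condition, two-test, two-valence within-subject
#' recognition cohort under the equal-variance Gaussian signal-detection
#' model.  Each cell (condition x test x valence) has a true d-prime; old
#' items draw latent familiarity from N(d', 1), novel items from N(0, 1),
#' and the 1-6 confidence rating is read off five fixed criteria placed
#' symmetrically around the decision criterion, so collapsing at the 3/4
#' boundary reproduces the present / not-present decision exactly.
#'
#' The default true d-prime table mirrors recognition performance typical
#' of emotional-picture studies (d' between roughly 1.8 and 2.4, with
#' sleep-dependent retention differing by drug condition and valence).
#'
#' @param n_subjects number of subjects.
#' @param true_dprime data.frame with columns `condition`, `test`,
#'   `valence`, `dprime` covering the 8 cells.
#' @param criterion latent decision criterion (items above it are called
#'   "present"); default 1.0, which yields realistic hit (~0.84 at d' = 2)
#'   and false-alarm (~0.16) rates.
#' @param n_old_per_valence,n_new_per_valence targets and foils per valence
#'   per test (defaults 10 and 10).
#' @param confidence_noise spacing scale of the confidence criteria.
#' @param weight_mean_kg,weight_sd_kg body-weight covariate distribution.
#' @param seed integer RNG seed.
#' @return a list of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(n_subjects = 28,
                                true_dprime = default_true_dprime(),
                                criterion = 1.0,
                                n_old_per_valence = 10,
                                n_new_per_valence = 10,
                                confidence_noise = 0.5,
                                weight_mean_kg = 72,
                                weight_sd_kg = 12,
                                seed = 1L) {
  true_dprime <- as.data.frame(true_dprime)
  need <- c("condition", "test", "valence", "dprime")
  stopifnot(all(need %in% names(true_dprime)))
  if (n_old_per_valence < 1 || n_new_per_valence < 1) {
    stop("invalid config: trial counts must be >= 1", call. = FALSE)
  }
  if (n_subjects < 1) {
    stop("invalid config: n_subjects must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(true_dprime$dprime))) {
    stop("invalid config: all true d-prime values must be finite",
         call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         true_dprime = true_dprime,
         criterion = criterion,
         n_old_per_valence = as.integer(n_old_per_valence),
         n_new_per_valence = as.integer(n_new_per_valence),
         confidence_noise = confidence_noise,
         weight_mean_kg = weight_mean_kg,
         weight_sd_kg = weight_sd_kg,
         seed = as.integer(seed)),
    class = "behavior_sim_config"
  )
}

#' @rdname behavior_sim_config
#' @export
default_true_dprime <- function() {
  expand.grid(condition = c("placebo", "zolpidem"),
              test = c(1L, 2L),
              valence = c("negative", "neutral"),
              stringsAsFactors = FALSE) |>
    transform(dprime = c(2.43, 2.30,   # test 1 negative
                         1.84, 2.18,   # test 2 negative
                         2.07, 2.36,   # test 1 neutral
                         2.30, 1.98))  # test 2 neutral
}

#' Detector configuration
#'
#' Houses every numeric criterion of the spindle, slow-oscillation and
#' coupling detectors.
#'
#' Spindles: a complex Morlet wavelet at `wavelet_f0_hz` with time spread
#' `wavelet_sigma_t_s` (the defaults give a half-power passband of about
#' 9-15 Hz) yields an amplitude trace; the detection statistic is its
#' square (`threshold_stat = "power"`) smoothed with a `ma_window_s` moving
#' average and compared against `threshold_factor` times the statistic's
#' mean over artifact-free NREM samples of the same channel.
#'
#' Slow oscillations: the signal is band-passed `so_filter_low_hz` to
#' `so_filter_high_hz` (zero phase) and consecutive down / up / down
#' zero-crossing triples are kept when the down-state duration lies in
#' `[so_down_dur_min_s, so_down_dur_max_s]`, the whole event is shorter
#' than `so_max_len_s`, the trough reaches `-so_down_amp_min_uv` or below,
#' and the up-state peak stays below `so_up_amp_max_uv`.
#'
#' @param spindle_band_low_hz,spindle_band_high_hz nominal sigma band (Hz).
#' @param wavelet_f0_hz Morlet centre frequency.
#' @param wavelet_sigma_t_s Morlet Gaussian time spread (s).
#' @param ma_window_s moving-average window for the detection statistic.
#' @param threshold_factor multiple of the NREM mean defining the detection
#'   threshold.
#' @param threshold_stat `"power"` (squared wavelet magnitude; default) or
#'   `"amplitude"` (rectified magnitude).
#' @param spindle_min_dur_s,spindle_max_dur_s spindle duration bounds (s).
#' @param so_filter_low_hz,so_filter_high_hz slow-oscillation band (Hz).
#' @param so_filter_order Butterworth order of the SO band-pass.
#' @param so_down_dur_min_s,so_down_dur_max_s down-state duration bounds.
#' @param so_max_len_s maximum event length (s).
#' @param so_down_amp_min_uv minimum |trough| amplitude (microvolts).
#' @param so_up_amp_max_uv maximum up-state amplitude (microvolts).
#' @param coupling_window_s half-width of the coupling window around the SO
#'   trough (s).
#' @param stages sleep stages searched for events.
#' @param channel_role channels searched (by role; default central).
#' @return a list of class `detector_config`.
#' @export
detector_config <- function(spindle_band_low_hz = 9,
                            spindle_band_high_hz = 15,
                            wavelet_f0_hz = 12,
                            wavelet_sigma_t_s = 0.06,
                            ma_window_s = 0.100,
                            threshold_factor = 4.0,
                            threshold_stat = c("power", "amplitude"),
                            spindle_min_dur_s = 0.3,
                            spindle_max_dur_s = 3.0,
                            so_filter_low_hz = 0.1,
                            so_filter_high_hz = 4.0,
                            so_filter_order = 2L,
                            so_down_dur_min_s = 0.3,
                            so_down_dur_max_s = 1.0,
                            so_max_len_s = 10.0,
                            so_down_amp_min_uv = 80,
                            so_up_amp_max_uv = 140,
                            coupling_window_s = 1.25,
                            stages = c("S2", "S3"),
                            channel_role = "central") {
  threshold_stat <- match.arg(threshold_stat)
  stopifnot(threshold_factor > 0, coupling_window_s > 0,
            spindle_min_dur_s > 0, spindle_max_dur_s > spindle_min_dur_s,
            ma_window_s > 0,
            so_down_dur_min_s > 0, so_down_dur_max_s > so_down_dur_min_s,
            so_max_len_s > 0, so_down_amp_min_uv > 0,
            so_filter_low_hz > 0, so_filter_high_hz > so_filter_low_hz)
  structure(
    list(spindle_band_low_hz = spindle_band_low_hz,
         spindle_band_high_hz = spindle_band_high_hz,
         wavelet_f0_hz = wavelet_f0_hz,
         wavelet_sigma_t_s = wavelet_sigma_t_s,
         ma_window_s = ma_window_s,
         threshold_factor = threshold_factor,
         threshold_stat = threshold_stat,
         spindle_min_dur_s = spindle_min_dur_s,
         spindle_max_dur_s = spindle_max_dur_s,
         so_filter_low_hz = so_filter_low_hz,
         so_filter_high_hz = so_filter_high_hz,
         so_filter_order = as.integer(so_filter_order),
         so_down_dur_min_s = so_down_dur_min_s,
         so_down_dur_max_s = so_down_dur_max_s,
         so_max_len_s = so_max_len_s,
         so_down_amp_min_uv = so_down_amp_min_uv,
         so_up_amp_max_uv = so_up_amp_max_uv,
         coupling_window_s = coupling_window_s,
         stages = stages,
         channel_role = channel_role),
    class = "detector_config"
  )
}

#' Spectral band definitions
#'
#' The five analysis bands: slow-wave activity 0.3-1 Hz, delta 1-4 Hz,
#' theta 4-7 Hz, slow sigma 9-11 Hz and fast sigma 12-15 Hz.  The 7-9 and
#' 15-35 Hz gaps belong to the complement band that
#' [stage_band_power()] adds so the bands partition the full 0.3-35 Hz
#' analysis range.
#'
#' @return data.frame with columns `band`, `low_hz`, `high_hz`.
#' @export
band_definitions <- function() {
  data.frame(band = c("SWA", "delta", "theta", "slow_sigma", "fast_sigma"),
             low_hz = c(0.3, 1, 4, 9, 12),
             high_hz = c(1, 4, 7, 11, 15),
             stringsAsFactors = FALSE)
}
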
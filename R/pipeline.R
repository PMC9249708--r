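#' Pipeline configuration
#'
#' Bundles the simulation, detection, spectral and statistical settings of
#' a full run.  The same subjects carry both the simulated EEG nights and
#' the behavioral sessions, so the sleep-memory correlation screen can be
#' computed on matched ids; `n_eeg_subjects` caps how many of them get
#' simulated nights (EEG simulation dominates runtime).
#'
#' @param out_dir output directory for stage CSVs and the manifest.
#' @param eeg an [eeg_sim_config()] template (per-night seeds are derived
#'   from `seed`).
#' @param behavior a [behavior_sim_config()].
#' @param detector a [detector_config()].
#' @param bands band table as from [band_definitions()].
#' @param alpha_spectral,alpha_events Bonferroni-corrected alphas for the
#'   two correlation screens (defaults 0.0025 and 0.004).
#' @param n_eeg_subjects number of subjects receiving simulated nights.
#' @param seed master seed; every stage's randomness derives from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            eeg = eeg_sim_config(),
                            behavior = behavior_sim_config(),
                            detector = detector_config(),
                            bands = band_definitions(),
                            alpha_spectral = 0.0025,
                            alpha_events = 0.004,
                            n_eeg_subjects = 6L,
                            seed = 1L) {
  if (missing(out_dir) || is.null(out_dir) || !nzchar(out_dir)) {
    stop("configuration error: out_dir is required", call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, eeg = eeg, behavior = behavior,
         detector = detector, bands = bands,
         alpha_spectral = alpha_spectral, alpha_events = alpha_events,
         n_eeg_subjects = as.integer(n_eeg_subjects),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full simulate / preprocess / detect / spectra / score / stats
#' pipeline
#'
#' Simulates the cohort (EEG nights per subject and condition, behavioral
#' sessions), preprocesses each night (contralateral-mastoid
#' re-referencing, 0.3-35 Hz zero-phase band-pass, amplitude-threshold
#' artifact mask), computes sleep architecture, per-stage band power,
#' spindle / slow-oscillation / coupling events and densities, scores
#' memory, and runs the inferential layer (repeated-measures ANOVA with
#' the weight covariate, paired t-tests with Holm correction, and the two
#' Bonferroni-screened correlation screens).  All stage outputs are
#' written as CSVs plus a JSON manifest (seed, configuration echo, file
#' checksums); a rerun with the same configuration reproduces every CSV
#' byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly (list with `seed`, `files`, `md5`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    stop("configuration error: config must be a pipeline_config",
         call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  conds <- c("placebo", "zolpidem")
  set.seed(config$seed)
  night_seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                                   config$n_eeg_subjects * 2L),
                        nrow = config$n_eeg_subjects)
  behav_seed <- sample.int(.Machine$integer.max %/% 2, 1L)

  arch_rows <- list(); power_rows <- list(); event_rows <- list()
  density_rows <- list(); coupling_rows <- list()

  say("simulate + preprocess + detect (", config$n_eeg_subjects,
      " subjects x 2 nights)")
  for (s in seq_len(config$n_eeg_subjects)) {
    for (ci in seq_along(conds)) {
      cn <- conds[ci]
      ecfg <- config$eeg
      ecfg$seed <- night_seeds[s, ci]
      sim <- generate_eeg(ecfg)
      rec <- bandpass_filter(
        rereference_contralateral_mastoid(sim$recording))
      mask <- mark_artifact_epochs(rec, sim$hypnogram)

      arch <- sleep_architecture(sim$hypnogram)
      arch_rows[[length(arch_rows) + 1L]] <- data.frame(
        subject = s, condition = cn,
        TST_min = arch$TST_min, SL_min = arch$SL_min,
        WASO_min = arch$WASO_min, SE_pct = arch$SE_pct,
        t(arch$stage_minutes), stringsAsFactors = FALSE)

      bp <- stage_band_power(rec, sim$hypnogram, mask, config$bands)
      bp <- cbind(subject = s, condition = cn, bp)
      power_rows[[length(power_rows) + 1L]] <- bp

      sp <- detect_spindles(rec, sim$hypnogram, mask, config$detector)
      so <- detect_slow_oscillations(rec, sim$hypnogram, mask,
                                     config$detector)
      cp <- couple_so_spindles(so, sp, config$detector)
      if (nrow(sp)) {
        event_rows[[length(event_rows) + 1L]] <- data.frame(
          subject = s, condition = cn, type = "spindle",
          channel = sp$channel, start_s = sp$start_s, end_s = sp$end_s,
          anchor_s = sp$peak_s, amplitude = sp$peak_amplitude,
          stage = sp$stage, stringsAsFactors = FALSE)
      }
      if (nrow(so)) {
        event_rows[[length(event_rows) + 1L]] <- data.frame(
          subject = s, condition = cn, type = "slow_oscillation",
          channel = so$channel, start_s = so$zc_down1_s,
          end_s = so$zc_down2_s, anchor_s = so$trough_s,
          amplitude = so$trough_amp_uv, stage = so$stage,
          stringsAsFactors = FALSE)
      }
      if (nrow(cp)) {
        coupling_rows[[length(coupling_rows) + 1L]] <-
          cbind(subject = s, condition = cn, cp)
      }
      for (st in config$detector$stages) {
        for (ch in unique(c(sp$channel, so$channel, cp$channel))) {
          density_rows[[length(density_rows) + 1L]] <- data.frame(
            subject = s, condition = cn, stage = st, channel = ch,
            spindle_per_min = event_density(sp, sim$hypnogram, st, ch),
            so_per_min = event_density(so, sim$hypnogram, st, ch),
            coupled_per_min = event_density(cp, sim$hypnogram, st, ch),
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  say("score behavior")
  bcfg <- config$behavior
  bcfg$seed <- behav_seed
  beh <- generate_behavior(bcfg)
  scores <- score_sessions(beh$trials)
  diffs <- difference_scores(scores)
  summ <- memory_summary(scores)

  say("stats")
  scores_w <- merge(scores, beh$subjects, by = "subject")
  aov_tab <- rm_anova_2x2x2(scores_w, covariate = "weight_kg")

  arch_df <- do.call(rbind, arch_rows)
  tvars <- c("TST_min", "WASO_min", "SE_pct", "S1", "S2", "S3", "REM")
  ttests <- do.call(rbind, lapply(tvars, function(v) {
    a <- arch_df[arch_df$condition == "placebo", ]
    b <- arch_df[arch_df$condition == "zolpidem", ]
    a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
    cbind(variable = v, paired_t(a[[v]], b[[v]]))
  }))
  hb <- holm_bonferroni(ifelse(is.na(ttests$p), 1, ttests$p))
  ttests$p_holm <- hb$p_adjusted
  ttests$reject_holm <- hb$reject

  power_df <- do.call(rbind, power_rows)
  dens_df <- if (length(density_rows)) do.call(rbind, density_rows) else
    data.frame(subject = integer(), condition = character(),
               stage = character(), channel = character(),
               spindle_per_min = numeric(), so_per_min = numeric(),
               coupled_per_min = numeric())

  # correlation screens on the EEG-simulated subjects
  feat_spec <- power_df[power_df$channel %in% c("F", "C") &
                          power_df$band != "total" &
                          power_df$band != "complement", ]
  feat_spec <- data.frame(subject = feat_spec$subject,
                          condition = feat_spec$condition,
                          feature = paste(feat_spec$channel, feat_spec$stage,
                                          feat_spec$band, sep = "_"),
                          value = feat_spec$rel_pct)
  mem_long <- data.frame(subject = scores$subject,
                         condition = scores$condition,
                         variable = paste0("dprime_t", scores$test, "_",
                                           scores$valence),
                         value = scores$dprime)
  screen_spec <- sleep_memory_screen(feat_spec, mem_long,
                                     config$alpha_spectral)
  feat_ev <- NULL
  if (nrow(dens_df)) {
    feat_ev <- rbind(
      data.frame(subject = dens_df$subject, condition = dens_df$condition,
                 feature = paste("spindle", dens_df$stage, dens_df$channel,
                                 sep = "_"),
                 value = dens_df$spindle_per_min),
      data.frame(subject = dens_df$subject, condition = dens_df$condition,
                 feature = paste("coupled", dens_df$stage, dens_df$channel,
                                 sep = "_"),
                 value = dens_df$coupled_per_min))
    screen_ev <- sleep_memory_screen(feat_ev, mem_long,
                                     config$alpha_events)
  } else {
    screen_ev <- sleep_memory_screen(
      data.frame(subject = integer(), condition = character(),
                 feature = character(), value = numeric()),
      mem_long, config$alpha_events)
  }

  say("write outputs")
  files <- c(architecture = "architecture.csv",
             band_power = "band_power.csv",
             events = "events.csv",
             densities = "densities.csv",
             coupling = "coupling.csv",
             scores = "memory_scores.csv",
             difference_scores = "difference_scores.csv",
             memory_summary = "memory_summary.csv",
             anova = "anova_dprime.csv",
             paired_tests = "architecture_ttests.csv",
             screen_spectral = "screen_spectral.csv",
             screen_events = "screen_events.csv")
  wr <- function(df, f) {
    utils::write.csv(df, file.path(config$out_dir, f), row.names = FALSE)
  }
  wr(arch_df, files["architecture"])
  wr(power_df, files["band_power"])
  wr(if (length(event_rows)) do.call(rbind, event_rows) else
    data.frame(), files["events"])
  wr(dens_df, files["densities"])
  wr(if (length(coupling_rows)) do.call(rbind, coupling_rows) else
    data.frame(), files["coupling"])
  wr(scores, files["scores"])
  wr(diffs, files["difference_scores"])
  wr(summ, files["memory_summary"])
  wr(aov_tab, files["anova"])
  wr(ttests, files["paired_tests"])
  wr(screen_spec, files["screen_spectral"])
  wr(screen_ev, files["screen_events"])

  paths <- file.path(config$out_dir, files)
  manifest <- list(
    package = "sleepmem",
    version = as.character(utils::packageVersion("sleepmem")),
    seed = config$seed,
    n_eeg_subjects = config$n_eeg_subjects,
    n_behavior_subjects = config$behavior$n_subjects,
    files = as.list(stats::setNames(files, names(files))),
    md5 = as.list(stats::setNames(unname(tools::md5sum(paths)), files))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
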
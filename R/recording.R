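#' EEG recording container
#'
#' A minimal multi-channel EEG container: a channels-by-samples matrix in
#' microvolts plus sampling rate and per-channel roles.  Roles drive
#' downstream behaviour (which channels are re-referenced, which enter
#' artifact detection and spectral analysis, which are treated as mastoid
#' references).
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param srate sampling rate in Hz (> 0).
#' @param labels character vector of channel labels (defaults to the
#'   rownames of `signal`).
#' @param roles named character vector mapping each label to one of
#'   `"frontal"`, `"central"`, `"parietal"`, `"occipital"`, `"mastoid"`,
#'   `"EOG"`, `"EMG"`, `"ECG"`, `"other"`.  Missing roles are inferred from
#'   the label (`infer_channel_roles()`).
#' @param start_time optional POSIXct recording start.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, srate, labels = rownames(signal),
                          roles = NULL, start_time = NULL) {
  signal <- as.matrix(signal)
  if (is.null(labels)) stop("channel labels are required", call. = FALSE)
  if (length(labels) != nrow(signal)) {
    stop("one label per signal row is required", call. = FALSE)
  }
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0) {
    stop("srate must be a single positive number", call. = FALSE)
  }
  rownames(signal) <- labels
  if (is.null(roles)) {
    roles <- infer_channel_roles(labels)
  } else {
    missing <- setdiff(labels, names(roles))
    if (length(missing)) {
      roles <- c(roles, infer_channel_roles(missing))
    }
    roles <- roles[labels]
  }
  structure(
    list(signal = signal, srate = srate, labels = labels,
         roles = roles, start_time = start_time),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f min)\n",
              nrow(x$signal), ncol(x$signal), x$srate,
              ncol(x$signal) / x$srate / 60))
  cat("  channels:", paste(sprintf("%s[%s]", x$labels, x$roles),
                           collapse = " "), "\n")
  invisible(x)
}

#' Infer channel roles from 10-20 labels
#'
#' Mastoids (`A1`/`A2`/`M1`/`M2`), EOG/EMG/ECG by prefix, otherwise the
#' leading letter of the 10-20 label (F frontal, C central, P parietal,
#' O occipital); anything else is `"other"`.
#'
#' @param labels character vector of channel labels.
#' @return named character vector of roles.
#' @export
infer_channel_roles <- function(labels) {
  role_of <- function(lab) {
    u <- toupper(lab)
    if (u %in% c("A1", "A2", "M1", "M2")) return("mastoid")
    if (startsWith(u, "EOG") || u %in% c("LOC", "ROC")) return("EOG")
    if (startsWith(u, "EMG") || startsWith(u, "CHIN")) return("EMG")
    if (startsWith(u, "ECG") || startsWith(u, "EKG")) return("ECG")
    switch(substr(u, 1L, 1L),
           "F" = "frontal", "C" = "central",
           "P" = "parietal", "O" = "occipital", "other")
  }
  stats::setNames(vapply(labels, role_of, character(1L)), labels)
}

# Channels that carry scalp EEG (enter filtering, artifact detection and
# spectral analysis).
scalp_channels <- function(rec) {
  rec$labels[rec$roles %in% c("frontal", "central", "parietal", "occipital")]
}

#' Hypnogram container
#'
#' Per-epoch sleep-stage labels aligned to a recording, with the lights-out
#' and lights-on epoch indices that delimit time in bed.  Epochs are 0-based
#' and half-open: epoch `i` covers `[i * epoch_len_s, (i + 1) * epoch_len_s)`
#' seconds.
#'
#' @param stages character vector of per-epoch stages, each one of
#'   `"Wake"`, `"S1"`, `"S2"`, `"S3"`, `"REM"`, `"Unscored"`.
#' @param epoch_len_s epoch length in seconds (default 30).
#' @param lights_out_epoch,lights_on_epoch 0-based epoch indices delimiting
#'   time in bed; defaults to the full hypnogram.
#' @return an object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_len_s = 30,
                      lights_out_epoch = 0L,
                      lights_on_epoch = length(stages)) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), sleep_stage_levels())
  if (length(bad)) {
    stop("unknown stage code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (lights_out_epoch > lights_on_epoch) {
    stop("lights_out_epoch must not exceed lights_on_epoch", call. = FALSE)
  }
  structure(
    list(stages = stages, epoch_len_s = epoch_len_s,
         lights_out_epoch = as.integer(lights_out_epoch),
         lights_on_epoch = as.integer(lights_on_epoch)),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  tb <- table(factor(x$stages, levels = sleep_stage_levels()))
  cat(sprintf("<hypnogram> %d x %g-s epochs (%.1f min in bed)\n",
              length(x$stages), x$epoch_len_s,
              (x$lights_on_epoch - x$lights_out_epoch) * x$epoch_len_s / 60))
  print(tb[tb > 0])
  invisible(x)
}

#' Sleep stage codes used throughout the package
#' @return character vector of valid stage labels.
#' @export
sleep_stage_levels <- function() {
  c("Wake", "S1", "S2", "S3", "REM", "Unscored")
}

# Stage of the epoch containing time t (seconds); "Unscored" past the end.
stage_at_time <- function(hyp, t) {
  idx <- floor(t / hyp$epoch_len_s) + 1L
  out <- rep("Unscored", length(t))
  ok <- idx >= 1L & idx <= length(hyp$stages)
  out[ok] <- hyp$stages[idx[ok]]
  out
}

# 0-based epoch index containing time t.
epoch_at_time <- function(hyp, t) {
  as.integer(floor(t / hyp$epoch_len_s))
}

#' Read / write a hypnogram CSV
#'
#' The on-disk format has columns `epoch_index` (0-based) and `stage` with
#' AASM-style codes `W`, `N1`, `N2`, `N3`, `R` (plus `U` for unscored),
#' mapped to the package's internal `Wake`/`S1`/`S2`/`S3`/`REM` labels.
#'
#' @param path file path.
#' @param hyp a [hypnogram()].
#' @return `read_hypnogram_csv` returns a [hypnogram()];
#'   `write_hypnogram_csv` returns `path` invisibly.
#' @export
read_hypnogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df))) {
    stop("hypnogram CSV needs columns epoch_index and stage", call. = FALSE)
  }
  df <- df[order(df$epoch_index), ]
  map <- c(W = "Wake", N1 = "S1", N2 = "S2", N3 = "S3", R = "REM",
           U = "Unscored")
  stages <- map[df$stage]
  if (anyNA(stages)) {
    stop("unknown stage code(s) in ", path, call. = FALSE)
  }
  lo <- if ("lights_out" %in% names(df)) which(df$lights_out == 1)[1] - 1L else 0L
  hypnogram(unname(stages),
            lights_out_epoch = if (is.na(lo)) 0L else lo)
}

#' @rdname read_hypnogram_csv
#' @export
write_hypnogram_csv <- function(hyp, path) {
  map <- c(Wake = "W", S1 = "N1", S2 = "N2", S3 = "N3", REM = "R",
           Unscored = "U")
  utils::write.csv(
    data.frame(epoch_index = seq_along(hyp$stages) - 1L,
               stage = unname(map[hyp$stages])),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
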
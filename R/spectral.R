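#' Welch power spectral density of one epoch
#'
#' Averaged modified periodogram with Hann-windowed segments (default 4 s
#' at 50% overlap, i.e. 14 segments per 30-s epoch).  The one-sided PSD is
#' scaled as a density in microvolts squared per Hz, so integrating over
#' frequency recovers signal variance: a pure tone of amplitude A carries
#' total power A^2 / 2 and white noise of variance s^2 integrates to s^2.
#'
#' @param x numeric vector, one epoch of signal in microvolts.
#' @param srate sampling rate in Hz.
#' @param window_s segment length in seconds (default 4).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz, 0 to Nyquist) and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, srate, window_s = 4, overlap = 0.5) {
  nw <- round(window_s * srate)
  if (length(x) < nw) {
    stop("parameter error: epoch shorter than one Welch segment",
         call. = FALSE)
  }
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1L)) / (nw - 1L))  # Hann
  norm <- srate * sum(w^2)
  nf <- nw %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)] * w
    p <- Mod(stats::fft(seg)[seq_len(nf)])^2 / norm
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]   # one-sided
    acc <- acc + p
  }
  list(freq = (0:(nf - 1L)) * srate / nw, psd = acc / length(starts))
}

#' Per-stage band power table
#'
#' For each requested sleep stage, Welch PSDs of the artifact-free epochs
#' of that stage are averaged per channel and then integrated over the
#' analysis bands (trapezoidal rule on the linearly interpolated PSD, so
#' band powers are exactly additive).  Relative power is each band as a
#' percentage of the total power over `total_range` (default 0.3-35 Hz);
#' a `complement` row collects the 7-9 and 15-35 Hz remainder so the rows
#' of one channel/stage partition the analysis range and their relative
#' powers sum to 100.
#'
#' Channel-average rows are emitted for homologous pairs: `"F"` for the
#' frontal pair and `"C"` for the central pair (arithmetic mean of the two
#' channels' PSDs).
#'
#' @param rec an [eeg_recording()].
#' @param hyp the aligned [hypnogram()].
#' @param mask logical artifact-free mask from [mark_artifact_epochs()].
#' @param bands band table as from [band_definitions()].
#' @param stages stages to summarise (default S2 and S3).
#' @param total_range numeric length-2, the analysis range in Hz.
#' @param window_s,overlap Welch parameters, see [welch_psd()].
#' @return data.frame with columns `stage`, `channel`, `band`, `abs_uv2`,
#'   `rel_pct`, `n_epochs`.  Stages with no artifact-free epochs yield
#'   rows with `NA` power and `n_epochs = 0`.
#' @export
stage_band_power <- function(rec, hyp, mask, bands = band_definitions(),
                             stages = c("S2", "S3"),
                             total_range = c(0.3, 35),
                             window_s = 4, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(hyp, "hypnogram"))
  if (length(mask) != length(hyp$stages)) {
    stop("mask length must equal the number of hypnogram epochs",
         call. = FALSE)
  }
  spe <- round(hyp$epoch_len_s * rec$srate)
  chans <- scalp_channels(rec)

  band_rows <- function(freq, psd) {
    abs_p <- vapply(seq_len(nrow(bands)), function(b) {
      trapz_band(freq, psd, bands$low_hz[b], bands$high_hz[b])
    }, numeric(1L))
    total <- trapz_band(freq, psd, total_range[1L], total_range[2L])
    comp <- total - sum(abs_p)
    data.frame(band = c(bands$band, "complement", "total"),
               abs_uv2 = c(abs_p, comp, total),
               rel_pct = 100 * c(abs_p, comp, total) / total,
               stringsAsFactors = FALSE)
  }

  out <- list()
  for (st in stages) {
    eps <- which(hyp$stages == st & mask)
    eps <- eps[eps * spe <= ncol(rec$signal)]
    psds <- NULL
    if (length(eps)) {
      psds <- lapply(chans, function(ch) {
        acc <- NULL
        for (e in eps) {
          seg <- rec$signal[ch, ((e - 1L) * spe + 1L):(e * spe)]
          ps <- welch_psd(seg, rec$srate, window_s, overlap)
          acc <- if (is.null(acc)) ps$psd else acc + ps$psd
        }
        list(freq = ps$freq, psd = acc / length(eps))
      })
      names(psds) <- chans
    }
    emit <- function(channel, freq, psd) {
      if (is.null(psd)) {
        df <- data.frame(band = c(bands$band, "complement", "total"),
                         abs_uv2 = NA_real_, rel_pct = NA_real_,
                         stringsAsFactors = FALSE)
      } else {
        df <- band_rows(freq, psd)
      }
      df$stage <- st
      df$channel <- channel
      df$n_epochs <- length(eps)
      df
    }
    for (ch in chans) {
      out[[length(out) + 1L]] <-
        emit(ch, psds[[ch]]$freq, psds[[ch]]$psd)
    }
    # homologous-pair averages
    for (pair in list(c(role = "frontal", name = "F"),
                      c(role = "central", name = "C"))) {
      members <- chans[rec$roles[chans] == pair[["role"]]]
      if (length(members) == 2L) {
        if (is.null(psds)) {
          out[[length(out) + 1L]] <- emit(pair[["name"]], NULL, NULL)
        } else {
          avg <- (psds[[members[1L]]]$psd + psds[[members[2L]]]$psd) / 2
          out[[length(out) + 1L]] <-
            emit(pair[["name"]], psds[[members[1L]]]$freq, avg)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("stage", "channel", "band", "abs_uv2", "rel_pct", "n_epochs")]
}
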
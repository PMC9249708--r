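#' Collapse a 1-6 confidence rating to a present / not-present decision
#'
#' Ratings 1-3 ("very confident present" through "not sure, but think
#' present") collapse to `"present"`; 4-6 collapse to `"not_present"`.
#'
#' @param confidence integer vector with values in 1..6.
#' @return character vector of `"present"` / `"not_present"`.
#' @export
collapse_confidence <- function(confidence) {
  if (any(!confidence %in% 1:6)) {
    stop("validation error: confidence ratings must lie in 1..6",
         call. = FALSE)
  }
  ifelse(confidence <= 3, "present", "not_present")
}

#' Signal-detection discriminability d-prime
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with the standard 1/(2N)
#' correction for extreme rates: a rate of 0 becomes `1 / (2N)` and a rate
#' of 1 becomes `1 - 1 / (2N)` (N = number of targets or foils) before the
#' inverse-normal transform, so the estimate is always finite.
#'
#' @param hit_rate,fa_rate rates in \[0, 1\] (vectorised).
#' @param n_targets,n_foils trial counts behind the two rates.
#' @param correction `"2N"` (default) or `"none"` (may return +/-Inf).
#' @return numeric d-prime.
#' @export
dprime <- function(hit_rate, fa_rate, n_targets, n_foils,
                   correction = c("2N", "none")) {
  correction <- match.arg(correction)
  stopifnot(all(hit_rate >= 0 & hit_rate <= 1),
            all(fa_rate >= 0 & fa_rate <= 1),
            all(n_targets >= 1), all(n_foils >= 1))
  if (correction == "2N") {
    hit_rate <- pmin(pmax(hit_rate, 1 / (2 * n_targets)),
                     1 - 1 / (2 * n_targets))
    fa_rate <- pmin(pmax(fa_rate, 1 / (2 * n_foils)),
                    1 - 1 / (2 * n_foils))
  }
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

#' Score recognition-memory sessions
#'
#' Collapses confidence ratings, excludes buffer trials, and computes per
#' subject x condition x test x valence cell: hit rate (P(present | old)),
#' false-alarm rate (P(present | new)), accuracy (percent of old + new
#' trials answered correctly) and d-prime (via [dprime()], 1/(2N)
#' corrected).  Cells lacking old or new trials are flagged via `NA`
#' scores.
#'
#' @param trials data.frame with columns `subject`, `condition`, `test`,
#'   `valence`, `status` (`old` / `new` / `buffer`), `confidence` (1-6).
#' @param correction extreme-rate correction passed to [dprime()].
#' @return data.frame with one row per cell: `subject`, `condition`,
#'   `test`, `valence`, `n_targets`, `n_foils`, `hit_rate`, `fa_rate`,
#'   `accuracy_pct`, `dprime`.
#' @export
score_sessions <- function(trials, correction = "2N") {
  need <- c("subject", "condition", "test", "valence", "status",
            "confidence")
  if (!all(need %in% names(trials))) {
    stop("trials must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tr <- trials[trials$status %in% c("old", "new"), , drop = FALSE]
  present <- collapse_confidence(tr$confidence) == "present"
  old <- tr$status == "old"

  key <- interaction(tr$subject, tr$condition, tr$test, tr$valence,
                     drop = TRUE, lex.order = TRUE)
  counts <- rowsum(cbind(n_targets = as.numeric(old),
                         n_hits = as.numeric(old & present),
                         n_foils = as.numeric(!old),
                         n_fas = as.numeric(!old & present)),
                   key)
  ids <- do.call(rbind, strsplit(rownames(counts), ".", fixed = TRUE))
  out <- data.frame(subject = utils::type.convert(ids[, 1L], as.is = TRUE),
                    condition = ids[, 2L],
                    test = utils::type.convert(ids[, 3L], as.is = TRUE),
                    valence = ids[, 4L],
                    n_targets = counts[, "n_targets"],
                    n_foils = counts[, "n_foils"],
                    stringsAsFactors = FALSE)
  out$hit_rate <- ifelse(out$n_targets > 0,
                         counts[, "n_hits"] / out$n_targets, NA_real_)
  out$fa_rate <- ifelse(out$n_foils > 0,
                        counts[, "n_fas"] / out$n_foils, NA_real_)
  n_all <- out$n_targets + out$n_foils
  n_correct <- counts[, "n_hits"] + (out$n_foils - counts[, "n_fas"])
  out$accuracy_pct <- ifelse(n_all > 0, 100 * n_correct / n_all, NA_real_)
  ok <- out$n_targets > 0 & out$n_foils > 0
  out$dprime <- NA_real_
  out$dprime[ok] <- dprime(out$hit_rate[ok], out$fa_rate[ok],
                           out$n_targets[ok], out$n_foils[ok],
                           correction = correction)
  if (!all(ok)) {
    warning(sum(!ok), " cell(s) lack old or new trials; scores set to NA",
            call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Test 2 minus test 1 difference scores
#'
#' Retention change across the consolidation interval: `d'(test 2) -
#' d'(test 1)` per subject, condition and valence (and the analogous
#' differences for accuracy and false alarms).  Negative values mean
#' forgetting from test 1 to test 2.
#'
#' @param scores data.frame from [score_sessions()].
#' @return data.frame with `subject`, `condition`, `valence`, `ddprime`,
#'   `daccuracy_pct`, `dfa_rate`.  Cells missing either test are dropped
#'   with a warning.
#' @export
difference_scores <- function(scores) {
  t1 <- scores[scores$test == 1, ]
  t2 <- scores[scores$test == 2, ]
  m <- merge(t1, t2, by = c("subject", "condition", "valence"),
             suffixes = c("_t1", "_t2"))
  n_cells <- nrow(unique(scores[, c("subject", "condition", "valence")]))
  if (nrow(m) < n_cells) {
    warning(n_cells - nrow(m), " cell(s) missing one of the two tests",
            call. = FALSE)
  }
  data.frame(subject = m$subject, condition = m$condition,
             valence = m$valence,
             ddprime = m$dprime_t2 - m$dprime_t1,
             daccuracy_pct = m$accuracy_pct_t2 - m$accuracy_pct_t1,
             dfa_rate = m$fa_rate_t2 - m$fa_rate_t1,
             stringsAsFactors = FALSE)
}

#' Outlier mask at +/- k standard deviations
#'
#' Flags values farther than `n_sd` standard deviations from the mean of
#' the supplied vector; used to exclude extreme scores per dependent
#' variable before group statistics.  When every value lies within the
#' bounds the mask is all-`TRUE` (a no-op).
#'
#' @param x numeric vector.
#' @param n_sd cutoff in standard deviations (default 2.5).
#' @return logical vector, `TRUE` = keep.
#' @export
outlier_mask <- function(x, n_sd = 2.5) {
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(x)))
  abs(x - m) <= n_sd * s | is.na(x)
}

#' Group summary of memory performance
#'
#' Mean and standard deviation of hit rate, false-alarm rate and d-prime
#' per condition x test x valence cell, in the layout of a performance
#' summary table.
#'
#' @param scores data.frame from [score_sessions()].
#' @return data.frame with one row per cell and columns `condition`,
#'   `test`, `valence`, `n`, `hit_mean`, `hit_sd`, `fa_mean`, `fa_sd`,
#'   `dprime_mean`, `dprime_sd`.
#' @export
memory_summary <- function(scores) {
  agg <- function(v) {
    cbind(
      stats::aggregate(scores[[v]],
                       by = scores[c("condition", "test", "valence")],
                       FUN = mean, na.rm = TRUE)["x"],
      stats::aggregate(scores[[v]],
                       by = scores[c("condition", "test", "valence")],
                       FUN = stats::sd, na.rm = TRUE)["x"]
    )
  }
  base <- stats::aggregate(scores$dprime,
                           by = scores[c("condition", "test", "valence")],
                           FUN = length)
  names(base)[4L] <- "n"
  h <- agg("hit_rate"); f <- agg("fa_rate"); d <- agg("dprime")
  out <- cbind(base, h, f, d)
  names(out)[5:10] <- c("hit_mean", "hit_sd", "fa_mean", "fa_sd",
                        "dprime_mean", "dprime_sd")
  out
}
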
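#' 2 x 2 x 2 repeated-measures ANOVA with an optional subject covariate
#'
#' Univariate repeated-measures analysis of the fully crossed
#' drug x test x emotion within-subject design.  Because every factor has
#' two levels, each within-subject effect has one numerator degree of
#' freedom and its F-test is exactly the squared one-sample t-test of the
#' corresponding per-subject contrast score; with a (mean-centred)
#' between-subject covariate the contrast scores are regressed on the
#' covariate, which reproduces the classical RM-ANCOVA partition: the
#' effect's F is the intercept test and the covariate x effect interaction
#' is the slope test, each on (1, n - 2) degrees of freedom.  The
#' covariate's between-subject main effect is the regression of subject
#' means on the covariate.
#'
#' Subjects with incomplete cells are dropped listwise (count reported via
#' the `n` column).  A covariate with zero variance is ignored, which
#' makes the analysis identical to the covariate-free one.
#'
#' @param data long data.frame with one row per subject x cell.
#' @param dv name of the dependent-variable column (default `"dprime"`).
#' @param subject,drug,test,emotion names of the id and factor columns
#'   (defaults `subject`, `condition`, `test`, `valence`).
#' @param covariate optional: name of a per-subject numeric column (e.g.
#'   body weight), mean-centred internally.
#' @return data.frame with columns `effect`, `F`, `df_num`, `df_den`,
#'   `p`, `n`.
#' @export
rm_anova_2x2x2 <- function(data, dv = "dprime", subject = "subject",
                           drug = "condition", test = "test",
                           emotion = "valence", covariate = NULL) {
  cols <- c(subject, drug, test, emotion, dv)
  if (!all(cols %in% names(data))) {
    stop("missing column(s): ",
         paste(setdiff(cols, names(data)), collapse = ", "), call. = FALSE)
  }
  d <- data[stats::complete.cases(data[cols]), cols]
  names(d) <- c("subject", "drug", "test", "emotion", "y")
  fd <- sort(unique(as.character(d$drug)))
  ft <- sort(unique(as.character(d$test)))
  fe <- sort(unique(as.character(d$emotion)))
  if (length(fd) != 2L || length(ft) != 2L || length(fe) != 2L) {
    stop("each within-subject factor must have exactly two levels",
         call. = FALSE)
  }
  # wide matrix: one row per subject, 8 cells in fixed order
  cell <- paste(d$drug, d$test, d$emotion, sep = "\r")
  g <- expand.grid(drug = fd, test = ft, emotion = fe,
                   stringsAsFactors = FALSE)
  cells <- paste(g$drug, g$test, g$emotion, sep = "\r")
  subj <- sort(unique(d$subject))
  Y <- matrix(NA_real_, length(subj), 8L,
              dimnames = list(subj, cells))
  Y[cbind(match(d$subject, subj), match(cell, cells))] <- d$y
  complete <- stats::complete.cases(Y)
  if (sum(!complete)) {
    message(sum(!complete), " subject(s) dropped (incomplete cells)")
  }
  Y <- Y[complete, , drop = FALSE]
  subj <- subj[complete]
  n <- nrow(Y)
  if (n < 3L) stop("need at least 3 complete subjects", call. = FALSE)

  cd <- ifelse(g$drug == fd[1L], -1, 1)
  ct <- ifelse(g$test == ft[1L], -1, 1)
  ce <- ifelse(g$emotion == fe[1L], -1, 1)
  contrasts <- list(drug = cd, test = ct, emotion = ce,
                    `drug:test` = cd * ct, `drug:emotion` = cd * ce,
                    `test:emotion` = ct * ce,
                    `drug:test:emotion` = cd * ct * ce)

  wc <- NULL
  if (!is.null(covariate)) {
    if (!covariate %in% names(data)) {
      stop("covariate column not found: ", covariate, call. = FALSE)
    }
    w <- stats::aggregate(data[[covariate]],
                          by = list(subject = data[[subject]]),
                          FUN = function(v) v[1L])
    wc <- w$x[match(subj, w$subject)]
    if (anyNA(wc)) stop("covariate missing for some subjects", call. = FALSE)
    if (stats::sd(wc) == 0) {
      wc <- NULL   # constant covariate: identical to no covariate
    } else {
      wc <- wc - mean(wc)
    }
  }

  res <- list()
  push <- function(effect, Fv, df1, df2, p) {
    res[[length(res) + 1L]] <<- data.frame(
      effect = effect, F = Fv, df_num = df1, df_den = df2, p = p, n = n,
      stringsAsFactors = FALSE)
  }
  if (!is.null(wc)) {
    cf <- summary(stats::lm(rowMeans(Y) ~ wc))$coefficients
    push(if (is.null(covariate)) "covariate" else covariate,
         cf[2L, 3L]^2, 1L, n - 2L, cf[2L, 4L])
  }
  for (nm in names(contrasts)) {
    s <- as.vector(Y %*% contrasts[[nm]]) / 8
    if (stats::sd(s) == 0) {
      # degenerate contrast: no within-subject variability left
      if (mean(s) == 0) push(nm, 0, 1L, n - 1L, 1) else
        push(nm, Inf, 1L, n - 1L, 0)
      if (!is.null(wc)) push(paste0(nm, ":", covariate), 0, 1L, n - 2L, 1)
      next
    }
    if (is.null(wc)) {
      tt <- stats::t.test(s)
      push(nm, unname(tt$statistic)^2, 1L, n - 1L, tt$p.value)
    } else {
      cf <- summary(stats::lm(s ~ wc))$coefficients
      push(nm, cf[1L, 3L]^2, 1L, n - 2L, cf[1L, 4L])
      push(paste0(nm, ":", covariate), cf[2L, 3L]^2, 1L, n - 2L,
           cf[2L, 4L])
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Paired t-test
#'
#' Two-sided paired t-test with `df = n - 1`.  A zero-variance difference
#' vector cannot be tested and is returned flagged as degenerate.
#'
#' @param x,y paired numeric vectors of equal length (>= 2).
#' @return data.frame with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  diffs <- x - y
  if (stats::sd(diffs) == 0) {
    return(data.frame(t = NA_real_, df = length(x) - 1L, p = NA_real_,
                      mean_diff = mean(diffs), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, mean_diff = unname(tt$estimate),
             degenerate = FALSE)
}

#' Holm-Bonferroni step-down correction
#'
#' Family-wise error control by the step-down schedule: the smallest
#' p-value is compared against `alpha / m`, the next against
#' `alpha / (m - 1)`, and so on, stopping at the first failure.
#' Implemented through `stats::p.adjust(method = "holm")`; decisions are
#' returned in the input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame with `p`, `p_adjusted`, `reject`.
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) {
    return(data.frame(p = numeric(), p_adjusted = numeric(),
                      reject = logical()))
  }
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  adj <- stats::p.adjust(pvalues, method = "holm")
  data.frame(p = pvalues, p_adjusted = adj, reject = adj <= alpha)
}

#' Correlation screen between sleep features and memory variables
#'
#' Pearson correlations of every sleep feature against every memory
#' variable, separately per condition, flagged for significance against a
#' Bonferroni-corrected alpha (the screening convention: 0.0025 for the
#' spectral screen, 0.004 for the event-density screen).  Subjects are
#' matched by id within condition; pairs with fewer than `min_n` matched
#' subjects or a constant vector are returned with `NA` statistics and
#' noted in the `note` column.
#'
#' @param features data.frame with columns `subject`, `condition`,
#'   `feature`, `value`.
#' @param scores data.frame with columns `subject`, `condition`,
#'   `variable`, `value`.
#' @param alpha_corrected the Bonferroni-corrected alpha for the flag.
#' @param min_n minimum matched subjects (default 3).
#' @return data.frame: `condition`, `feature`, `variable`, `n`, `r`, `p`,
#'   `alpha_corrected`, `significant`, `note`.
#' @export
sleep_memory_screen <- function(features, scores, alpha_corrected = 0.0025,
                                min_n = 3L) {
  stopifnot(all(c("subject", "condition", "feature", "value") %in%
                  names(features)),
            all(c("subject", "condition", "variable", "value") %in%
                  names(scores)))
  out <- list()
  for (cond in unique(features$condition)) {
    fsub <- features[features$condition == cond, ]
    ssub <- scores[scores$condition == cond, ]
    for (ft in unique(fsub$feature)) {
      fv <- fsub[fsub$feature == ft, c("subject", "value")]
      for (vb in unique(ssub$variable)) {
        sv <- ssub[ssub$variable == vb, c("subject", "value")]
        m <- merge(fv, sv, by = "subject")
        m <- m[stats::complete.cases(m), ]
        row <- data.frame(condition = cond, feature = ft, variable = vb,
                          n = nrow(m), r = NA_real_, p = NA_real_,
                          alpha_corrected = alpha_corrected,
                          significant = FALSE, note = "",
                          stringsAsFactors = FALSE)
        if (nrow(m) < min_n) {
          row$note <- "too few subjects"
        } else if (stats::sd(m$value.x) == 0 || stats::sd(m$value.y) == 0) {
          row$note <- "constant vector"
        } else {
          ct <- stats::cor.test(m$value.x, m$value.y, method = "pearson")
          row$r <- unname(ct$estimate)
          row$p <- ct$p.value
          row$significant <- ct$p.value < alpha_corrected
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
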
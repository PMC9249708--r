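#' Generate a synthetic recognition-memory cohort
#'
#' Simulates the within-subject, two-condition cross-over recognition
#' design: every subject encodes negative and neutral pictures in each
#' condition and is tested twice, with half the old pictures and a fresh
#' set of novel pictures per test.  Confidence ratings (1 = very confident
#' present ... 6 = very confident not present) are drawn from the
#' equal-variance Gaussian signal-detection model at the configured
#' per-cell true d-prime and criterion, so downstream scoring can be
#' validated against known parameters.
#'
#' Per subject, condition and test the trial table holds
#' `n_old_per_valence` old and `n_new_per_valence` novel pictures per
#' valence (defaults 10 + 10), plus 4 buffer rows (the primacy/recency
#' pictures, 8 per condition split across the two tests) that scoring must
#' exclude.  The companion encoding table lists all 48 encoded pictures per
#' condition: 20 negative and 28 neutral, the extra 8 neutral placed at
#' serial positions 1-4 and 45-48 as buffers.
#'
#' @param config a [behavior_sim_config()].
#' @return list with data.frames `trials` (subject, condition, test,
#'   valence, status, picture, confidence), `encoding` (subject, condition,
#'   position, valence, picture, is_buffer) and `subjects` (subject,
#'   weight_kg).
#' @export
generate_behavior <- function(config) {
  if (!inherits(config, "behavior_sim_config")) {
    stop("config must be a behavior_sim_config", call. = FALSE)
  }
  set.seed(config$seed)
  n_old <- config$n_old_per_valence
  n_new <- config$n_new_per_valence
  conds <- c("placebo", "zolpidem")
  vals <- c("negative", "neutral")
  subj <- seq_len(config$n_subjects)

  subjects <- data.frame(
    subject = subj,
    weight_kg = stats::rnorm(config$n_subjects,
                             config$weight_mean_kg, config$weight_sd_kg)
  )

  # encoding lists: per condition 2*n_old negative + 2*n_old + 8 neutral,
  # buffers (neutral) at the first and last four serial positions
  enc <- do.call(rbind, lapply(subj, function(s) {
    do.call(rbind, lapply(conds, function(cn) {
      mid <- sample(c(rep("negative", 2L * n_old), rep("neutral", 2L * n_old)))
      data.frame(subject = s, condition = cn,
                 position = seq_len(2L * n_old + 2L * n_old + 8L),
                 valence = c(rep("neutral", 4L), mid, rep("neutral", 4L)),
                 stringsAsFactors = FALSE)
    }))
  }))
  enc$is_buffer <- enc$position <= 4L |
    enc$position > max(enc$position) - 4L
  enc$picture <- paste0(substr(enc$condition, 1, 1), "_enc_", enc$position)

  # confidence criteria: five fixed cuts symmetric around the decision
  # criterion; the middle cut is the criterion itself so collapsing at 3/4
  # reproduces the present / not-present decision
  cuts <- config$criterion +
    c(-1.5, -0.5, 0, 0.5, 1.5) * config$confidence_noise

  dmap <- config$true_dprime
  cell_d <- function(cn, te, va) {
    i <- which(dmap$condition == cn & dmap$test == te & dmap$valence == va)
    if (length(i) != 1L) {
      stop("true_dprime must contain exactly one row per cell", call. = FALSE)
    }
    dmap$dprime[i]
  }

  grid <- expand.grid(subject = subj, condition = conds, test = 1:2,
                      stringsAsFactors = FALSE)
  trials <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    s <- grid$subject[g]; cn <- grid$condition[g]; te <- grid$test[g]
    block <- do.call(rbind, lapply(vals, function(va) {
      d <- cell_d(cn, te, va)
      data.frame(
        subject = s, condition = cn, test = te, valence = va,
        status = c(rep("old", n_old), rep("new", n_new)),
        latent = c(stats::rnorm(n_old, mean = d),
                   stats::rnorm(n_new, mean = 0)),
        stringsAsFactors = FALSE
      )
    }))
    # four buffer pictures shown at each test, excluded from scoring;
    # buffers were encoded, so they behave like old items
    buf <- data.frame(
      subject = s, condition = cn, test = te, valence = "neutral",
      status = "buffer",
      latent = stats::rnorm(4L, mean = cell_d(cn, te, "neutral")),
      stringsAsFactors = FALSE
    )
    rbind(block, buf)
  }))
  trials$confidence <- 6L - findInterval(trials$latent, cuts)
  trials$picture <- paste0(substr(trials$condition, 1, 1), "t", trials$test,
                           "_", seq_len(nrow(trials)))
  trials$latent <- NULL

  list(trials = trials, encoding = enc, subjects = subjects)
}
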
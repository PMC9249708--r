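test_that("paired t-test reproduces hand-computed values and symmetry", {
  x <- c(2, 4, 6, 8)
  y <- c(1, 2, 3, 4)          # differences 1, 2, 3, 4
  r <- paired_t(x, y)
  expect_equal(r$t, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-9)
  expect_equal(r$t, 3.872983, tolerance = 1e-6)
  expect_equal(r$df, 3)
  r2 <- paired_t(y, x)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_true(is.na(same$t))
})

test_that("Holm-Bonferroni matches its definition on worked examples", {
  r <- holm_bonferroni(0.04, alpha = 0.05)
  expect_true(r$reject)
  # step-down schedule: 0.01 <= 0.05/3 rejects; 0.03 > 0.05/2 stops the
  # procedure, so 0.03 and 0.04 survive (verified against holm_oracle)
  r2 <- holm_bonferroni(c(0.01, 0.04, 0.03), alpha = 0.05)
  expect_identical(r2$reject, holm_oracle(c(0.01, 0.04, 0.03), 0.05))
  expect_identical(r2$reject, c(TRUE, FALSE, FALSE))
  r3 <- holm_bonferroni(rep(1, 5))
  expect_true(!any(r3$reject))
  expect_equal(nrow(holm_bonferroni(numeric(0))), 0L)
})

test_that("Holm decisions equal the brute-force step-down on random
           p-vectors", {
  set.seed(2024)
  for (i in 1:200) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    alpha <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(holm_bonferroni(p, alpha)$reject,
                     holm_oracle(p, alpha))
  }
})

test_that("RM-ANOVA F and p equal the aov Error-strata oracle, with and
           without covariate", {
  set.seed(71)
  n <- 10
  d <- expand.grid(subject = 1:n, condition = c("placebo", "zolpidem"),
                   test = 1:2, valence = c("negative", "neutral"),
                   stringsAsFactors = FALSE)
  d$dprime <- rnorm(nrow(d)) + 0.4 * (d$condition == "zolpidem") +
    0.6 * (d$condition == "zolpidem") * (d$valence == "negative")
  w <- rnorm(n, 70, 10)
  d$weight_kg <- w[d$subject]

  oracle_F <- function(formula, data) {
    sm <- summary(stats::aov(formula, data = data))
    out <- list()
    for (stratum in sm) {
      tab <- stratum[[1]]
      for (i in seq_len(nrow(tab))) {
        nm <- trimws(rownames(tab)[i])
        if (nm == "Residuals") next
        out[[nm]] <- c(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
      }
    }
    out
  }
  da <- transform(d, subject = factor(subject), condition = factor(condition),
                  test = factor(test), valence = factor(valence))

  # no covariate
  mine <- rm_anova_2x2x2(d)
  orc <- oracle_F(dprime ~ condition * test * valence +
                    Error(subject / (condition * test * valence)), da)
  key <- c(drug = "condition", test = "test", emotion = "valence",
           `drug:test` = "condition:test",
           `drug:emotion` = "condition:valence",
           `test:emotion` = "test:valence",
           `drug:test:emotion` = "condition:test:valence")
  for (eff in names(key)) {
    row <- mine[mine$effect == eff, ]
    expect_equal(row$F, unname(orc[[key[[eff]]]]["F"]), tolerance = 1e-8)
    expect_equal(row$p, unname(orc[[key[[eff]]]]["p"]), tolerance = 1e-8)
  }

  # with mean-centred covariate and its interactions
  da$wc <- d$weight_kg - mean(w)
  mine2 <- rm_anova_2x2x2(d, covariate = "weight_kg")
  orc2 <- oracle_F(dprime ~ wc * condition * test * valence +
                     Error(subject / (condition * test * valence)), da)
  for (eff in names(key)) {
    row <- mine2[mine2$effect == eff, ]
    expect_equal(row$F, unname(orc2[[key[[eff]]]]["F"]), tolerance = 1e-8)
    row_i <- mine2[mine2$effect == paste0(eff, ":weight_kg"), ]
    expect_equal(row_i$F, unname(orc2[[paste0("wc:", key[[eff]])]]["F"]),
                 tolerance = 1e-8)
  }
  expect_equal(mine2$F[mine2$effect == "weight_kg"],
               unname(orc2[["wc"]]["F"]), tolerance = 1e-8)
  expect_true(all(mine2$df_den == n - 2))
})

test_that("a constant covariate reduces to the covariate-free analysis
           and equal cell means give null effects", {
  set.seed(72)
  n <- 8
  d <- expand.grid(subject = 1:n, condition = c("a", "b"), test = 1:2,
                   valence = c("x", "y"), stringsAsFactors = FALSE)
  d$dprime <- rnorm(nrow(d))
  d$weight_kg <- 70
  with_const <- rm_anova_2x2x2(d, covariate = "weight_kg")
  without <- rm_anova_2x2x2(d)
  expect_equal(with_const, without)

  # all cell means identical and no noise: every F ~ 0
  d2 <- d
  d2$dprime <- rep(rnorm(n), times = 8)   # subject offsets only
  r <- rm_anova_2x2x2(d2)
  expect_true(all(r$F < 1e-12))
})

test_that("incomplete subjects are dropped listwise with reported n", {
  set.seed(73)
  n <- 9
  d <- expand.grid(subject = 1:n, condition = c("a", "b"), test = 1:2,
                   valence = c("x", "y"), stringsAsFactors = FALSE)
  d$dprime <- rnorm(nrow(d))
  d <- d[!(d$subject == 3 & d$test == 2), ]   # subject 3 incomplete
  expect_message(r <- rm_anova_2x2x2(d), "dropped")
  expect_true(all(r$n == n - 1))
})

test_that("correlation screen recovers exact and noisy relationships", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.7)
  feats <- data.frame(subject = 1:6, condition = "zolpidem",
                      feature = "swa", value = x)
  mk_scores <- function(y) data.frame(subject = 1:6,
                                      condition = "zolpidem",
                                      variable = "d1", value = y)
  r1 <- sleep_memory_screen(feats, mk_scores(x), alpha_corrected = 0.0025)
  expect_equal(r1$r, 1)
  r2 <- sleep_memory_screen(feats, mk_scores(-2 * x + rnorm(6, sd = 1e-8)),
                            alpha_corrected = 0.0025)
  expect_equal(r2$r, -1, tolerance = 1e-6)
  expect_true(r2$significant)
  # constant feature is flagged, not crashed
  feats$value <- 5
  r3 <- sleep_memory_screen(feats, mk_scores(x), alpha_corrected = 0.0025)
  expect_true(is.na(r3$r))
  expect_match(r3$note, "constant")
})

test_that("the screen's r is consistent with the generating correlation
           on a synthetic cohort", {
  set.seed(74)
  n <- 26
  a <- 0.8
  score <- rnorm(n)
  feature <- a * score + rnorm(n, sd = sqrt(1 - a^2))
  feats <- data.frame(subject = 1:n, condition = "zolpidem",
                      feature = "sigma", value = feature)
  scs <- data.frame(subject = 1:n, condition = "zolpidem",
                    variable = "d", value = score)
  r <- sleep_memory_screen(feats, scs, alpha_corrected = 0.004)
  # population r = 0.8; 95% CI half-width at n = 26 is about 0.25
  expect_lt(abs(r$r - a), 0.3)
  expect_equal(r$n, n)
})
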
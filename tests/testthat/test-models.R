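# Small kinematics-like table with a known group effect and random intercepts.
make_mixed_data <- function(n_subj = 40, n_obs = 6, b_group = 3,
                            sd_u = 2, sd_e = 1, sessions = 2, seed = 1) {
  set.seed(seed)
  subj <- rep(seq_len(n_subj), each = n_obs)
  decoding <- rep(rep(c("poor", "good"), each = n_subj / 2), each = n_obs)
  u <- rnorm(n_subj, 0, sd_u)[subj]
  data.frame(
    subject = paste0("S", subj),
    decoding = factor(decoding, levels = c("poor", "good")),
    session = rep_len(seq_len(sessions), n_subj * n_obs),
    phase = rep_len(1:2, n_subj)[subj],
    word = rep_len(c("bora", "muti", "faderont"), n_subj * n_obs),
    y = 10 + b_group * (decoding == "good") + u + rnorm(n_subj * n_obs, 0, sd_e)
  )
}

test_that("the kinematics model recovers a known group contrast", {
  d <- make_mixed_data(b_group = 3, seed = 42)
  fit <- fit_kinematics_model(d, "y")
  expect_s3_class(fit, "digitrace_fit")
  ct <- decoding_contrast(fit)
  expect_gt(ct$estimate, 0)
  expect_lt(abs(ct$estimate - 3), 3 * ct$SE)
  expect_true(ct$ci_lower < 3 & 3 < ct$ci_upper)
})

test_that("inestimable designs are rejected", {
  d <- make_mixed_data(sessions = 1)
  expect_error(fit_kinematics_model(d, "y"), "one session")
  d2 <- make_mixed_data()
  d2$word <- "bora"
  expect_error(fit_kinematics_model(d2, "y", include_word_re = TRUE),
               "one word")
  expect_error(fit_kinematics_model(make_mixed_data(), "missing_col"),
               "missing")
})

test_that("a word random intercept is accepted for word-level analyses", {
  d <- make_mixed_data(seed = 9)
  # only 3 words: the word variance component may sit at zero (flagged)
  fit <- suppressWarnings(fit_kinematics_model(d, "y", include_word_re = TRUE))
  expect_true("word" %in% names(fit$n_groups))
  expect_equal(unname(fit$n_groups[["word"]]), 3L)
})

test_that("the reading-change model needs its covariates and flags singular fits", {
  set.seed(3)
  n <- 30
  subj <- rep(seq_len(n), 2)
  d <- data.frame(
    subject = paste0("S", subj),
    phase = rep(1:2, each = n),
    modality = ifelse((subj <= n / 2) == (rep(1:2, each = n) == 1),
                      "digit", "paper"),
    age = rnorm(2 * n, 6.3, 0.3),
    similarities = rnorm(2 * n, 10, 3), matrix = rnorm(2 * n, 10, 3),
    vocabulary = rnorm(2 * n, 10, 3), oral_comprehension = rnorm(2 * n, 19, 2),
    memory_span = rnorm(2 * n, 11, 3), cancellation = rnorm(2 * n, 10, 3),
    selective_attention = rnorm(2 * n, 120, 30))
  d$gain <- 7 + 3.33 * (d$modality == "digit") + rnorm(n, 0, 2)[subj] +
    rnorm(2 * n, 0, 1.5)
  fit <- fit_reading_change_model(d)
  b_mod <- fit$coefficients["modalitydigit", ]
  expect_lt(abs(b_mod$b - 3.33), 3 * b_mod$SE)

  expect_error(fit_reading_change_model(d[, !(names(d) == "age")]), "age")

  d0 <- d
  d0$gain <- rnorm(2 * n)  # no subject structure: variance component at zero
  expect_warning(f0 <- fit_reading_change_model(d0), "singular")
  expect_true(f0$singular)
})

test_that("semi-partial R2 matches its variance-ratio definition", {
  d <- make_mixed_data(b_group = 3, seed = 7)
  fit <- lmerTest::lmer(y ~ decoding + (1 | subject), data = d)
  r2 <- semi_partial_r2(fit)
  # naive recomputation with explicit algebra
  X <- model.matrix(fit)
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  denom <- var(drop(X %*% beta)) + sum(vc$vcov[is.na(vc$var2)])
  g <- X[, "decodinggood"] * beta["decodinggood"]
  expect_equal(unname(r2[["decoding"]]), var(g) / denom, tolerance = 1e-10)
  expect_equal(unname(r2[["model"]]), var(drop(X %*% beta)) / denom,
               tolerance = 1e-10)
  expect_error(semi_partial_r2(fit, "nonexistent"), "not in the model")
})

test_that("semi-partial R2 approaches the closed-form variance ratio at large n", {
  # truth: var(b g)/(var(b g) + sd_u^2 + sd_e^2) with balanced 0/1 coding
  d <- make_mixed_data(n_subj = 300, n_obs = 5, b_group = 3, sd_u = 0.5,
                       sd_e = 1, seed = 11)
  fit <- lmerTest::lmer(y ~ decoding + (1 | subject), data = d)
  r2 <- semi_partial_r2(fit, "decoding")
  truth <- (9 * 0.25) / (9 * 0.25 + 0.25 + 1)
  expect_equal(unname(r2[["decoding"]]), truth, tolerance = 0.05)
})

test_that("model-level R2 bounds term-level R2 and null terms vanish", {
  d <- make_mixed_data(b_group = 2, seed = 5)
  d$noise <- rnorm(nrow(d))
  fit <- lmerTest::lmer(y ~ decoding + noise + (1 | subject), data = d)
  r2 <- semi_partial_r2(fit)
  expect_true(all(r2[["model"]] >= r2[-1] - 1e-12))
  expect_lt(r2[["noise"]], 0.01)
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("model comparison reproduces the information-criterion identities", {
  d <- make_mixed_data(seed = 8)
  f1 <- fit_kinematics_model(d, "y", REML = FALSE)
  f2 <- fit_kinematics_model(d, "y", REML = FALSE)
  tab <- compare_models(list(full = f1, again = f2))
  expect_equal(tab$AIC[1], tab$AIC[2])
  expect_equal(tab$RMSE[1], tab$RMSE[2])
  expect_equal(tab$AIC[1], AIC(f1$fit), tolerance = 1e-8)
  expect_equal(tab$BIC[1], BIC(f1$fit), tolerance = 1e-8)
  expect_equal(tab$AIC[1], 2 * tab$k[1] - 2 * tab$logLik[1])

  d2 <- d[-(1:6), ]
  f3 <- fit_kinematics_model(d2, "y", REML = FALSE)
  expect_error(compare_models(list(f1, f3)), "differing observation")
})

test_that("a model with real covariate signal wins the AIC comparison", {
  set.seed(19)
  wins <- 0L
  for (i in 1:10) {
    d <- make_mixed_data(b_group = 0, seed = 100 + i)
    d$skill <- rnorm(nrow(d))
    d$y <- d$y + 2 * d$skill
    full <- fit_mixed_model(y ~ decoding + skill + (1 | subject), d,
                            REML = FALSE)
    minimal <- fit_mixed_model(y ~ decoding + (1 | subject), d, REML = FALSE)
    tab <- compare_models(list(full = full, minimal = minimal))
    if (tab$model[1] == "full") wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("the normality gate selects t vs wilcoxon as Shapiro dictates", {
  set.seed(4)
  a <- rnorm(27); b <- rnorm(27, 0.3)
  stopifnot(shapiro.test(a)$p.value > 0.05, shapiro.test(b)$p.value > 0.05)
  gc1 <- group_comparison(c(a, b), rep(c("g1", "g2"), each = 27))
  expect_equal(gc1$test, "t")

  skew <- rexp(27)
  stopifnot(shapiro.test(skew)$p.value <= 0.05)
  gc2 <- group_comparison(c(a, skew), rep(c("g1", "g2"), each = 27))
  expect_equal(gc2$test, "wilcoxon")

  same <- group_comparison(c(a, a), rep(c("g1", "g2"), each = 27))
  expect_equal(same$p, 1, tolerance = 1e-12)

  expect_error(group_comparison(rnorm(4), rep(c("g1", "g2"), 2)),
               "at least 3")
})
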
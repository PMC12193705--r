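#' Fit the reading-change mixed model
#'
#' Models the pre/post gain on a reading score with training modality
#' (digit-tracking vs paper), training phase (1 vs 2), their interaction, and
#' a priori cognitive covariates as fixed effects, plus a random intercept per
#' subject:
#' `gain ~ modality * phase + <covariates> + (1 | subject)`.
#' Degrees of freedom use Satterthwaite's approximation throughout. Estimates
#' `b` are unstandardised, in the response's native units. Reference levels
#' are "paper" and phase "1" (treatment coding), so printed contrasts read
#' digit-tracking minus paper.
#'
#' @param data One row per subject x phase with columns `gain`, `modality`,
#'   `phase`, `subject`, and every covariate.
#' @param covariates Character vector of covariate column names (the study
#'   used age plus eight general cognitive scores).
#' @param REML Use REML (`TRUE`, final estimates) or ML (`FALSE`, required to
#'   compare fixed structures by AIC).
#' @return A `digitrace_fit`; see [fit_kinematics_model()] for the contents.
#' @export
fit_reading_change_model <- function(data,
                                     covariates = c("age", "similarities",
                                                    "matrix", "vocabulary",
                                                    "oral_comprehension",
                                                    "memory_span",
                                                    "cancellation",
                                                    "selective_attention"),
                                     REML = TRUE) {
  needed <- c("gain", "modality", "phase", "subject", covariates)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data$modality <- stats::relevel(factor(data$modality), ref = "paper")
  data$phase <- stats::relevel(factor(data$phase), ref = sort(unique(as.character(data$phase)))[1])
  rhs <- paste(c("modality * phase", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("gain ~", rhs, "+ (1 | subject)"))
  .fit_lmm(fml, data, REML = REML)
}

#' Fit the finger-kinematics mixed model
#'
#' The study's kinematics specification: a per-trial (or per-event) movement
#' variable modelled by decoding skill (good vs poor), session (1-6,
#' categorical) and training phase (1 vs 2), all interactions, with a random
#' intercept per subject — and per word for word-level analyses:
#' `response ~ decoding * session * phase + (1|subject) [+ (1|word)]`.
#' Reference levels: "poor", session "1", phase "1".
#'
#' @param data Table with columns `decoding` ("good"/"poor"), `session`,
#'   `phase`, `subject`, the response, and `word` if `include_word_re`.
#' @param response Name of the response column.
#' @param include_word_re Add a `(1|word)` random intercept.
#' @param REML Use REML (`TRUE`) or ML (`FALSE`).
#' @return An object of class `digitrace_fit`: a list with the `lmerModLmerTest`
#'   `fit`, the `coefficients` table (`b`, `SE`, `df`, `t`, `p`, Wald 95% CI),
#'   the Satterthwaite `anova` table, `r2` (model-level and per-term
#'   semi-partial R-squared), `AIC`, `BIC`, `RMSE`, `logLik`, `n_obs`,
#'   `n_groups`, `REML` and `singular`.
#' @export
fit_kinematics_model <- function(data, response, include_word_re = FALSE,
                                 REML = TRUE) {
  needed <- c(response, "decoding", "session", "phase", "subject",
              if (include_word_re) "word")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data$decoding <- stats::relevel(factor(data$decoding), ref = "poor")
  data$session <- factor(data$session)
  data$phase <- factor(data$phase)
  if (nlevels(data$session) < 2L) {
    stop("only one session present: session terms inestimable", call. = FALSE)
  }
  if (include_word_re && length(unique(data$word)) < 2L) {
    stop("word random intercept requested but only one word present",
         call. = FALSE)
  }
  re <- if (include_word_re) "(1 | subject) + (1 | word)" else "(1 | subject)"
  fml <- stats::as.formula(paste(response, "~ decoding * session * phase +", re))
  .fit_lmm(fml, data, REML = REML)
}

#' Fit an arbitrary linear mixed model with the package's reporting
#'
#' Thin wrapper around [lmerTest::lmer()] producing the same `digitrace_fit`
#' report (Satterthwaite tests, Wald CIs, semi-partial R-squared, AIC/BIC/
#' RMSE) as the study-specific model constructors. Useful for ad-hoc model
#' structures in comparisons.
#'
#' @param formula An `lme4` model formula.
#' @param data Model data.
#' @param REML Use REML (`TRUE`) or ML (`FALSE`).
#' @return A `digitrace_fit`.
#' @export
fit_mixed_model <- function(formula, data, REML = TRUE) {
  .fit_lmm(formula, data, REML = REML)
}

# Shared fitting path for the model wrappers.
.fit_lmm <- function(formula, data, REML = TRUE) {
  fit <- lmerTest::lmer(formula, data = data, REML = REML)
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("fit is singular (a variance component is estimated at zero)",
            call. = FALSE)
  }
  cs <- as.data.frame(stats::coef(summary(fit)))
  names(cs) <- c("b", "SE", "df", "t", "p")
  cs$ci_lower <- cs$b - stats::qt(0.975, cs$df) * cs$SE
  cs$ci_upper <- cs$b + stats::qt(0.975, cs$df) * cs$SE
  res <- stats::residuals(fit)
  out <- list(
    fit = fit,
    formula = formula,
    coefficients = cs,
    anova = as.data.frame(stats::anova(fit)),  # Satterthwaite, type III
    r2 = semi_partial_r2(fit),
    AIC = stats::AIC(fit),
    BIC = stats::BIC(fit),
    logLik = as.numeric(stats::logLik(fit)),
    RMSE = sqrt(mean(res^2)),
    n_obs = stats::nobs(fit),
    n_groups = lme4::ngrps(fit),
    REML = REML,
    singular = singular
  )
  class(out) <- "digitrace_fit"
  out
}

#' @export
print.digitrace_fit <- function(x, ...) {
  cat("Linear mixed model (Satterthwaite df):\n  ")
  print(x$formula)
  cat(sprintf("  n = %d observations, groups: %s%s\n", x$n_obs,
              paste(names(x$n_groups), x$n_groups, sep = "=", collapse = ", "),
              if (x$singular) "  [singular]" else ""))
  stats::printCoefmat(as.matrix(x$coefficients[, c("b", "SE", "df", "t", "p")]),
               P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("AIC %.2f  BIC %.2f  RMSE %.3f  R2_model %.3f\n",
              x$AIC, x$BIC, x$RMSE, x$r2[["model"]]))
  invisible(x)
}

#' Semi-partial R-squared for mixed-model fixed effects
#'
#' Variance-ratio effect sizes in the Nakagawa-Schielzeth tradition (with
#' Johnson's extension to random-slope-free denominators): the model-level
#' R-squared is the variance of the fixed-effect predictions over the total
#' model variance (fixed + random-intercept components + residual), and each
#' term's semi-partial R-squared replaces the numerator with the variance of
#' that term's own contribution to the linear predictor.
#'
#' With correlated predictors the per-term numerators need not sum to the
#' model numerator; in the balanced designs this package generates the
#' model-level value bounds every term-level value.
#'
#' @param fit An `lmerMod`/`lmerModLmerTest` or a `digitrace_fit`.
#' @param term Optional term label (as in `attr(terms(fit), "term.labels")`);
#'   `NULL` returns the model-level value and every term.
#' @return Named numeric vector (`model`, then one entry per requested term),
#'   values in \[0, 1\].
#' @export
semi_partial_r2 <- function(fit, term = NULL) {
  if (inherits(fit, "digitrace_fit")) fit <- fit$fit
  stopifnot(inherits(fit, "merMod"))
  X <- stats::model.matrix(fit)
  beta <- lme4::fixef(fit)
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_random <- sum(vc$vcov[is.na(vc$var2)])  # intercept variances + residual
  pred <- drop(X %*% beta)
  var_fixed <- stats::var(pred)
  denom <- var_fixed + var_random
  wanted <- if (is.null(term)) labels else term
  bad <- setdiff(wanted, labels)
  if (length(bad)) {
    stop("term(s) not in the model: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  r2_terms <- vapply(wanted, function(tl) {
    cols <- which(asgn == match(tl, labels))
    stats::var(drop(X[, cols, drop = FALSE] %*% beta[cols])) / denom
  }, 0)
  c(model = var_fixed / denom, r2_terms)
}

#' Compare mixed models by AIC, BIC and RMSE
#'
#' Validation table for competing fixed-effect structures on identical
#' observations (e.g. the minimal modality-phase model vs the full model with
#' cognitive covariates). AIC = 2k - 2 logL and BIC = k log(n) - 2 logL are
#' recomputed from each fit's log-likelihood; rows are sorted by AIC. Models
#' fitted by REML cannot be compared across different fixed structures — fit
#' with `REML = FALSE` for this table.
#'
#' @param fits Named list of `digitrace_fit` objects on the same observations.
#' @return A data.frame (`model`, `k`, `logLik`, `AIC`, `BIC`, `RMSE`) sorted
#'   by AIC.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  ns <- vapply(fits, function(f) f$n_obs, 0L)
  if (length(unique(ns)) != 1L) {
    stop("models are fitted on differing observation sets (n = ",
         paste(ns, collapse = ", "), ")", call. = FALSE)
  }
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    k <- attr(stats::logLik(f$fit), "df")
    data.frame(model = nm, k = k, logLik = f$logLik,
               AIC = 2 * k - 2 * f$logLik,
               BIC = k * log(f$n_obs) - 2 * f$logLik,
               RMSE = f$RMSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$AIC), , drop = FALSE]
}

#' Normality-gated two-group comparison
#'
#' The descriptive group comparisons use a two-sample t test when both groups
#' pass a Shapiro-Wilk normality check at alpha = 0.05, and a two-sided
#' Wilcoxon rank-sum test otherwise.
#'
#' @param values Numeric measurements.
#' @param group Two-level factor/character of the same length.
#' @param alpha Normality-gate significance level.
#' @return A list of class `group_comparison`: `measure` means and standard
#'   errors per group, `shapiro_p`, `test` ("t" or "wilcoxon"), `statistic`,
#'   `p`.
#' @export
group_comparison <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("need exactly two groups", call. = FALSE)
  parts <- split(values, group)
  if (any(vapply(parts, length, 0L) < 3L)) {
    stop("need at least 3 observations per group", call. = FALSE)
  }
  shapiro_p <- vapply(parts, function(v) {
    if (length(unique(v)) == 1L) return(0)  # degenerate: clearly non-normal
    stats::shapiro.test(v)$p.value
  }, 0)
  normal <- all(shapiro_p > alpha)
  ht <- if (normal) stats::t.test(parts[[1]], parts[[2]]) else
    stats::wilcox.test(parts[[1]], parts[[2]], exact = FALSE)
  out <- list(
    groups = levels(group),
    means = vapply(parts, mean, 0),
    se = vapply(parts, function(v) stats::sd(v) / sqrt(length(v)), 0),
    shapiro_p = shapiro_p,
    test = if (normal) "t" else "wilcoxon",
    statistic = unname(ht$statistic),
    p = ht$p.value
  )
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: %.3f (SE %.3f) vs %.3f (SE %.3f); %s test, p = %.4g\n",
              x$groups[1], x$groups[2], x$means[1], x$se[1], x$means[2],
              x$se[2], x$test, x$p))
  invisible(x)
}

#' Marginal good-minus-poor contrast from a kinematics fit
#'
#' Averages the fitted cell means over session and phase (estimated marginal
#' means via \pkg{emmeans}, Satterthwaite df) and returns the good - poor
#' contrast with its 95% confidence interval — the quantity the
#' parameter-recovery experiments compare against the generator's truth.
#'
#' @param fit A `digitrace_fit` from [fit_kinematics_model()].
#' @return A one-row data.frame: `estimate`, `SE`, `df`, `ci_lower`,
#'   `ci_upper`.
#' @export
decoding_contrast <- function(fit) {
  if (inherits(fit, "digitrace_fit")) fit <- fit$fit
  # marginal over session and phase by design; silence the emmeans note
  # about averaging over terms involved in interactions
  emm <- suppressMessages(
    emmeans::emmeans(fit, ~decoding, lmer.df = "satterthwaite"))
  lev <- levels(stats::model.frame(fit)$decoding)
  w <- ifelse(lev == "good", 1, -1)
  ct <- emmeans::contrast(emm, method = list(good_minus_poor = w))
  ci <- stats::confint(ct)
  s <- summary(ct)
  data.frame(estimate = s$estimate, SE = s$SE, df = s$df,
             ci_lower = ci$lower.CL, ci_upper = ci$upper.CL)
}
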
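# Mixed-model likelihood-ratio tests, repeated-measures correlation,
# behavioural summaries and ordinal temporal profiles.

#' Reverse a 1-6 rating
#'
#' Confidence and familiarity are collected on a 1-6 scale with 1 = high;
#' for analysis the scales are reversed (`7 - raw`) so larger numbers mean
#' more confident / more familiar. The operation is an involution.
#'
#' @param raw integer rating(s) in 1..6.
#' @return reversed rating(s) in 1..6.
#' @export
reverse_rating <- function(raw) {
  if (any(!raw %in% 1:6)) stop("ratings must lie in 1..6")
  7 - raw
}

#' Chance-level accuracy for an n-alternative forced choice
#'
#' @param n_alternatives number of response alternatives (>= 2).
#' @return list with `probability` (exact `1/n`) and `displayed` (the
#'   two-decimal truncated presentation form, e.g. 0.16 for six
#'   alternatives).
#' @export
chance_level <- function(n_alternatives) {
  if (n_alternatives < 2) stop("need at least 2 alternatives")
  p <- 1 / n_alternatives
  list(probability = p, displayed = floor(p * 100) / 100)
}

#' Likelihood-ratio test for one effect in a linear mixed model
#'
#' Fits the full model `response ~ fixed effects + (1|random intercepts)`
#' and the model with `effect` removed, both by maximum likelihood (never
#' REML, which would invalidate fixed-effect comparisons), and compares
#' them with a chi-square likelihood-ratio test whose degrees of freedom
#' equal the number of removed parameters.
#'
#' @param data data frame containing the response, the fixed-effect columns
#'   and the random-intercept grouping columns.
#' @param response name of the response column.
#' @param effect the fixed effect to test (must appear in `fixed_effects`).
#' @param fixed_effects character vector of fixed-effect column names,
#'   entered additively (no interactions).
#' @param random_intercepts character vector of grouping factors receiving
#'   random intercepts (non-empty).
#' @param family `"gaussian"` (linear mixed model, the default used for all
#'   responses including accuracy, which is modelled on the probability
#'   scale) or `"binomial"` (logistic variant for 0/1 accuracy).
#' @param log_response take the natural log of the response before fitting
#'   (used for fixation durations, whose distribution is right-skewed).
#' @param on_singular `"error"` (default) raises a diagnostic error when
#'   either fit is singular; `"warn"` downgrades this to a warning, which is
#'   the appropriate setting inside large simulation loops where occasional
#'   boundary estimates are expected.
#' @return list of class `lrt_result` with `chi2`, `df`, `p`,
#'   `full_loglik`, `reduced_loglik`, `effect`, `response`.
#' @export
lrt_effect <- function(data, response, effect,
                       fixed_effects = c("task", "expertise"),
                       random_intercepts = c("subject", "image"),
                       family = c("gaussian", "binomial"),
                       log_response = FALSE,
                       on_singular = c("error", "warn")) {
  family <- match.arg(family)
  on_singular <- match.arg(on_singular)
  if (!effect %in% fixed_effects) stop("effect must be one of fixed_effects")
  if (!length(random_intercepts)) stop("random_intercepts must be non-empty")
  miss <- setdiff(c(response, fixed_effects, random_intercepts), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (fe in fixed_effects) {
    if (length(unique(data[[fe]])) < 2) {
      stop("fixed effect '", fe, "' has fewer than 2 levels")
    }
  }
  d <- data
  if (log_response) {
    if (any(d[[response]] <= 0)) stop("log transform requires positive response")
    d[[response]] <- log(d[[response]])
  }
  re <- paste(sprintf("(1|%s)", random_intercepts), collapse = " + ")
  f_full <- stats::as.formula(paste(
    response, "~", paste(fixed_effects, collapse = " + "), "+", re))
  fe_red <- setdiff(fixed_effects, effect)
  f_red <- stats::as.formula(paste(
    response, "~", if (length(fe_red)) paste(fe_red, collapse = " + ") else "1",
    "+", re))
  fit <- function(fml) {
    # lme4 emits its own boundary-fit message; singularity is diagnosed
    # explicitly below, so that duplicate channel is muffled
    m <- tryCatch(
      suppressMessages(
        if (family == "gaussian") {
          lme4::lmer(fml, data = d, REML = FALSE)
        } else {
          lme4::glmer(fml, data = d, family = stats::binomial())
        }),
      error = function(e) stop("mixed-model fit failed for ",
                               deparse(fml), ": ", conditionMessage(e)))
    if (lme4::isSingular(m)) {
      msg <- paste("singular mixed-model fit for", deparse(fml))
      if (on_singular == "error") stop(msg) else warning(msg)
    }
    m
  }
  m_full <- fit(f_full)
  m_red <- fit(f_red)
  ll_full <- stats::logLik(m_full)
  ll_red <- stats::logLik(m_red)
  df <- attr(ll_full, "df") - attr(ll_red, "df")
  chi2 <- max(0, 2 * (as.numeric(ll_full) - as.numeric(ll_red)))
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 full_loglik = as.numeric(ll_full),
                 reduced_loglik = as.numeric(ll_red),
                 effect = effect, response = response),
            class = "lrt_result")
}

#' Repeated-measures correlation
#'
#' Common within-subject correlation between two variables measured
#' repeatedly in the same subjects, from the ANCOVA decomposition with
#' subject as a factor: the shared slope gives the sign, the within-subject
#' sums of squares the magnitude, and the degrees of freedom are
#' `n_observations - n_subjects - 1`. Between-subject differences in level
#' are removed by the subject factor, so the statistic reflects only
#' within-subject covariation.
#'
#' @param subject subject identifier for each observation.
#' @param x,y paired measurements.
#' @return list of class `rmcorr_result` with `r`, `df`, `p`.
#' @export
rmcorr <- function(subject, x, y) {
  keep <- is.finite(x) & is.finite(y)
  subject <- factor(subject[keep]); x <- x[keep]; y <- y[keep]
  n <- length(x)
  k <- nlevels(subject)
  if (k < 2 || any(table(subject) < 2)) {
    stop("rmcorr needs >= 2 subjects each with >= 2 observations")
  }
  xw <- x - stats::ave(x, subject)   # within-subject centred
  if (all(abs(xw) < 1e-12)) stop("x has no within-subject variance")
  m <- stats::lm(y ~ subject + x)
  a <- stats::anova(m)
  ss_x <- a["x", "Sum Sq"]
  ss_err <- a["Residuals", "Sum Sq"]
  df <- n - k - 1
  r <- sign(stats::coef(m)[["x"]]) * sqrt(ss_x / (ss_x + ss_err))
  fstat <- ss_x / (ss_err / df)
  structure(list(r = unname(r), df = df,
                 p = stats::pf(fstat, 1, df, lower.tail = FALSE)),
            class = "rmcorr_result")
}

#' Ordinal temporal profile of fixation durations or saccade amplitudes
#'
#' The first fixation carries a strong central bias (long duration, short
#' first saccade) and is summarized separately; the profile proper covers
#' ordinals in `ord_range` (default 2-13), reporting per-ordinal means and
#' t-based 95% confidence intervals across events. Empty ordinal bins are
#' flagged, never imputed.
#'
#' @param events data frame with columns `ordinal` and the value column.
#' @param value name of the value column (e.g. `"duration_ms"` or
#'   `"amplitude_deg"`).
#' @param ord_range inclusive ordinal range of the profile.
#' @param conf confidence level for the interval.
#' @return list with `profile` (data frame `ordinal,n,mean,sd,ci_lo,ci_hi,
#'   empty`) and `first` (list `n,mean,sd` for ordinal-1 events).
#' @export
ordinal_profile <- function(events, value, ord_range = c(2L, 13L),
                            conf = 0.95) {
  v1 <- events[[value]][events$ordinal == 1]
  first <- list(n = length(v1),
                mean = if (length(v1)) mean(v1) else NA_real_,
                sd = if (length(v1) > 1) stats::sd(v1) else NA_real_)
  ords <- seq(ord_range[1], ord_range[2])
  rows <- lapply(ords, function(o) {
    v <- events[[value]][events$ordinal == o]
    n <- length(v)
    if (n == 0) {
      return(data.frame(ordinal = o, n = 0L, mean = NA_real_, sd = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_, empty = TRUE))
    }
    m <- mean(v)
    s <- if (n > 1) stats::sd(v) else NA_real_
    half <- if (n > 1) stats::qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
            else NA_real_
    data.frame(ordinal = o, n = n, mean = m, sd = s,
               ci_lo = m - half, ci_hi = m + half, empty = FALSE)
  })
  list(profile = do.call(rbind, rows), first = first)
}

#' Behavioural summary by group and task
#'
#' Emits the group x task table of accuracy, confidence and familiarity
#' means and SDs (ratings are expected to be already reversed), plus a
#' per-group flag marking performance significantly above chance by an
#' exact binomial test against `1/n_alternatives` at the given alpha.
#'
#' @param trials data frame with columns `group`, `task`, `correct`,
#'   `confidence`, `familiarity`.
#' @param n_alternatives alternatives of the forced choice (default 6).
#' @param alpha significance level of the above-chance test.
#' @return list with `cells` (group x task rows) and `groups` (per-group
#'   accuracy with `above_chance` flag and binomial p-value).
#' @export
summarize_behavior <- function(trials, n_alternatives = 6, alpha = 0.05) {
  p0 <- chance_level(n_alternatives)$probability
  agg <- function(d) {
    data.frame(n = nrow(d),
               accuracy_mean = mean(d$correct),
               accuracy_sd = stats::sd(d$correct),
               confidence_mean = mean(d$confidence),
               confidence_sd = stats::sd(d$confidence),
               familiarity_mean = mean(d$familiarity),
               familiarity_sd = stats::sd(d$familiarity))
  }
  cells <- do.call(rbind, lapply(split(
    trials, list(trials$group, trials$task), drop = TRUE), function(d) {
      cbind(group = d$group[1], task = d$task[1], agg(d))
    }))
  rownames(cells) <- NULL
  groups <- do.call(rbind, lapply(split(trials, trials$group), function(d) {
    bt <- stats::binom.test(sum(d$correct), nrow(d), p = p0,
                            alternative = "greater")
    data.frame(group = d$group[1], n = nrow(d),
               accuracy_mean = mean(d$correct),
               chance = p0, p_above_chance = bt$p.value,
               above_chance = bt$p.value < alpha)
  }))
  rownames(groups) <- NULL
  list(cells = cells, groups = groups)
}
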
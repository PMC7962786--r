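test_that("rating reversal is the 7 - x involution on 1..6", {
  expect_equal(reverse_rating(1), 6)
  expect_equal(reverse_rating(6), 1)
  expect_equal(reverse_rating(reverse_rating(1:6)), 1:6)
  expect_error(reverse_rating(0), "1..6")
  expect_error(reverse_rating(7), "1..6")
})

test_that("chance level is 1/n with two-decimal truncated display", {
  c6 <- chance_level(6)
  expect_equal(c6$probability, 1 / 6)
  expect_equal(c6$displayed, 0.16)     # truncation, not rounding
  expect_equal(chance_level(2)$probability, 0.5)
  expect_equal(chance_level(4)$probability, 0.25)
  expect_error(chance_level(1), "at least 2")
})

# deterministic small mixed-design table used by the LRT tests
make_lme_table <- function(seed = 1, task_effect = c(0, 0, 0),
                           group_effect = 0, n_sub = 10, n_img = 9) {
  set.seed(seed)
  tasks <- c("movement", "date", "medium")
  sub_re <- stats::rnorm(n_sub, 0, 0.6)
  img_re <- stats::rnorm(n_img, 0, 0.4)
  g <- rep(c("expert", "nonexpert"), length.out = n_sub)
  d <- expand.grid(subject = seq_len(n_sub), image = seq_len(n_img))
  d$task <- tasks[(d$subject + d$image) %% 3 + 1]
  d$expertise <- g[d$subject]
  d$y <- 5 + task_effect[match(d$task, tasks)] +
    group_effect * (d$expertise == "expert") +
    sub_re[d$subject] + img_re[d$image] + stats::rnorm(nrow(d), 0, 0.8)
  d$subject <- factor(d$subject)
  d$image <- factor(d$image)
  d
}

test_that("LRT degrees of freedom equal the removed parameter count", {
  d <- make_lme_table(seed = 2, task_effect = c(0, 0.4, -0.4),
                      group_effect = 0.5)
  r_task <- lrt_effect(d, "y", "task", on_singular = "warn")
  expect_equal(r_task$df, 2)          # 3 task levels -> 2 parameters
  r_grp <- lrt_effect(d, "y", "expertise", on_singular = "warn")
  expect_equal(r_grp$df, 1)           # 2 groups -> 1 parameter
  expect_gte(r_task$chi2, 0)
  expect_true(r_task$p >= 0 && r_task$p <= 1)
  expect_equal(r_task$chi2,
               2 * (r_task$full_loglik - r_task$reduced_loglik))
})

test_that("LRT chi2 is invariant to affine rescaling of the response", {
  d <- make_lme_table(seed = 3, task_effect = c(0, 0.3, -0.1))
  r1 <- lrt_effect(d, "y", "task", on_singular = "warn")
  d$y <- 100 * d$y + 7
  r2 <- lrt_effect(d, "y", "task", on_singular = "warn")
  expect_equal(r1$chi2, r2$chi2, tolerance = 1e-6)
})

test_that("log transform changes the model and requires positivity", {
  d <- make_lme_table(seed = 4, task_effect = c(0, 0.4, 0))
  d$y <- exp(d$y / 5)
  r_log <- suppressWarnings(lrt_effect(d, "y", "task", log_response = TRUE,
                                       on_singular = "warn"))
  r_raw <- suppressWarnings(lrt_effect(d, "y", "task",
                                       on_singular = "warn"))
  expect_false(isTRUE(all.equal(r_log$chi2, r_raw$chi2)))
  d$y[1] <- -1
  expect_error(lrt_effect(d, "y", "task", log_response = TRUE), "positive")
})

test_that("LRT input validation is strict", {
  d <- make_lme_table(seed = 5)
  expect_error(lrt_effect(d, "y", "nope"), "fixed_effects")
  expect_error(lrt_effect(d, "y", "task", random_intercepts = character(0)),
               "non-empty")
  d1 <- d; d1$task <- "movement"
  expect_error(lrt_effect(d1, "y", "task"), "fewer than 2 levels")
})

test_that("LRT detects the injected expert amplitude advantage", {
  # power simulation: expertise is a between-subject effect, so the cohort
  # is kept at study size (13 + 14 subjects); images and trial length are
  # trimmed for speed, which barely affects power against the subject-level
  # intercept variance
  geom <- screen_geometry()
  frame <- image_frame(geom = geom)
  rej <- vapply(1:20, function(s) {
    st <- generate_study(
      study_design(n_experts = 13, n_nonexperts = 14, n_images = 12,
                   trial_ms = 2000),
      generative_params(blink_rate = 0, artifact_rate = 0),
      seed = 90000 + s, render = FALSE, geom = geom, frame = frame)
    sc <- st$events[st$events$type == "saccade", ]
    tm <- stats::aggregate(amplitude_deg ~ trial_id, sc, mean)
    tm <- merge(tm, st$trials[c("trial_id", "subject_id", "image_id",
                                "task", "group")], by = "trial_id")
    tm$subject <- tm$subject_id; tm$image <- tm$image_id
    tm$expertise <- tm$group
    r <- suppressWarnings(lrt_effect(tm, "amplitude_deg", "expertise",
                                     on_singular = "warn"))
    r$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("rmcorr df formula and degenerate fixtures", {
  # 27 subjects x 36 observations -> df = 972 - 27 - 1 = 944
  set.seed(7)
  d <- expand.grid(subject = 1:27, obs = 1:36)
  d$x <- stats::rnorm(nrow(d))
  d$y <- 0.2 * d$x + stats::rnorm(nrow(d))
  r <- rmcorr(d$subject, d$x, d$y)
  expect_equal(r$df, 944)

  # y = x + subject offset -> r exactly 1 (perfect fit warns in anova)
  d$y2 <- d$x + as.numeric(d$subject) * 10
  r1 <- suppressWarnings(rmcorr(d$subject, d$x, d$y2))
  expect_equal(r1$r, 1, tolerance = 1e-12)

  # and the negative counterpart
  rm1 <- suppressWarnings(
    rmcorr(d$subject, d$x, -d$y2 + 2 * as.numeric(d$subject) * 10))
  expect_equal(rm1$r, -1, tolerance = 1e-12)

  expect_error(rmcorr(rep(1:3, 2), rep(1, 6), stats::rnorm(6)),
               "within-subject variance")
  expect_error(rmcorr(1:6, stats::rnorm(6), stats::rnorm(6)), ">= 2")
})

test_that("rmcorr matches the residualization oracle on a small table", {
  # oracle: centre x and y within subject, correlate the residuals; the
  # ANCOVA magnitude equals this correlation when each subject is balanced
  set.seed(8)
  d <- expand.grid(subject = 1:3, obs = 1:4)
  d$x <- stats::rnorm(12)
  d$y <- 0.6 * d$x + stats::rnorm(12, 0, 0.5) + d$subject * 3
  xw <- d$x - stats::ave(d$x, d$subject)
  yw <- d$y - stats::ave(d$y, d$subject)
  oracle_r <- stats::cor(xw, yw)
  r <- rmcorr(d$subject, d$x, d$y)
  expect_equal(r$r, oracle_r, tolerance = 1e-10)
  expect_equal(r$df, 12 - 3 - 1)
  # p-value from the adjusted-df t reference
  tval <- oracle_r * sqrt(r$df / (1 - oracle_r^2))
  expect_equal(r$p, 2 * stats::pt(abs(tval), r$df, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("rmcorr reduces to Pearson in the single-centred-group limit", {
  set.seed(9)
  x <- stats::rnorm(20); y <- 0.5 * x + stats::rnorm(20, 0, 0.7)
  x2 <- rep(x - mean(x), 2); y2 <- rep(y - mean(y), 2)
  r <- rmcorr(rep(1:2, each = 20), x2, y2)
  expect_equal(r$r, stats::cor(x - mean(x), y - mean(y)), tolerance = 1e-10)
})

test_that("ordinal profile excludes the first event and flags empty bins", {
  ev <- data.frame(ordinal = rep(1, 5), duration_ms = c(300, 350, 400,
                                                        380, 320))
  p <- ordinal_profile(ev, "duration_ms")
  expect_true(all(p$profile$empty))
  expect_equal(p$first$n, 5)
  expect_equal(p$first$mean, mean(ev$duration_ms))

  # 20-event fixture: per-ordinal means equal a brute-force group-by
  set.seed(10)
  ev <- data.frame(ordinal = rep(1:5, each = 4),
                   duration_ms = stats::rnorm(20, 250, 30))
  p <- ordinal_profile(ev, "duration_ms", ord_range = c(2, 13))
  byo <- tapply(ev$duration_ms, ev$ordinal, mean)
  expect_equal(p$profile$mean[p$profile$ordinal %in% 2:5],
               as.numeric(byo[c("2", "3", "4", "5")]))
  expect_true(all(p$profile$empty[p$profile$ordinal > 5]))
  # CI contains the mean and is symmetric
  ok <- !p$profile$empty
  expect_true(all(p$profile$ci_lo[ok] < p$profile$mean[ok]))
  expect_equal(p$profile$mean[ok] - p$profile$ci_lo[ok],
               p$profile$ci_hi[ok] - p$profile$mean[ok])
})

test_that("behavior summary reproduces a hand-computed fixture", {
  tr <- data.frame(
    group = rep(c("expert", "nonexpert"), each = 6),
    task = rep(c("movement", "date", "medium"), 4),
    correct = c(1, 1, 0, 1, 0, 1, 0, 0, 1, 0, 1, 0),
    confidence = c(5, 4, 6, 3, 4, 5, 2, 3, 4, 3, 2, 3),
    familiarity = c(2, 1, 3, 2, 1, 2, 1, 1, 2, 1, 2, 1))
  s <- summarize_behavior(tr)
  cell <- s$cells[s$cells$group == "expert" & s$cells$task == "movement", ]
  expect_equal(cell$accuracy_mean, 1)       # trials 1 and 4, both correct
  expect_equal(cell$confidence_mean, 4)     # (5 + 3) / 2
  cell2 <- s$cells[s$cells$group == "nonexpert" & s$cells$task == "date", ]
  expect_equal(cell2$accuracy_mean, 0.5)   # trials 8 and 11: 0 and 1
  expect_equal(cell2$familiarity_mean, 1.5)  # ratings 1 and 2

  # all-correct input gives accuracy 1 everywhere
  tr$correct <- 1
  s2 <- summarize_behavior(tr)
  expect_true(all(s2$cells$accuracy_mean == 1))

  # above-chance flag is exactly the binomial test decision
  g <- s$groups[s$groups$group == "expert", ]
  bt <- stats::binom.test(4, 6, p = 1 / 6, alternative = "greater")
  expect_equal(g$p_above_chance, bt$p.value)
  expect_equal(g$above_chance, bt$p.value < 0.05)
})
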
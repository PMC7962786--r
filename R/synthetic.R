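# Synthetic gaze-study generator.
#
# Emulates a task-dependent art-viewing experiment: a cohort of experts and
# non-experts views a balanced image x task design for 5000 ms per trial at
# 1000 Hz. Scanpaths carry the statistical structure the analysis stage
# assumes: a long, centrally biased first fixation followed by a small
# first saccade; lognormal fixation durations that grow with ordinal
# number; saccade amplitudes around 5.3 deg that shrink over the trial;
# longer fixations / shorter saccades in the medium task; larger amplitudes
# in experts; a congruence parameter kappa controlling how strongly
# observers share image ROIs; and injected blinks and hook-shaped artifact
# saccades for exercising the exclusion rules.
#
# Congruent fixations land on shared ROIs, so their amplitudes are emergent
# (ROI geometry) and identical across groups/tasks. Group, task and ordinal
# amplitude effects therefore live only in the non-congruent saccades and
# are inflated by 1/(1-kappa) inside the generator so that the *cohort-level*
# effect equals the stated parameter value (e.g. expert_amp_delta_deg is
# the cohort-level expert - non-expert amplitude difference).

#' Study design
#'
#' @param n_experts,n_nonexperts group sizes (defaults 13 and 14).
#' @param n_images number of stimulus images; must be divisible by 3 so the
#'   image sets can be balanced over tasks.
#' @param tasks the three task labels.
#' @param trial_ms stimulus presentation duration in ms.
#' @param sample_rate_hz gaze sampling rate.
#' @return object of class `study_design`.
#' @export
study_design <- function(n_experts = 13, n_nonexperts = 14, n_images = 36,
                         tasks = c("movement", "date", "medium"),
                         trial_ms = 5000, sample_rate_hz = 1000) {
  if (length(tasks) != 3) stop("exactly three tasks are required")
  if (n_images %% 3 != 0) {
    stop("infeasible balanced assignment: n_images must be divisible by 3")
  }
  structure(list(n_experts = n_experts, n_nonexperts = n_nonexperts,
                 n_images = n_images, tasks = tasks, trial_ms = trial_ms,
                 sample_rate_hz = sample_rate_hz),
            class = "study_design")
}

#' Generative parameters
#'
#' Defaults target the headline statistics of a typical art-viewing study:
#' overall mean fixation duration near 266 ms (first fixation near 385 ms),
#' mean saccade amplitude near 5.3 deg (first saccade near 3.2 deg), a
#' +0.5 deg cohort-level expert amplitude advantage, and a medium-task
#' shift towards longer fixations and smaller saccades.
#'
#' @param n_rois number of shared regions of interest per image.
#' @param congruence_kappa probability that a fixation targets a shared ROI
#'   rather than an observer-private location, in `[0,1]`.
#' @param kappa_expert_delta additive change of kappa for experts; kept at 0
#'   by default because a group-dependent kappa changes the congruent/free
#'   amplitude mix and would distort the calibrated cohort-level amplitude
#'   delta.
#' @param spread_sigma_deg SD of the jitter around an ROI centre, deg.
#' @param spread_expert_factor multiplier on the ROI jitter for experts
#'   (> 1 produces the less congruent, more dispersed expert gaze with only
#'   a second-order effect on saccade amplitudes).
#' @param fixdur_median_ms median of the lognormal fixation duration at
#'   ordinal 2.
#' @param fixdur_sdlog lognormal sigma of fixation durations.
#' @param fixdur_ordinal_slope additive duration drift, ms per ordinal.
#' @param amp_mean_deg mean of the non-congruent saccade amplitude draw.
#' @param amp_sd_deg SD of that draw.
#' @param amp_ordinal_slope amplitude drift, deg per ordinal (negative).
#' @param expert_amp_delta_deg cohort-level expert amplitude advantage.
#' @param medium_task_dur_delta_ms extra fixation duration in the medium
#'   task.
#' @param medium_task_amp_delta_deg amplitude change in the medium task
#'   (negative).
#' @param date_task_amp_delta_deg amplitude change in the date task.
#' @param first_fix_mu_ms mean duration of the initial (central) fixation.
#' @param first_sacc_amp_deg mean amplitude of the initial saccade.
#' @param blink_rate expected blinks per trial (Poisson).
#' @param artifact_rate expected hook-shaped artifact saccades per trial.
#' @param jitter_step_sd_deg per-millisecond SD of the fixational drift
#'   walk; small enough to stay far below detection thresholds.
#' @param subject_amp_sd,image_amp_sd SD of subject- and image-level random
#'   intercepts on saccade amplitude (deg); the nuisance variability the
#'   crossed random effects of the mixed models absorb.
#' @param subject_dur_sd,image_dur_sd same for fixation duration (ms).
#' @param accuracy named per-group vectors of per-task probability correct.
#' @param confidence_mean per-group x task mean reversed confidence.
#' @param familiarity_mean per-group mean reversed familiarity.
#' @return object of class `generative_params`.
#' @export
generative_params <- function(n_rois = 6,
                              congruence_kappa = 0.5,
                              kappa_expert_delta = 0,
                              spread_sigma_deg = 1.0,
                              spread_expert_factor = 1.25,
                              fixdur_median_ms = 210,
                              fixdur_sdlog = 0.42,
                              fixdur_ordinal_slope = 4,
                              amp_mean_deg = 5.6,
                              amp_sd_deg = 2.0,
                              amp_ordinal_slope = -0.15,
                              expert_amp_delta_deg = 0.5,
                              medium_task_dur_delta_ms = 25,
                              medium_task_amp_delta_deg = -0.19,
                              date_task_amp_delta_deg = 0.05,
                              first_fix_mu_ms = 385,
                              first_sacc_amp_deg = 3.2,
                              blink_rate = 0.2,
                              artifact_rate = 0.1,
                              jitter_step_sd_deg = 0.002,
                              subject_amp_sd = 0.35,
                              subject_dur_sd = 20,
                              image_amp_sd = 0.2,
                              image_dur_sd = 10,
                              accuracy = list(
                                expert = c(movement = 0.55, date = 0.40,
                                           medium = 0.55),
                                nonexpert = c(movement = 0.42, date = 0.20,
                                              medium = 0.45)),
                              confidence_mean = list(
                                expert = c(movement = 4.09, date = 4.04,
                                           medium = 4.62),
                                nonexpert = c(movement = 3.36, date = 2.86,
                                              medium = 3.80)),
                              familiarity_mean = c(expert = 2.15,
                                                   nonexpert = 1.45)) {
  p <- as.list(environment())
  if (p$congruence_kappa < 0 || p$congruence_kappa > 1) {
    stop("congruence_kappa must lie in [0,1]")
  }
  if (p$spread_sigma_deg < 0 || p$fixdur_median_ms <= 0 || p$amp_mean_deg <= 0) {
    stop("scale parameters must be positive")
  }
  structure(p, class = "generative_params")
}

# deterministic per-stream seed expansion (counter-based, < 2^31)
.substream_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 9973) %% 2147483647)
}

# shared ROI centres for one image, drawn in the inner 80% of the frame
.image_rois <- function(seed, image_index, n_rois, frame) {
  set.seed(.substream_seed(seed, 700000 + image_index))
  mx <- 0.1 * frame$width_px
  my <- 0.1 * frame$height_px
  data.frame(
    x_px = frame$origin_x_px + stats::runif(n_rois, mx, frame$width_px - mx),
    y_px = frame$origin_y_px + stats::runif(n_rois, my, frame$height_px - my))
}

# one scanpath: returns the ground-truth event table for a single trial
.simulate_scanpath <- function(rois, task, group, params, frame, geom,
                               trial_ms, amp_off = 0, dur_off = 0) {
  ppd <- px_per_degree(geom)
  kappa <- params$congruence_kappa +
    if (group == "expert") params$kappa_expert_delta else 0
  kappa <- min(max(kappa, 0), 1)
  infl <- 1 / max(1 - params$congruence_kappa, 0.05)
  is_exp <- group == "expert"
  task_amp <- switch(task,
                     medium = params$medium_task_amp_delta_deg,
                     date = params$date_task_amp_delta_deg,
                     0)
  task_dur <- if (task == "medium") params$medium_task_dur_delta_ms else 0
  mu_log <- log(params$fixdur_median_ms)
  cx <- frame$origin_x_px + frame$width_px / 2
  cy <- frame$origin_y_px + frame$height_px / 2
  clamp_frame <- function(x, y) {
    c(min(max(x, frame$origin_x_px + 2), frame$origin_x_px + frame$width_px - 3),
      min(max(y, frame$origin_y_px + 2), frame$origin_y_px + frame$height_px - 3))
  }

  pos <- clamp_frame(cx + stats::rnorm(1, 0, 0.5 * ppd),
                     cy + stats::rnorm(1, 0, 0.5 * ppd))
  first_mu_log <- log(params$first_fix_mu_ms) - 0.30^2 / 2
  ev <- list()
  t <- 0
  ord_fix <- 1L
  ord_sac <- 0L
  n_art <- stats::rpois(1, params$artifact_rate)

  fix_dur <- function(ord) {
    base <- if (ord == 1) stats::rlnorm(1, first_mu_log, 0.30)
            else stats::rlnorm(1, mu_log, params$fixdur_sdlog) +
              params$fixdur_ordinal_slope * (ord - 2) + task_dur + dur_off
    round(max(base, 40))  # whole milliseconds: events align with samples
  }
  add <- function(e) ev[[length(ev) + 1L]] <<- e

  d <- fix_dur(1L)
  add(list(type = "fixation", onset = t, dur = d, x = pos[1], y = pos[2],
           ordinal = ord_fix, congruent = FALSE, artifact = FALSE))
  t <- t + d

  repeat {
    ord_sac <- ord_sac + 1L
    congruent <- ord_sac > 1L && stats::runif(1) < kappa
    if (ord_sac == 1L) {
      a <- max(0.5, stats::rnorm(1, params$first_sacc_amp_deg, 1.0))
      th <- stats::runif(1, 0, 2 * pi)
      tgt <- clamp_frame(pos[1] + a * ppd * cos(th),
                         pos[2] + a * ppd * sin(th))
    } else if (congruent) {
      dists <- sqrt((rois$x_px - pos[1])^2 + (rois$y_px - pos[2])^2) / ppd
      w <- exp(-dists / 3.5)
      if (any(dists >= 1)) w[dists < 1] <- 0
      j <- sample.int(nrow(rois), 1, prob = w)
      spr <- params$spread_sigma_deg *
        (if (is_exp) params$spread_expert_factor else 1) * ppd
      tgt <- clamp_frame(rois$x_px[j] + stats::rnorm(1, 0, spr),
                         rois$y_px[j] + stats::rnorm(1, 0, spr))
    } else {
      # group/task deltas are cohort-level targets: only the non-congruent
      # fraction carries them, hence the 1/(1-kappa) inflation; the ordinal
      # slope is a within-condition drift and enters uninflated
      a_mu <- params$amp_mean_deg + infl *
        ((if (is_exp) params$expert_amp_delta_deg else 0) + task_amp) +
        params$amp_ordinal_slope * (ord_sac - 2) + amp_off
      a <- min(max(stats::rnorm(1, a_mu, params$amp_sd_deg), 0.7), 25)
      tgt <- NULL
      for (k in 1:30) {
        th <- stats::runif(1, 0, 2 * pi)
        cand <- c(pos[1] + a * ppd * cos(th), pos[2] + a * ppd * sin(th))
        if (in_frame(cand[1], cand[2], frame)) { tgt <- cand; break }
      }
      if (is.null(tgt)) {
        th <- atan2(cy - pos[2], cx - pos[1])
        tgt <- clamp_frame(pos[1] + a * ppd * cos(th),
                           pos[2] + a * ppd * sin(th))
      }
    }
    amp <- sqrt(sum((tgt - pos)^2)) / ppd
    artifact <- n_art > 0 && ord_sac > 1L && stats::runif(1) < 0.35
    if (artifact) n_art <- n_art - 1L
    sdur <- max(12, round(2.2 * (if (artifact) 4 * amp else amp) + 21))
    d <- fix_dur(ord_fix + 1L)
    if (t + sdur + 40 > trial_ms) break
    add(list(type = "saccade", onset = t, dur = sdur,
             x0 = pos[1], y0 = pos[2], x = tgt[1], y = tgt[2],
             amplitude = amp, ordinal = ord_sac, congruent = congruent,
             artifact = artifact))
    t <- t + sdur
    ord_fix <- ord_fix + 1L
    truncated <- t + d > trial_ms
    if (truncated) d <- trial_ms - t
    add(list(type = "fixation", onset = t, dur = d, x = tgt[1], y = tgt[2],
             ordinal = ord_fix, congruent = congruent, artifact = FALSE,
             truncated = truncated))
    t <- t + d
    pos <- tgt
    if (t >= trial_ms) break
  }
  # extend the final fixation to fill any residual time
  last <- ev[[length(ev)]]
  if (t < trial_ms && last$type == "fixation") {
    last$dur <- last$dur + (trial_ms - t)
    last$truncated <- TRUE
    ev[[length(ev)]] <- last
  }

  # blinks: placed inside sufficiently long fixations
  n_blink <- stats::rpois(1, params$blink_rate)
  blinks <- list()
  if (n_blink > 0) {
    fid <- which(vapply(ev, function(e) e$type == "fixation" && e$dur > 260,
                        logical(1)))
    for (b in seq_len(min(n_blink, length(fid)))) {
      i <- if (length(fid) == 1) fid else sample(fid, 1)
      fid <- setdiff(fid, i)
      e <- ev[[i]]
      bd <- round(stats::runif(1, 60, 140))
      on <- e$onset + round(stats::runif(1, 50, e$dur - bd - 50))
      blinks[[length(blinks) + 1L]] <- list(type = "blink", onset = on,
                                            dur = bd)
    }
  }

  all_ev <- c(ev, blinks)
  num <- function(field) vapply(all_ev, function(e) {
    v <- e[[field]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  lgl <- function(field) vapply(all_ev, function(e) isTRUE(e[[field]]),
                                logical(1))
  type <- vapply(all_ev, function(e) {
    if (isTRUE(e$artifact)) "artifact_saccade" else e$type
  }, character(1))
  onset <- num("onset"); dur <- num("dur")
  data.frame(type = type, onset_ms = onset, offset_ms = onset + dur,
             duration_ms = dur, x_px = num("x"), y_px = num("y"),
             start_x_px = num("x0"), start_y_px = num("y0"),
             amplitude_deg = num("amplitude"),
             ordinal = as.integer(num("ordinal")),
             congruent = lgl("congruent"), truncated = lgl("truncated"))
}

# minimum-jerk displacement profile on n samples (0 -> 1)
.minjerk <- function(n) {
  tau <- seq_len(n) / n
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# render one trial's truth events into a 1 kHz sample stream
.render_trial <- function(truth, params, geom, trial_ms) {
  ppd <- px_per_degree(geom)
  n <- trial_ms
  x <- numeric(n); y <- numeric(n); valid <- rep(TRUE, n)
  step_sd <- params$jitter_step_sd_deg * ppd
  evs <- truth[truth$type != "blink", , drop = FALSE]
  for (i in seq_len(nrow(evs))) {
    e <- evs[i, ]
    i0 <- e$onset_ms + 1L
    i1 <- min(e$offset_ms, n)
    len <- i1 - i0 + 1L
    if (len <= 0) next
    if (e$type == "fixation") {
      dx <- cumsum(stats::rnorm(len, 0, step_sd))
      dy <- cumsum(stats::rnorm(len, 0, step_sd))
      x[i0:i1] <- e$x_px + dx - dx[1]
      y[i0:i1] <- e$y_px + dy - dy[1]
    } else if (e$type == "saccade") {
      s <- .minjerk(len)
      x[i0:i1] <- e$start_x_px + s * (e$x_px - e$start_x_px)
      y[i0:i1] <- e$start_y_px + s * (e$y_px - e$start_y_px)
    } else {  # artifact_saccade: curved (hook) quadratic Bezier trajectory
      p0 <- c(e$start_x_px, e$start_y_px)
      p1 <- c(e$x_px, e$y_px)
      chord <- p1 - p0
      perp <- c(-chord[2], chord[1])
      pn <- sqrt(sum(perp^2))
      perp <- if (pn > 0) perp / pn else c(0, 1)
      ctrl <- (p0 + p1) / 2 + perp * 3.8 * sqrt(sum(chord^2))
      s <- .minjerk(len)
      x[i0:i1] <- (1 - s)^2 * p0[1] + 2 * (1 - s) * s * ctrl[1] + s^2 * p1[1]
      y[i0:i1] <- (1 - s)^2 * p0[2] + 2 * (1 - s) * s * ctrl[2] + s^2 * p1[2]
    }
  }
  bl <- truth[truth$type == "blink", , drop = FALSE]
  for (i in seq_len(nrow(bl))) {
    i0 <- bl$onset_ms[i] + 1L
    i1 <- min(bl$offset_ms[i], n)
    valid[i0:i1] <- FALSE
    x[i0:i1] <- NA_real_
    y[i0:i1] <- NA_real_
  }
  data.frame(t_ms = 0:(n - 1), x_px = x, y_px = y, valid = valid)
}

# balanced image-set / task assignment: image sets by index mod 3, subjects
# rotate the set -> task mapping, so each image is seen under each task
# equally often across the cohort and no subject sees an image twice.
.assign_tasks <- function(design, subject_index) {
  sets <- (seq_len(design$n_images) - 1L) %% 3L
  rot <- (subject_index - 1L) %% 3L
  design$tasks[((sets + rot) %% 3L) + 1L]
}

#' Generate a complete synthetic gaze study
#'
#' Produces trial metadata with behavioural responses, ground-truth event
#' tables per trial and (optionally) rendered 1 kHz sample streams. The
#' global seed is expanded into per-trial substreams by a counter-based
#' scheme, so regenerating with the same seed is bit-exact and subsets
#' regenerate independently.
#'
#' @param design a [study_design()].
#' @param params a [generative_params()].
#' @param seed integer master seed.
#' @param render if `TRUE`, render sample streams (slow for full-size
#'   studies); if `FALSE`, only ground-truth events are produced.
#' @param geom a [screen_geometry()].
#' @param frame an [image_frame()].
#' @return list with `trials` (metadata data frame), `events` (ground-truth
#'   event table over all trials), `samples` (named list of per-trial
#'   sample data frames, or `NULL`), `rois`, `random_effects` (the realized
#'   subject/image intercepts, part of the ground truth), `design`,
#'   `params`, `seed`.
#' @export
generate_study <- function(design = study_design(),
                           params = generative_params(),
                           seed = 1, render = TRUE,
                           geom = screen_geometry(),
                           frame = image_frame(geom = geom)) {
  n_sub <- design$n_experts + design$n_nonexperts
  groups <- c(rep("expert", design$n_experts),
              rep("nonexpert", design$n_nonexperts))
  rois <- lapply(seq_len(design$n_images), function(i) {
    .image_rois(seed, i, params$n_rois, frame)
  })
  # subject- and image-level random intercepts (nuisance variability the
  # mixed models are meant to absorb)
  set.seed(.substream_seed(seed, 650001))
  re <- list(
    sub_amp = stats::rnorm(n_sub, 0, params$subject_amp_sd),
    sub_dur = stats::rnorm(n_sub, 0, params$subject_dur_sd),
    img_amp = stats::rnorm(design$n_images, 0, params$image_amp_sd),
    img_dur = stats::rnorm(design$n_images, 0, params$image_dur_sd))
  trials <- list()
  events <- list()
  samples <- if (render) list() else NULL
  counter <- 0L
  for (s in seq_len(n_sub)) {
    task_of_image <- .assign_tasks(design, s)
    grp <- groups[s]
    for (img in seq_len(design$n_images)) {
      counter <- counter + 1L
      task <- task_of_image[img]
      set.seed(.substream_seed(seed, counter))
      truth <- .simulate_scanpath(
        rois[[img]], task, grp, params, frame, geom, design$trial_ms,
        amp_off = re$sub_amp[s] + re$img_amp[img],
        dur_off = re$sub_dur[s] + re$img_dur[img])
      trial_id <- sprintf("s%02d_i%02d", s, img)
      truth$trial_id <- trial_id

      p_corr <- params$accuracy[[grp]][[task]]
      correct <- stats::runif(1) < p_corr
      fam_rev <- min(max(round(stats::rnorm(
        1, params$familiarity_mean[[grp]], 1.2)), 1), 6)
      conf_mu <- params$confidence_mean[[grp]][[task]]
      conf_rev <- min(max(round(
        conf_mu + 0.45 * (correct - p_corr) +
          0.30 * (fam_rev - params$familiarity_mean[[grp]]) +
          stats::rnorm(1, 0, 1.0)), 1), 6)
      trials[[counter]] <- data.frame(
        trial_id = trial_id, subject_id = sprintf("s%02d", s), group = grp,
        image_id = sprintf("i%02d", img), task = task,
        presentation_ms = design$trial_ms,
        answer = sample(LETTERS[1:6], 1), correct = correct,
        confidence_raw = 7 - conf_rev, familiarity_raw = 7 - fam_rev)
      events[[counter]] <- truth
      if (render) {
        samples[[trial_id]] <- .render_trial(truth, params, geom,
                                             design$trial_ms)
      }
    }
  }
  names(re$sub_amp) <- names(re$sub_dur) <- sprintf("s%02d", seq_len(n_sub))
  names(re$img_amp) <- names(re$img_dur) <-
    sprintf("i%02d", seq_len(design$n_images))
  list(trials = do.call(rbind, trials),
       events = do.call(rbind, events),
       samples = samples, rois = rois, random_effects = re,
       design = design, params = params, seed = seed)
}

#' Inject blinks and hook-shaped artifact saccades into a sample stream
#'
#' Used to exercise the exclusion rules on existing trials: blinks become
#' runs of invalid samples; artifacts replace a short mid-fixation window
#' with a strongly curved out-and-back excursion whose path length exceeds
#' 3.5 times its amplitude, shifting all subsequent samples by the small
#' net displacement to preserve continuity.
#'
#' @param samples per-trial sample data frame.
#' @param artifact_rate,blink_rate expected counts per trial (Poisson).
#' @param seed integer seed.
#' @param geom a [screen_geometry()].
#' @return list with `samples`, `n_blinks`, `n_artifacts`.
#' @export
inject_artifacts <- function(samples, artifact_rate, blink_rate, seed = 1,
                             geom = screen_geometry()) {
  if (artifact_rate < 0 || blink_rate < 0) stop("rates must be >= 0")
  set.seed(.substream_seed(seed, 424243))
  n <- nrow(samples)
  ppd <- px_per_degree(geom)
  n_art <- stats::rpois(1, artifact_rate)
  n_blink <- stats::rpois(1, blink_rate)
  if (n_art == 0 && n_blink == 0) {
    return(list(samples = samples, n_blinks = 0L, n_artifacts = 0L))
  }
  # stable windows: low positional range over 240 ms
  is_stable <- function(i0, len) {
    idx <- i0:(i0 + len - 1)
    if (any(!samples$valid[idx])) return(FALSE)
    (max(samples$x_px[idx]) - min(samples$x_px[idx]) < 0.8 * ppd) &&
      (max(samples$y_px[idx]) - min(samples$y_px[idx]) < 0.8 * ppd)
  }
  placed_a <- 0L
  for (k in seq_len(n_art)) {
    for (try in 1:50) {
      i0 <- sample.int(n - 300, 1) + 20L
      if (!is_stable(i0, 240)) next
      amp_px <- 1.2 * ppd
      dur <- round(2.2 * 4 * 1.2 + 21)
      j0 <- i0 + 60L
      j1 <- j0 + dur - 1L
      p0 <- c(samples$x_px[j0 - 1], samples$y_px[j0 - 1])
      th <- stats::runif(1, 0, 2 * pi)
      p1 <- p0 + amp_px * c(cos(th), sin(th))
      chord <- p1 - p0
      perp <- c(-chord[2], chord[1]) / sqrt(sum(chord^2))
      ctrl <- (p0 + p1) / 2 + perp * 3.8 * sqrt(sum(chord^2))
      s <- .minjerk(dur)
      samples$x_px[j0:j1] <- (1 - s)^2 * p0[1] + 2 * (1 - s) * s * ctrl[1] +
        s^2 * p1[1]
      samples$y_px[j0:j1] <- (1 - s)^2 * p0[2] + 2 * (1 - s) * s * ctrl[2] +
        s^2 * p1[2]
      if (j1 < n) {
        sel <- (j1 + 1):n
        samples$x_px[sel] <- samples$x_px[sel] + (p1[1] - p0[1])
        samples$y_px[sel] <- samples$y_px[sel] + (p1[2] - p0[2])
      }
      placed_a <- placed_a + 1L
      break
    }
  }
  placed_b <- 0L
  for (k in seq_len(n_blink)) {
    i0 <- sample.int(n - 200, 1) + 50L
    idx <- i0:(i0 + round(stats::runif(1, 60, 140)))
    idx <- idx[idx <= n]
    samples$valid[idx] <- FALSE
    samples$x_px[idx] <- NA_real_
    samples$y_px[idx] <- NA_real_
    placed_b <- placed_b + 1L
  }
  list(samples = samples, n_blinks = placed_b, n_artifacts = placed_a)
}
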
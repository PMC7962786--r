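# End-to-end orchestration: samples -> events -> filters -> metrics ->
# statistics -> report, with a manifest recording configuration, seed and
# per-stage record counts.

#' Detect and filter events for a set of trials
#'
#' Runs blink/saccade/fixation detection on every trial, applies the
#' off-image / blink-adjacency fixation filter and the trajectory-ratio
#' saccade filter, and returns tidy event tables.
#'
#' @param samples named list of per-trial sample data frames.
#' @param det [detection_params()].
#' @param filt [filter_params()], or `NULL` to disable the saccade ratio
#'   filter.
#' @param geom [screen_geometry()].
#' @param frame [image_frame()].
#' @return list with `fixations` (kept), `saccades` (kept),
#'   `removed_fixations`, `excluded_saccades`, `blinks`; all carry a
#'   `trial_id` column. The final fixation of each trial is flagged
#'   `trial_final` (its duration is cut by stimulus offset).
#' @export
process_trials <- function(samples, det = detection_params(),
                           filt = filter_params(),
                           geom = screen_geometry(),
                           frame = image_frame(geom = geom)) {
  fx <- list(); sc <- list(); rf <- list(); es <- list(); bl <- list()
  for (id in names(samples)) {
    evs <- detect_events(samples[[id]], det, geom, frame)
    f <- evs$fixations
    if (nrow(f)) {
      f$trial_final <- seq_len(nrow(f)) == nrow(f)
      f$trial_id <- id
    }
    s <- evs$saccades
    if (nrow(s)) s$trial_id <- id
    b <- evs$blinks
    if (nrow(b)) b$trial_id <- id
    ff <- filter_fixations(f, frame)
    if (!is.null(filt)) {
      sf <- filter_saccade_artifacts(s, filt)
    } else {
      sf <- list(kept = s, excluded = s[0, , drop = FALSE])
    }
    fx[[id]] <- ff$kept; rf[[id]] <- ff$removed
    sc[[id]] <- sf$kept; es[[id]] <- sf$excluded
    bl[[id]] <- b
  }
  bind <- function(l) {
    l <- Filter(function(d) !is.null(d) && nrow(d) > 0, l)
    if (!length(l)) return(NULL)
    out <- do.call(rbind, l)
    rownames(out) <- NULL
    out
  }
  list(fixations = bind(fx), saccades = bind(sc),
       removed_fixations = bind(rf), excluded_saccades = bind(es),
       blinks = bind(bl))
}

#' Per-trial NSS and dispersion metric table
#'
#' Computes leave-one-out NSS per observer within every image x task cell
#' (the pool ignores expertise group) and the per-trial dispersion score,
#' returning the table that feeds the statistics stage.
#'
#' @param fixations kept fixation table with `trial_id` column.
#' @param trials trial metadata (`trial_id,subject_id,group,image_id,task`).
#' @param kernel [kernel_spec()].
#' @param frame,geom geometry.
#' @param aggregate NSS aggregation, `"mean"` (default) or `"sum"`.
#' @param grid_step pixel stride of the map grid (use > 1 for speed on
#'   full-resolution images; NSS and dispersion are ratio statistics and
#'   are nearly invariant to the stride).
#' @return data frame `subject_id,image_id,task,group,nss,dispersion,
#'   n_fixations`.
#' @export
compute_metrics <- function(fixations, trials, kernel = kernel_spec(),
                            frame = image_frame(), geom = screen_geometry(),
                            aggregate = "mean", grid_step = 1L) {
  f <- merge(fixations, trials[c("trial_id", "subject_id", "group",
                                 "image_id", "task")], by = "trial_id")
  rows <- list()
  for (cell in split(f, list(f$image_id, f$task), drop = TRUE)) {
    obs <- unique(cell$subject_id)
    nss <- if (length(obs) >= 2) {
      d <- data.frame(observer = cell$subject_id,
                      x_px = cell$centroid_x_px, y_px = cell$centroid_y_px)
      nss_loo(d, kernel, frame, geom, aggregate = aggregate,
              grid_step = grid_step)
    } else NULL
    for (o in obs) {
      co <- cell[cell$subject_id == o, ]
      disp <- dispersion(co$centroid_x_px, co$centroid_y_px, kernel, frame,
                         geom, grid_step = grid_step)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = o, image_id = co$image_id[1], task = co$task[1],
        group = co$group[1],
        nss = if (is.null(nss)) NA_real_ else nss$nss[nss$observer == o],
        dispersion = disp, n_fixations = nrow(co))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full statistical battery
#'
#' Reproduces the standard analysis set: four primary mixed models
#' (accuracy, confidence, log fixation duration, saccade amplitude; fixed
#' effects task + expertise without interaction, random intercepts for
#' subject and image, each effect tested by LRT), NSS/dispersion models
#' (fixed effect expertise or task, random intercept image),
#' repeated-measures correlation of confidence and familiarity, the
#' behavioural summary and the ordinal 2-13 temporal profiles.
#'
#' @param metrics table from [compute_metrics()].
#' @param trials trial metadata with `correct`, `confidence_raw`,
#'   `familiarity_raw` (raw, pre-reversal ratings).
#' @param fixations,saccades kept event tables with `trial_id`.
#' @param on_singular passed to [lrt_effect()].
#' @return list with `lrt` (data frame of tests), `rmcorr`, `behavior`,
#'   `profiles`.
#' @export
compute_stats <- function(metrics, trials, fixations, saccades,
                          on_singular = "warn") {
  tr <- trials
  tr$confidence <- reverse_rating(tr$confidence_raw)
  tr$familiarity <- reverse_rating(tr$familiarity_raw)
  tr$correct <- as.numeric(tr$correct)
  tr$subject <- tr$subject_id; tr$image <- tr$image_id
  tr$expertise <- tr$group

  key <- c("trial_id", "subject_id", "group", "image_id", "task")
  fx <- merge(fixations, tr[c(key, "correct")], by = "trial_id")
  fx$subject <- fx$subject_id; fx$image <- fx$image_id
  fx$expertise <- fx$group
  sc <- merge(saccades, tr[key], by = "trial_id")
  sc$subject <- sc$subject_id; sc$image <- sc$image_id
  sc$expertise <- sc$group
  metrics$subject <- metrics$subject_id
  metrics$image <- metrics$image_id
  metrics$expertise <- metrics$group

  run <- function(data, response, effect, log_response = FALSE,
                  fixed = c("task", "expertise"),
                  random = c("subject", "image")) {
    r <- tryCatch(
      suppressWarnings(lrt_effect(data, response, effect,
                                  fixed_effects = fixed,
                                  random_intercepts = random,
                                  log_response = log_response,
                                  on_singular = on_singular)),
      error = function(e) NULL)
    if (is.null(r)) {
      return(data.frame(response = response, effect = effect,
                        chi2 = NA_real_, df = NA_integer_, p = NA_real_))
    }
    data.frame(response = response, effect = effect, chi2 = r$chi2,
               df = r$df, p = r$p)
  }
  lrt <- rbind(
    run(tr, "correct", "task"), run(tr, "correct", "expertise"),
    run(tr, "confidence", "task"), run(tr, "confidence", "expertise"),
    run(fx, "duration_ms", "task", log_response = TRUE),
    run(fx, "duration_ms", "expertise", log_response = TRUE),
    run(sc, "amplitude_deg", "task"), run(sc, "amplitude_deg", "expertise"),
    run(metrics, "nss", "expertise", fixed = "expertise", random = "image"),
    run(metrics, "nss", "task", fixed = "task", random = "image"),
    run(metrics, "dispersion", "expertise", fixed = "expertise",
        random = "image"),
    run(metrics, "dispersion", "task", fixed = "task", random = "image"))

  rmc <- rmcorr(tr$subject_id, tr$familiarity, tr$confidence)
  behavior <- summarize_behavior(tr)
  profiles <- list(
    fixation_duration = ordinal_profile(fx, "duration_ms"),
    saccade_amplitude = ordinal_profile(sc, "amplitude_deg"))
  list(lrt = lrt, rmcorr = rmc, behavior = behavior, profiles = profiles)
}

#' Run the complete pipeline
#'
#' `config` is a named list with either `synthetic = TRUE` (plus optional
#' `design` / `params` overrides) or a `samples_csv` / `trials_csv` input
#' pair, together with optional `detection`, `filter`, `kernel`,
#' `aggregate`, `grid_step`, `seed` entries. Writes events, metrics, stats,
#' report and a manifest to `out_dir` when given.
#'
#' @param config run configuration list.
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @return list with `events`, `metrics`, `stats`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = list(synthetic = TRUE), out_dir = NULL) {
  geom <- do.call(screen_geometry, config$geometry %||% list())
  frame <- do.call(image_frame,
                   c(config$frame %||% list(), list(geom = geom)))
  det <- do.call(detection_params, config$detection %||% list())
  filt <- if (isFALSE(config$filter)) NULL else
    do.call(filter_params, config$filter %||% list(duration_units = "s"))
  kern <- do.call(kernel_spec, config$kernel %||% list())
  seed <- config$seed %||% 1L
  grid_step <- config$grid_step %||% 4L
  aggregate <- config$aggregate %||% "mean"

  if (isTRUE(config$synthetic)) {
    design <- do.call(study_design, config$design %||% list())
    params <- do.call(generative_params, config$params %||% list())
    study <- generate_study(design, params, seed = seed, render = TRUE,
                            geom = geom, frame = frame)
    samples <- study$samples
    trials <- study$trials
  } else {
    if (is.null(config$samples_csv) || is.null(config$trials_csv)) {
      stop("stage[input]: need samples_csv and trials_csv, or synthetic=TRUE")
    }
    samples <- read_samples(config$samples_csv, dialect = "csv")
    trials <- read_trials(config$trials_csv)
  }

  ev <- tryCatch(process_trials(samples, det, filt, geom, frame),
                 error = function(e) stop("stage[events]: ",
                                          conditionMessage(e)))
  if (is.null(ev$fixations)) stop("stage[events]: no fixations detected")
  metrics <- tryCatch(
    compute_metrics(ev$fixations, trials, kern, frame, geom,
                    aggregate = aggregate, grid_step = grid_step),
    error = function(e) stop("stage[metrics]: ", conditionMessage(e)))
  stats <- tryCatch(
    compute_stats(metrics, trials, ev$fixations, ev$saccades),
    error = function(e) stop("stage[stats]: ", conditionMessage(e)))

  n_excl <- if (is.null(ev$excluded_saccades)) 0L
            else nrow(ev$excluded_saccades)
  manifest <- list(
    package_version = as.character(utils::packageVersion("gazecraft")),
    seed = seed,
    config = config,
    counts = list(
      trials = nrow(trials),
      fixations_kept = nrow(ev$fixations),
      fixations_removed = if (is.null(ev$removed_fixations)) 0L
                          else nrow(ev$removed_fixations),
      saccades_kept = if (is.null(ev$saccades)) 0L else nrow(ev$saccades),
      saccades_excluded = n_excl,
      blinks = if (is.null(ev$blinks)) 0L else nrow(ev$blinks)))
  report <- make_report(list(metrics = metrics, stats = stats,
                             trials = trials, events = ev))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(ev$fixations, file.path(out_dir, "fixations.csv"),
                     row.names = FALSE)
    if (!is.null(ev$saccades)) {
      utils::write.csv(ev$saccades, file.path(out_dir, "saccades.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(stats$lrt, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(report, file.path(out_dir, "report.txt"))
  }
  list(events = ev, metrics = metrics, stats = stats, report = report,
       manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Human-readable group x task summary report
#'
#' Emits a text table of accuracy, confidence, fixation duration, saccade
#' amplitude, NSS and dispersion by group and task (means and SDs).
#' Missing metrics are marked absent rather than causing a failure.
#'
#' @param artifacts list with `metrics`, `stats`, `trials`, `events`.
#' @return character vector of report lines.
#' @export
make_report <- function(artifacts) {
  out <- c("gazecraft run summary", "=====================")
  tr <- artifacts$trials
  fmt <- function(m, s) sprintf("%.3f (%.3f)", m, s)
  cell_line <- function(name, d, col) {
    if (is.null(d) || !nrow(d)) {
      return(sprintf("%-22s: absent", name))
    }
    cells <- vapply(split(d, list(d$group, d$task), drop = TRUE),
                    function(x) fmt(mean(x[[col]], na.rm = TRUE),
                                    stats::sd(x[[col]], na.rm = TRUE)),
                    character(1))
    paste0(sprintf("%-22s: ", name),
           paste(names(cells), cells, sep = "=", collapse = "  "))
  }
  if (!is.null(tr) && all(c("correct", "confidence_raw") %in% names(tr))) {
    tr$correct <- as.numeric(tr$correct)
    tr$confidence <- reverse_rating(tr$confidence_raw)
    out <- c(out, cell_line("accuracy", tr, "correct"),
             cell_line("confidence", tr, "confidence"))
  } else {
    out <- c(out, "behavioral data        : absent")
  }
  ev <- artifacts$events
  me <- artifacts$metrics
  if (!is.null(ev$fixations) && !is.null(tr)) {
    fx <- merge(ev$fixations, tr[c("trial_id", "group", "task")],
                by = "trial_id")
    out <- c(out, cell_line("fixation duration ms", fx, "duration_ms"))
  }
  if (!is.null(ev$saccades) && !is.null(tr)) {
    sc <- merge(ev$saccades, tr[c("trial_id", "group", "task")],
                by = "trial_id")
    out <- c(out, cell_line("saccade amplitude deg", sc, "amplitude_deg"))
  }
  out <- c(out, cell_line("nss", me, "nss"),
           cell_line("dispersion", me, "dispersion"))
  out
}
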
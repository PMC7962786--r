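# Readers/writers for gaze samples, trial metadata and run configuration.
#
# Canonical sample dialect is plain CSV with columns
#   trial_id,t_ms,x_px,y_px,valid
# An ASC-like adapter accepts EyeLink-export-style whitespace lines
# ("<t> <x> <y>", missing coordinates as ".", trials introduced by
# "TRIALID <id>" lines). Readers never drop or reorder samples: malformed
# coordinates become valid = FALSE rows, unsorted timestamps are an error.

#' Read gaze samples
#'
#' @param path file to read.
#' @param dialect `"csv"` (canonical, columns `trial_id,t_ms,x_px,y_px,valid`)
#'   or `"asc"` (whitespace `t x y` lines with `.` for missing and
#'   `TRIALID <id>` separators).
#' @return A named list of per-trial data frames with columns
#'   `t_ms`, `x_px`, `y_px`, `valid`, time-sorted.
#' @export
read_samples <- function(path, dialect = c("csv", "asc")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("trial_id", "t_ms", "x_px", "y_px", "valid")
    if (!all(need %in% names(df))) {
      stop("samples CSV must have columns ", paste(need, collapse = ","))
    }
    df$trial_id <- as.character(df$trial_id)
    df$x_px <- suppressWarnings(as.numeric(df$x_px))
    df$y_px <- suppressWarnings(as.numeric(df$y_px))
    df$valid <- as.logical(df$valid) & is.finite(df$x_px) & is.finite(df$y_px)
    trials <- split(df[c("t_ms", "x_px", "y_px", "valid")], df$trial_id)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    id <- "trial_1"
    rows <- list()
    for (ln in lines) {
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      if (identical(tok[1], "TRIALID")) {
        id <- tok[2]
        next
      }
      if (grepl("^[A-Za-z]", tok[1])) next  # other message lines
      x <- suppressWarnings(as.numeric(tok[2]))
      y <- suppressWarnings(as.numeric(tok[3]))
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = id, t_ms = as.numeric(tok[1]),
        x_px = x, y_px = y,
        valid = is.finite(x) && is.finite(y))
    }
    if (!length(rows)) stop("no sample lines found in ASC-like file")
    df <- do.call(rbind, rows)
    trials <- split(df[c("t_ms", "x_px", "y_px", "valid")], df$trial_id)
  }
  lapply(trials, function(tr) {
    if (is.unsorted(tr$t_ms, strictly = TRUE)) {
      stop("timestamps must be strictly increasing within a trial")
    }
    rownames(tr) <- NULL
    tr
  })
}

#' Write gaze samples in the canonical CSV dialect
#'
#' Round-trips bit-exactly with [read_samples()] on the CSV dialect.
#'
#' @param trials named list of per-trial sample data frames.
#' @param path output file.
#' @export
write_samples <- function(trials, path) {
  stopifnot(is.list(trials), !is.null(names(trials)))
  out <- do.call(rbind, lapply(names(trials), function(id) {
    cbind(trial_id = id, trials[[id]][c("t_ms", "x_px", "y_px", "valid")])
  }))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read / write trial metadata
#'
#' Trials CSV columns: `trial_id,subject_id,group,image_id,task,
#' presentation_ms,answer,correct,confidence_raw,familiarity_raw`.
#'
#' @param path file path.
#' @return data frame of trial metadata.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (any(!df$confidence_raw %in% 1:6) || any(!df$familiarity_raw %in% 1:6)) {
    stop("confidence_raw and familiarity_raw must lie in 1..6")
  }
  df
}

#' @rdname read_trials
#' @param trials data frame as returned by [generate_study()]`$trials`.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
}

#' Downsample a 2000 Hz sample stream to 1000 Hz
#'
#' Decimates by averaging consecutive sample pairs (positions), keeping the
#' earlier timestamp of each pair; a pair is valid only if both members are
#' valid. An odd trailing sample is kept as-is with a warning.
#'
#' @param samples per-trial sample data frame (`t_ms,x_px,y_px,valid`).
#' @return downsampled data frame at half the input rate.
#' @export
downsample_2k_to_1k <- function(samples) {
  n <- nrow(samples)
  if (n < 2) return(samples)
  odd <- n %% 2L == 1L
  m <- n %/% 2L
  i1 <- seq(1L, by = 2L, length.out = m)
  i2 <- i1 + 1L
  out <- data.frame(
    t_ms = samples$t_ms[i1],
    x_px = (samples$x_px[i1] + samples$x_px[i2]) / 2,
    y_px = (samples$y_px[i1] + samples$y_px[i2]) / 2,
    valid = samples$valid[i1] & samples$valid[i2])
  out$valid[!is.finite(out$x_px) | !is.finite(out$y_px)] <- FALSE
  if (odd) {
    warning("odd trailing sample kept as-is")
    out <- rbind(out, samples[n, c("t_ms", "x_px", "y_px", "valid")])
  }
  rownames(out) <- NULL
  out
}

#' Read / write a run configuration
#'
#' Configurations are stored as JSON and hold the screen geometry, detection
#' and filter parameters, kernel specification and seed. Round-trips
#' losslessly.
#'
#' @param path file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' @rdname read_config
#' @param config named list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}
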
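# Gaussian fixation maps, leave-one-out Normalized Scanpath Saliency,
# spatial dispersion, duration-weighted heatmaps and difference maps.
#
# The computation grid is the image pixel rectangle (not the full screen):
# off-image fixations have been removed upstream, and the dispersion
# statistic divides by the number of image pixels. `grid_step` allows
# computing on every s-th pixel for speed; statistics that are ratios of
# map functionals (NSS, dispersion) are nearly invariant to this choice.

#' Gaussian kernel specification
#'
#' Each fixation is modelled as an isotropic Gaussian with a standard
#' deviation of 1.5 degrees of visual angle (converted to pixels through the
#' screen geometry). The kernel is truncated at `truncation_radius_sigmas`
#' standard deviations with no edge renormalization; at the default 4 sigma
#' the truncated mass is below 1e-4 of the kernel.
#'
#' @param sigma_deg kernel standard deviation in degrees (default 1.5).
#' @param truncation_radius_sigmas truncation radius in sigmas (default 4).
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(sigma_deg = 1.5, truncation_radius_sigmas = 4) {
  if (sigma_deg <= 0) stop("sigma_deg must be strictly positive")
  structure(list(sigma_deg = sigma_deg,
                 truncation_radius_sigmas = truncation_radius_sigmas),
            class = "kernel_spec")
}

.empty_grid <- function(frame, grid_step) {
  nx <- length(seq(0, frame$width_px - 1, by = grid_step))
  ny <- length(seq(0, frame$height_px - 1, by = grid_step))
  matrix(0, nrow = ny, ncol = nx)
}

#' Build a raw Gaussian fixation map
#'
#' Accumulates one truncated Gaussian kernel per fixation, weighted by
#' `weights` (all ones for an unweighted map), over the image pixel grid.
#' Kernels are scaled to unit continuous mass (`2*pi*sigma^2` per pixel
#' area), so the grid total approximates the total weight up to truncation
#' and edge clipping; no edge renormalization is applied.
#'
#' @param x_px,y_px fixation centroids in screen coordinates.
#' @param weights nonnegative weights, one per fixation (default all 1).
#' @param kernel a [kernel_spec()].
#' @param frame an [image_frame()].
#' @param geom a [screen_geometry()].
#' @param grid_step compute on every `grid_step`-th pixel (default 1).
#' @return object of class `fixation_map` with fields `grid` (matrix,
#'   rows = y), `frame`, `px_per_deg`, `grid_step`, `normalization`.
#' @export
build_fixation_map <- function(x_px, y_px, weights = NULL,
                               kernel = kernel_spec(),
                               frame = image_frame(),
                               geom = screen_geometry(),
                               grid_step = 1L) {
  n <- length(x_px)
  if (n == 0) stop("cannot build a fixation map from zero fixations")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), length(y_px) == n)
  ppd <- px_per_degree(geom)
  sigma <- kernel$sigma_deg * ppd
  r <- kernel$truncation_radius_sigmas * sigma
  xs <- seq(0, frame$width_px - 1, by = grid_step)
  ys <- seq(0, frame$height_px - 1, by = grid_step)
  grid <- matrix(0, nrow = length(ys), ncol = length(xs))
  norm <- 2 * pi * sigma^2 / grid_step^2   # unit continuous mass per kernel
  fx <- x_px - frame$origin_x_px
  fy <- y_px - frame$origin_y_px
  for (i in seq_len(n)) {
    jx <- which(xs >= fx[i] - r & xs <= fx[i] + r)
    jy <- which(ys >= fy[i] - r & ys <= fy[i] + r)
    if (!length(jx) || !length(jy)) next
    gx <- exp(-(xs[jx] - fx[i])^2 / (2 * sigma^2))
    gy <- exp(-(ys[jy] - fy[i])^2 / (2 * sigma^2))
    grid[jy, jx] <- grid[jy, jx] + (weights[i] / norm) * outer(gy, gx)
  }
  structure(list(grid = grid, frame = frame, px_per_deg = ppd,
                 grid_step = grid_step, normalization = "raw"),
            class = "fixation_map")
}

#' Normalize a fixation map
#'
#' * `zscore`: mean 0 and unit variance over image pixels (population
#'   variance), the normalization used before reading off NSS values.
#' * `max1`: maximum exactly 1 (the dispersion convention).
#' * `mass1`: grid sums exactly to 1 (density-map convention).
#'
#' @param map a `fixation_map`.
#' @param normalization one of `"zscore"`, `"max1"`, `"mass1"`.
#' @return the normalized `fixation_map`.
#' @export
normalize_map <- function(map, normalization = c("zscore", "max1", "mass1")) {
  normalization <- match.arg(normalization)
  g <- map$grid
  if (normalization == "zscore") {
    mu <- mean(g)
    sd <- sqrt(mean((g - mu)^2))
    if (sd == 0) stop("cannot z-score a constant map")
    map$grid <- (g - mu) / sd
  } else if (normalization == "max1") {
    mx <- max(g)
    if (mx <= 0) stop("cannot max-normalize an empty map")
    map$grid <- g / mx
  } else {
    s <- sum(g)
    if (s <= 0) stop("cannot mass-normalize an empty map")
    map$grid <- g / s
  }
  map$normalization <- normalization
  map
}

#' Read map values at screen positions (nearest-pixel lookup)
#'
#' @param map a `fixation_map`.
#' @param x_px,y_px screen coordinates.
#' @return numeric vector of grid values.
#' @export
map_value_at <- function(map, x_px, y_px) {
  fx <- x_px - map$frame$origin_x_px
  fy <- y_px - map$frame$origin_y_px
  jx <- pmin(pmax(round(fx / map$grid_step), 0), ncol(map$grid) - 1) + 1L
  jy <- pmin(pmax(round(fy / map$grid_step), 0), nrow(map$grid) - 1) + 1L
  map$grid[cbind(jy, jx)]
}

#' Leave-one-out Normalized Scanpath Saliency
#'
#' For each observer, the fixations of all other observers of the same
#' image under the same task are accumulated into a Gaussian fixation map,
#' which is z-normalized over image pixels (mean zero, unit variance). The
#' map values at the left-out observer's fixation locations are then read
#' off (nearest pixel) and aggregated. Positive NSS indicates congruent
#' fixation locations, values near zero uncorrelated ones, negative NSS
#' incoherent locations.
#'
#' The leave-one-out pool is everyone viewing the same image under the same
#' task, regardless of expertise group; group labels only annotate records.
#'
#' @param fixations data frame with columns `observer`, `x_px`, `y_px`
#'   (kept fixations of all observers of one image x task cell).
#' @param kernel a [kernel_spec()].
#' @param frame an [image_frame()].
#' @param geom a [screen_geometry()].
#' @param aggregate `"mean"` (default, the standard NSS definition:
#'   average over the left-out fixations) or `"sum"` (literal summation).
#' @param grid_step pixel stride of the computation grid.
#' @return data frame with one row per observer: `observer`, `nss`,
#'   `n_fixations_used`, `defined` (FALSE when the observer has no kept
#'   fixations or the leave-one-out map is constant).
#' @export
nss_loo <- function(fixations, kernel = kernel_spec(),
                    frame = image_frame(), geom = screen_geometry(),
                    aggregate = c("mean", "sum"), grid_step = 1L) {
  aggregate <- match.arg(aggregate)
  obs <- unique(fixations$observer)
  if (length(obs) < 2) stop("leave-one-out NSS needs at least 2 observers")
  per_obs <- lapply(obs, function(o) {
    f <- fixations[fixations$observer == o, , drop = FALSE]
    if (!nrow(f)) return(NULL)
    build_fixation_map(f$x_px, f$y_px, kernel = kernel, frame = frame,
                       geom = geom, grid_step = grid_step)
  })
  names(per_obs) <- as.character(obs)
  grids <- Filter(Negate(is.null), per_obs)
  if (length(grids) < 2) stop("need at least 2 observers with kept fixations")
  total <- Reduce(`+`, lapply(grids, `[[`, "grid"))
  template <- grids[[1]]
  rows <- lapply(obs, function(o) {
    f <- fixations[fixations$observer == o, , drop = FALSE]
    own <- per_obs[[as.character(o)]]
    loo <- if (is.null(own)) total else total - own$grid
    mu <- mean(loo)
    sd <- sqrt(mean((loo - mu)^2))
    if (nrow(f) == 0 || sd == 0) {
      return(data.frame(observer = o, nss = NA_real_,
                        n_fixations_used = nrow(f), defined = FALSE))
    }
    zmap <- template
    zmap$grid <- (loo - mu) / sd
    zmap$normalization <- "zscore"
    vals <- map_value_at(zmap, f$x_px, f$y_px)
    data.frame(observer = o,
               nss = if (aggregate == "mean") mean(vals) else sum(vals),
               n_fixations_used = nrow(f), defined = TRUE)
  })
  do.call(rbind, rows)
}

#' Spatial dispersion of a fixation set
#'
#' All fixation Gaussians of a trial are summed, the map is normalized to a
#' maximum of 1, and the values are divided by the number of pixels, giving
#' a score in (0, 1]: small when fixations pile up in one spot, larger when
#' they cover more of the image. Equivalently `mean(map) / max(map)`.
#'
#' @param x_px,y_px kept fixation centroids (screen coordinates).
#' @inheritParams nss_loo
#' @return dispersion score in (0, 1].
#' @export
dispersion <- function(x_px, y_px, kernel = kernel_spec(),
                       frame = image_frame(), geom = screen_geometry(),
                       grid_step = 1L) {
  if (length(x_px) == 0) stop("dispersion undefined for zero fixations")
  m <- build_fixation_map(x_px, y_px, kernel = kernel, frame = frame,
                          geom = geom, grid_step = grid_step)
  mean(m$grid) / max(m$grid)
}

#' Duration-weighted group fixation density map
#'
#' Accumulates all contributing fixations, each weighted by its duration,
#' and divides by the total fixation duration, yielding a density (heat)
#' map of where viewing time was spent. The result is mass-normalized so
#' the grid sums exactly to 1.
#'
#' @param x_px,y_px fixation centroids of all contributing trials.
#' @param duration_ms fixation durations used as weights.
#' @inheritParams nss_loo
#' @return a `fixation_map` with normalization `"mass1"`.
#' @export
group_heatmap <- function(x_px, y_px, duration_ms, kernel = kernel_spec(),
                          frame = image_frame(), geom = screen_geometry(),
                          grid_step = 1L) {
  if (length(x_px) == 0) stop("cannot build a heatmap from zero fixations")
  m <- build_fixation_map(x_px, y_px, weights = duration_ms,
                          kernel = kernel, frame = frame, geom = geom,
                          grid_step = grid_step)
  m$grid <- m$grid / sum(duration_ms)
  normalize_map(m, "mass1")
}

#' Signed difference of two density maps
#'
#' Elementwise `a - b` of two mass-normalized maps; the result sums to zero
#' (within floating-point error).
#'
#' @param map_a,map_b `fixation_map`s with normalization `"mass1"` and
#'   identical grid shapes.
#' @return a `fixation_map` with normalization `"difference"`.
#' @export
difference_map <- function(map_a, map_b) {
  if (!identical(dim(map_a$grid), dim(map_b$grid))) {
    stop("difference_map requires identical grid shapes")
  }
  if (map_a$normalization != "mass1" || map_b$normalization != "mass1") {
    stop("difference_map requires mass1-normalized maps")
  }
  out <- map_a
  out$grid <- map_a$grid - map_b$grid
  out$normalization <- "difference"
  out
}

#' Write / read a fixation map as a portable text grid
#'
#' The grid is written as a plain-text matrix next to a JSON sidecar
#' (`<path>.json`) recording shape, pixel scale and normalization state.
#'
#' @param map a `fixation_map`.
#' @param path output path for the grid values.
#' @export
write_map <- function(map, path) {
  utils::write.table(map$grid, path, row.names = FALSE, col.names = FALSE)
  meta <- list(nrow = nrow(map$grid), ncol = ncol(map$grid),
               px_per_deg = map$px_per_deg, grid_step = map$grid_step,
               normalization = map$normalization,
               frame = unclass(map$frame))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  grid <- as.matrix(utils::read.table(path))
  dimnames(grid) <- NULL
  structure(list(grid = grid, frame = structure(meta$frame,
                                                class = "image_frame"),
                 px_per_deg = meta$px_per_deg, grid_step = meta$grid_step,
                 normalization = meta$normalization),
            class = "fixation_map")
}
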
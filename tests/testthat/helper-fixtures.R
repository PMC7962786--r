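# Shared fixtures and independent oracles, built in code at test time.

# small geometry/frame pair used by most map tests: 10 px/deg on a
# 240 x 160 px image, cheap to evaluate densely
small_geom <- function() {
  # 10 px/deg at 60 cm: deg_per_px = 0.1 -> cm_per_px = 60*tan(0.1 deg)
  cmppx <- 60 * tan(0.1 * pi / 180)
  screen_geometry(width_px = 400, height_px = 300,
                  width_cm = 400 * cmppx, height_cm = 300 * cmppx,
                  viewing_distance_cm = 60)
}
small_frame <- function(geom = small_geom()) {
  image_frame(width_px = 240, height_px = 160, geom = geom)
}

# noiseless trial with min-jerk saccades between given fixation positions
# (px), fixed fixation duration; returns samples + the true event schedule
make_noiseless_trial <- function(targets_px, fix_ms = 250, sacc_ms = 40,
                                 t0 = 0) {
  minjerk <- function(n) {
    tau <- seq_len(n) / n
    10 * tau^3 - 15 * tau^4 + 6 * tau^5
  }
  x <- c(); y <- c(); truth <- list()
  pos <- targets_px[[1]]
  t <- t0
  x <- rep(pos[1], fix_ms); y <- rep(pos[2], fix_ms)
  truth[[1]] <- list(type = "fixation", onset = t, dur = fix_ms)
  t <- t + fix_ms
  for (i in seq_along(targets_px)[-1]) {
    tgt <- targets_px[[i]]
    s <- minjerk(sacc_ms)
    x <- c(x, pos[1] + s * (tgt[1] - pos[1]))
    y <- c(y, pos[2] + s * (tgt[2] - pos[2]))
    truth[[length(truth) + 1]] <- list(type = "saccade", onset = t,
                                       dur = sacc_ms)
    t <- t + sacc_ms
    x <- c(x, rep(tgt[1], fix_ms)); y <- c(y, rep(tgt[2], fix_ms))
    truth[[length(truth) + 1]] <- list(type = "fixation", onset = t,
                                       dur = fix_ms)
    t <- t + fix_ms
    pos <- tgt
  }
  list(samples = data.frame(t_ms = t0 + seq_along(x) - 1, x_px = x,
                            y_px = y, valid = TRUE),
       truth = truth)
}

# independent brute-force threshold scan: raw central differences on the
# unsmoothed signal, no run post-processing beyond the thresholds
brute_force_saccade_scan <- function(samples, geom,
                                     vthresh = 30, athresh = 8000) {
  ppd <- px_per_degree(geom)
  n <- nrow(samples)
  vx <- c(NA, (samples$x_px[3:n] - samples$x_px[1:(n - 2)]) / 2, NA)
  vy <- c(NA, (samples$y_px[3:n] - samples$y_px[1:(n - 2)]) / 2, NA)
  speed <- sqrt(vx^2 + vy^2) / ppd * 1000
  ax <- c(NA, (vx[3:n] - vx[1:(n - 2)]) / 2, NA)
  ay <- c(NA, (vy[3:n] - vy[1:(n - 2)]) / 2, NA)
  acc <- sqrt(ax^2 + ay^2) / ppd * 1e6
  flag <- (speed > vthresh) | (acc > athresh)
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  data.frame(onset_ms = samples$t_ms[starts[r$values]],
             offset_ms = samples$t_ms[ends[r$values]] + 1)
}

# dense brute-force Gaussian sum on a small frame (the map oracle)
dense_gaussian_sum <- function(x_px, y_px, weights, sigma_px, frame) {
  xs <- seq(0, frame$width_px - 1)
  ys <- seq(0, frame$height_px - 1)
  g <- matrix(0, length(ys), length(xs))
  for (i in seq_along(x_px)) {
    dx2 <- outer(rep(1, length(ys)), (xs - (x_px[i] - frame$origin_x_px))^2)
    dy2 <- outer((ys - (y_px[i] - frame$origin_y_px))^2, rep(1, length(xs)))
    g <- g + weights[i] * exp(-(dx2 + dy2) / (2 * sigma_px^2))
  }
  g
}
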
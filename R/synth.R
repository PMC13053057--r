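#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter group_by summarise ungroup arrange
#'   select left_join bind_rows n transmute
NULL

# ---- cell placement -------------------------------------------------------

# Rejection-sample non-overlapping disc centres. Coordinates are 0-based
# pixel indices with pixel centres at integers; discs are kept fully inside
# the field so the detector sees complete cells.
place_cancer_cells <- function(cfg) {
  nr <- cfg$field_size_px[1L]; nc <- cfg$field_size_px[2L]
  n <- cfg$n_cancer
  radius_px <- pmax(3, rnorm(n, cfg$cancer_radius_um[1L], cfg$cancer_radius_um[2L]) /
                      cfg$pixel_size_um)
  if (sum(pi * (radius_px + 2)^2) > 0.5 * nr * nc)
    abort("field too small for the requested number of cancer cells")
  rows <- numeric(n); cols <- numeric(n)
  max_attempts <- 200L * n
  attempts <- 0L
  placed <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      abort(sprintf("cell placement failed after %d rejection-sampling attempts", max_attempts))
    r <- radius_px[placed + 1L]
    cand_r <- runif(1, r + 4, nr - 1 - r - 4)
    cand_c <- runif(1, r + 4, nc - 1 - r - 4)
    if (placed > 0L) {
      i <- seq_len(placed)
      d2 <- (rows[i] - cand_r)^2 + (cols[i] - cand_c)^2
      # the smoothed disc edge thresholds ~2-3 px beyond the nominal radius;
      # an 8 px gap keeps neighbouring masks 8-disconnected
      if (any(d2 < (radius_px[i] + r + 8)^2)) next
    }
    placed <- placed + 1L
    rows[placed] <- cand_r; cols[placed] <- cand_c
  }
  tibble(id = seq_len(n), row = rows, col = cols, radius_px = radius_px)
}

# ---- CAF motion -----------------------------------------------------------

#' Simulate CAF trajectories as a persistent random walk
#'
#' Each CAF is an elongated capsule whose centroid performs a fixed-step
#' persistent random walk (Gaussian turning angles) at the transmission frame
#' cadence, with reflective boundary handling; the capsule is aligned with the
#' current heading. For lag times long against the persistence time the mean
#' squared displacement grows linearly with effective diffusion coefficient
#' `D = step^2 (1 + c) / (4 dt (1 - c))`, `c = exp(-turn_sd^2 / 2)`.
#'
#' @param config A [sim_config()] (or list coercible to one).
#' @param n_frames Number of transmission frames to simulate; defaults to the
#'   full acquisition span.
#' @return A tibble with one row per (frame, CAF): `frame` (1-based), `t_h`,
#'   `caf`, `x_um`, `y_um` (centroid, 0-based physical coordinates), `theta`
#'   (heading, radians).
#' @export
simulate_caf_motion <- function(config, n_frames = NULL) {
  cfg <- validate_sim_config(config)
  dt_h <- cfg$dt_trans_min / 60
  nf <- n_frames %||% (floor(cfg$duration_h / dt_h) + 1L)
  n <- cfg$n_caf
  fw <- (cfg$field_size_px - 1L) * cfg$pixel_size_um  # physical field extent
  x <- runif(n, 0, fw[2L]); y <- runif(n, 0, fw[1L])
  th <- runif(n, 0, 2 * pi)
  out_x <- matrix(0, nf, n); out_y <- matrix(0, nf, n); out_th <- matrix(0, nf, n)
  for (f in seq_len(nf)) {
    out_x[f, ] <- x; out_y[f, ] <- y; out_th[f, ] <- th
    th <- th + rnorm(n, 0, cfg$caf_turn_sd)
    x <- x + cfg$caf_step_um * cos(th)
    y <- y + cfg$caf_step_um * sin(th)
    # reflective boundaries
    ref_x <- x < 0 | x > fw[2L]
    x[x < 0] <- -x[x < 0]; x[x > fw[2L]] <- 2 * fw[2L] - x[x > fw[2L]]
    th[ref_x] <- pi - th[ref_x]
    ref_y <- y < 0 | y > fw[1L]
    y[y < 0] <- -y[y < 0]; y[y > fw[1L]] <- 2 * fw[1L] - y[y > fw[1L]]
    th[ref_y] <- -th[ref_y]
  }
  tibble(
    frame = rep(seq_len(nf), each = n),
    t_h = rep((seq_len(nf) - 1L) * dt_h, each = n),
    caf = rep(seq_len(n), nf),
    x_um = as.vector(t(out_x)),
    y_um = as.vector(t(out_y)),
    theta = as.vector(t(out_th))
  )
}

# Distance from points to a capsule (segment of half-length `half` dilated by
# `w2`), all in physical units. Vectorised over points.
point_capsule_dist <- function(px, py, cx, cy, theta, half, w2) {
  ax <- cx - half * cos(theta); ay <- cy - half * sin(theta)
  vx <- 2 * half * cos(theta);  vy <- 2 * half * sin(theta)
  L2 <- vx * vx + vy * vy
  t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
  pmax(0, sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2) - w2)
}

# Analytic per-(cell, frame) minimum centroid-to-CAF-surface distance (um).
true_min_distances <- function(cells, traj, cfg) {
  half <- pmax(0, (cfg$caf_length_um - cfg$caf_width_um) / 2)
  w2 <- cfg$caf_width_um / 2
  px <- cells$col * cfg$pixel_size_um   # x = col, y = row
  py <- cells$row * cfg$pixel_size_um
  frames <- sort(unique(traj$frame))
  res <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    tf <- traj[traj$frame == frames[k], ]
    dmin <- rep(Inf, length(px))
    for (j in seq_len(nrow(tf)))
      dmin <- pmin(dmin, point_capsule_dist(px, py, tf$x_um[j], tf$y_um[j],
                                            tf$theta[j], half, w2))
    res[[k]] <- tibble(id = cells$id, frame = frames[k], t_h = tf$t_h[1L],
                       min_dist_um = dmin)
  }
  bind_rows(res)
}

# ---- apoptosis times ------------------------------------------------------

#' Sample per-cell apoptosis times under a proximity-modified hazard
#'
#' Cells whose early-window minimum CAF distance falls below `d_prox_um`
#' draw an exponential event time with rate `lambda0_per_h * rho`; all other
#' cells use rate `lambda0_per_h`. Times beyond `duration_h` are recorded as
#' `Inf` (alive at the end of the video).
#'
#' @param min_dist_early_um Per-cell minimum CAF distance over the early
#'   window, in micrometres (`Inf` when no CAF exists). Either a numeric
#'   vector or a tibble with columns `id`, `min_dist_um` (e.g. the output of
#'   [simulate_caf_motion()] distances filtered to the window), in which case
#'   the per-id minimum is taken.
#' @param lambda0_per_h Baseline hazard per hour, `>= 0`.
#' @param rho Hazard multiplier for proximal cells, `> 0`.
#' @param d_prox_um Distance threshold defining proximity.
#' @param duration_h Acquisition span.
#' @return Numeric vector of event times in hours (`Inf` = no event).
#' @export
sample_apoptosis_times <- function(min_dist_early_um, lambda0_per_h, rho = 1,
                                   d_prox_um = 50, duration_h = 72) {
  if (is.data.frame(min_dist_early_um)) {
    agg <- tapply(min_dist_early_um$min_dist_um, min_dist_early_um$id, min)
    min_dist_early_um <- as.numeric(agg[order(as.numeric(names(agg)))])
  }
  if (lambda0_per_h < 0) abort("lambda0_per_h must be >= 0")
  if (rho <= 0) abort("rho must be > 0")
  n <- length(min_dist_early_um)
  rate <- ifelse(min_dist_early_um < d_prox_um, lambda0_per_h * rho, lambda0_per_h)
  t <- ifelse(rate > 0, rexp(n, pmax(rate, .Machine$double.xmin)), Inf)
  # rexp is vectorised over rate, but a zero rate must give Inf exactly
  t[rate == 0] <- Inf
  t[t > duration_h] <- Inf
  t
}

# ---- rasterisation --------------------------------------------------------

# Rasterise CAF capsules for the given frames into a logical stack.
# A pixel belongs to a CAF iff its centre lies within the capsule.
rasterize_caf_masks <- function(traj, cfg, frames = NULL) {
  nr <- cfg$field_size_px[1L]; nc <- cfg$field_size_px[2L]
  ps <- cfg$pixel_size_um
  half <- pmax(0, (cfg$caf_length_um - cfg$caf_width_um) / 2)
  w2 <- cfg$caf_width_um / 2
  frames <- frames %||% sort(unique(traj$frame))
  masks <- array(FALSE, c(nr, nc, length(frames)))
  pad <- ceiling((half + w2) / ps) + 1L
  for (k in seq_along(frames)) {
    tf <- traj[traj$frame == frames[k], ]
    m <- matrix(FALSE, nr, nc)
    for (j in seq_len(nrow(tf))) {
      c_col <- tf$x_um[j] / ps; c_row <- tf$y_um[j] / ps
      r0 <- max(0L, floor(c_row) - pad); r1 <- min(nr - 1L, ceiling(c_row) + pad)
      c0 <- max(0L, floor(c_col) - pad); c1 <- min(nc - 1L, ceiling(c_col) + pad)
      if (r1 < r0 || c1 < c0) next
      rr <- r0:r1; cc <- c0:c1
      py <- rep(rr, times = length(cc)) * ps
      px <- rep(cc, each = length(rr)) * ps
      d <- point_capsule_dist(px, py, tf$x_um[j], tf$y_um[j], tf$theta[j], half, w2)
      inside <- d <= 0
      if (any(inside)) {
        sub <- m[rr + 1L, cc + 1L, drop = FALSE]
        sub[inside] <- TRUE
        m[rr + 1L, cc + 1L] <- sub
      }
    }
    masks[, , k] <- m
  }
  masks
}

# Smooth-edged disc profile for a cancer cell, returned as a small patch with
# its top-left (0-based) field position. Peak height 1.
cell_profile_patch <- function(row, col, radius_px, nr, nc, edge = 0.6) {
  pad <- ceiling(radius_px) + 3L
  r0 <- max(0L, floor(row) - pad); r1 <- min(nr - 1L, ceiling(row) + pad)
  c0 <- max(0L, floor(col) - pad); c1 <- min(nc - 1L, ceiling(col) + pad)
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer((rr - row)^2, (cc - col)^2, "+"))
  list(r0 = r0, c0 = c0,
       patch = stats::plogis((radius_px - d) / edge))
}

# ---- the generator --------------------------------------------------------

#' Generate a synthetic tumor-on-chip time-lapse video with ground truth
#'
#' Renders static bright cancer-cell discs in the red channel, a caspase-like
#' green signal that switches on permanently after each cell's apoptosis
#' time, and motile elongated CAFs (plus faint static cancer discs) in the
#' transmission channel, over a smooth illumination gradient with Gaussian
#' read noise and optional Poisson shot noise. All randomness derives from
#' `config$seed`; the ground truth is drawn before any pixel noise, and each
#' channel renders from its own derived seed, so truth and rendered channels
#' are reproducible independently of which channels are requested.
#'
#' @param config A [sim_config()].
#' @param channels Channels to render, subset of `c("red","green","trans")`.
#'   Rendering fewer channels never changes the ground truth.
#' @param render If `FALSE`, skip all pixel rendering (`stack` is `NULL`);
#'   useful for statistical experiments that only need ground truth.
#' @param caf_masks If `TRUE`, include rasterised ground-truth CAF masks
#'   (logical array at the transmission cadence) in the truth bundle; an
#'   integer vector of transmission frame indices rasterises only those
#'   frames (stored with attribute `frames`), which keeps long videos cheap
#'   when only a window is analysed.
#' @return A list of class `toc_video` with elements `stack` (a
#'   [toc_stack()] or `NULL`) and `truth`: `cells` (id, centroid, radius,
#'   `apoptosis_time_h` with `Inf` = never, `proximal` exposure flag),
#'   `caf` (trajectories), `min_dist` (per-cell per-frame analytic minimum
#'   CAF distances over the early window), `caf_masks`, and the validated
#'   `config`.
#' @export
generate_toc_video <- function(config,
                               channels = c("red", "green", "trans"),
                               render = TRUE,
                               caf_masks = TRUE) {
  cfg <- validate_sim_config(config)
  channels <- match.arg(channels, several.ok = TRUE)
  nr <- cfg$field_size_px[1L]; nc <- cfg$field_size_px[2L]
  dt_fluor_h <- cfg$dt_fluor_min / 60
  dt_trans_h <- cfg$dt_trans_min / 60
  t_fluor <- seq(0, cfg$duration_h, by = dt_fluor_h)
  t_trans <- seq(0, cfg$duration_h, by = dt_trans_h)

  withr::with_preserve_seed({
    # -- ground truth (seed, fixed draw order) --
    set.seed(cfg$seed)
    cells <- place_cancer_cells(cfg)
    traj <- simulate_caf_motion(cfg)
    early_frames <- which(t_trans <= cfg$w_early_h)
    min_dist <- if (cfg$n_caf > 0)
      true_min_distances(cells, traj[traj$frame %in% early_frames, ], cfg)
    else tibble(id = cells$id, frame = 1L, t_h = 0, min_dist_um = Inf)
    early_min <- tapply(min_dist$min_dist_um, min_dist$id, min)
    early_min <- as.numeric(early_min[order(as.numeric(names(early_min)))])
    cells$min_dist_early_um <- early_min
    cells$proximal <- early_min < cfg$d_prox_um
    cells$apoptosis_time_h <- sample_apoptosis_times(
      early_min, cfg$lambda0_per_h, cfg$rho, cfg$d_prox_um, cfg$duration_h)

    masks <- if (cfg$n_caf > 0 && !isFALSE(caf_masks)) {
      if (isTRUE(caf_masks)) rasterize_caf_masks(traj, cfg)
      else structure(rasterize_caf_masks(traj, cfg, frames = caf_masks),
                     frames = as.integer(caf_masks))
    } else NULL

    # -- rendering (independent derived seeds per channel) --
    profiles <- lapply(seq_len(nrow(cells)), function(i)
      cell_profile_patch(cells$row[i], cells$col[i], cells$radius_px[i], nr, nc))
    add_patch <- function(img, p, scale) {
      rr <- (p$r0 + 1L):(p$r0 + nrow(p$patch))
      cc <- (p$c0 + 1L):(p$c0 + ncol(p$patch))
      img[rr, cc] <- img[rr, cc] + p$patch * scale
      img
    }
    gradient_plane <- function(phi, amp) {
      gx <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
      gy <- matrix(rep(seq(0, 1, length.out = nr), nc), nr, nc)
      amp * (cos(phi) * gx + sin(phi) * gy + 1) / 2
    }
    apply_noise <- function(img) {
      img <- pmax(img, 0)
      if (cfg$shot_scale > 0)
        img <- rpois(length(img), img * cfg$shot_scale) / cfg$shot_scale
      if (cfg$read_sd > 0) img <- img + rnorm(length(img), 0, cfg$read_sd)
      matrix(as.integer(round(pmin(pmax(img, 0), 65535))), nr, nc)
    }

    red <- green <- trans <- NULL
    if (render && "red" %in% channels) {
      set.seed(cfg$seed + 1L)
      base <- matrix(cfg$background, nr, nc)
      for (p in profiles) base <- add_patch(base, p, cfg$red_intensity)
      base <- base + gradient_plane(runif(1, 0, 2 * pi), cfg$gradient_amp)
      red <- array(0L, c(nr, nc, length(t_fluor)))
      for (f in seq_along(t_fluor)) red[, , f] <- apply_noise(base)
    }
    if (render && "green" %in% channels) {
      set.seed(cfg$seed + 2L)
      grad <- gradient_plane(runif(1, 0, 2 * pi), cfg$gradient_amp)
      base0 <- matrix(cfg$background, nr, nc) + grad
      rise_h <- cfg$green_rise_frames * dt_fluor_h
      green <- array(0L, c(nr, nc, length(t_fluor)))
      for (f in seq_along(t_fluor)) {
        img <- base0
        amp <- pmin(1, pmax(0, (t_fluor[f] - cells$apoptosis_time_h) / rise_h))
        for (i in which(amp > 0))
          img <- add_patch(img, profiles[[i]], cfg$green_plateau * amp[i])
        green[, , f] <- apply_noise(img)
      }
    }
    if (render && "trans" %in% channels) {
      set.seed(cfg$seed + 3L)
      grad <- gradient_plane(runif(1, 0, 2 * pi), cfg$gradient_amp)
      base0 <- matrix(cfg$trans_background, nr, nc) + grad
      # static darkening under cancer discs, with mild texture
      cancer_idx <- matrix(FALSE, nr, nc)
      for (p in profiles) {
        rr <- (p$r0 + 1L):(p$r0 + nrow(p$patch))
        cc <- (p$c0 + 1L):(p$c0 + ncol(p$patch))
        sub <- cancer_idx[rr, cc]; sub[p$patch > 0.5] <- TRUE
        cancer_idx[rr, cc] <- sub
      }
      base0[cancer_idx] <- base0[cancer_idx] * (0.5 + 0.5 * cfg$caf_contrast)
      tmask <- if (!is.null(masks) && is.null(attr(masks, "frames"))) masks
      else if (cfg$n_caf > 0) rasterize_caf_masks(traj, cfg)
      else array(FALSE, c(nr, nc, length(t_trans)))
      trans <- array(0L, c(nr, nc, length(t_trans)))
      for (f in seq_along(t_trans)) {
        img <- base0
        if (any(cancer_idx))
          img[cancer_idx] <- img[cancer_idx] +
            rnorm(sum(cancer_idx), 0, cfg$caf_texture_sd / 2)
        mk <- tmask[, , f]
        if (any(mk))
          img[mk] <- cfg$trans_background * cfg$caf_contrast +
            rnorm(sum(mk), 0, cfg$caf_texture_sd)
        trans[, , f] <- apply_noise(img)
      }
    }
    stack <- if (render && length(channels) > 0)
      toc_stack(red = red, green = green, trans = trans,
                frame_times_fluor_h = if (any(c("red", "green") %in% channels)) t_fluor else NULL,
                frame_times_trans_h = if ("trans" %in% channels) t_trans else NULL,
                pixel_size_um = cfg$pixel_size_um)
    else NULL

    structure(
      list(stack = stack,
           truth = list(cells = cells, caf = traj, min_dist = min_dist,
                        caf_masks = masks, t_trans_h = t_trans,
                        t_fluor_h = t_fluor, config = cfg)),
      class = "toc_video")
  })
}

#' @export
print.toc_video <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("<toc_video> %d cancer cells, %d CAFs, %.0f h (seed %d)\n",
              cfg$n_cancer, cfg$n_caf, cfg$duration_h, cfg$seed))
  cat(sprintf("  apoptosis events: %d/%d\n",
              sum(is.finite(x$truth$cells$apoptosis_time_h)), cfg$n_cancer))
  if (!is.null(x$stack)) print(x$stack)
  invisible(x)
}

#' Write a synthetic video and its ground truth to disk
#'
#' Writes the rendered channels via [write_toc_stack()] plus the
#' ground-truth bundle: `cells.csv` (id, row, col, radius_px,
#' apoptosis_time_h), `caf_masks.tif` (binary, transmission cadence) and a
#' round-trippable `config.json`.
#'
#' @param video A `toc_video` from [generate_toc_video()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_toc_video <- function(video, dir) {
  stopifnot(inherits(video, "toc_video"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(video$stack)) write_toc_stack(video$stack, dir)
  cells <- video$truth$cells
  readr::write_csv(
    dplyr::select(cells, "id", "row", "col", "radius_px", "apoptosis_time_h"),
    file.path(dir, "cells.csv"))
  if (!is.null(video$truth$caf_masks))
    write_mask_tiff(video$truth$caf_masks, file.path(dir, "caf_masks.tif"))
  config_to_json(video$truth$config, file.path(dir, "config.json"))
  invisible(dir)
}

#' Ground-truth tables for a synthetic video
#'
#' Convenience accessors that reshape the truth bundle into the tibbles the
#' analysis functions consume, bypassing detection: `truth_cells_table()`
#' gives the cell table ([proximity_records()] input; placement keeps cells
#' off the border, so `touches_border` is FALSE), `truth_events_table()` the
#' realised apoptosis events ([fate_table()] input).
#'
#' @param video A `toc_video` from [generate_toc_video()].
#' @return A tibble.
#' @export
truth_cells_table <- function(video) {
  stopifnot(inherits(video, "toc_video"))
  cells <- video$truth$cells
  tibble(label = cells$id, row = cells$row, col = cells$col,
         touches_border = FALSE)
}

#' @rdname truth_cells_table
#' @export
truth_events_table <- function(video) {
  stopifnot(inherits(video, "toc_video"))
  cells <- video$truth$cells
  dead <- is.finite(cells$apoptosis_time_h)
  tibble(label = cells$id[dead], event_time_h = cells$apoptosis_time_h[dead])
}

#' Proximity records computed on the ground-truth CAF masks
#'
#' Runs [proximity_records()] over the rasterised true CAF masks (the import
#' backend's bypass contract): the proximity metrics are exercised on masks
#' free of segmentation error, which isolates the statistical analysis from
#' the segmenter.
#'
#' @param video A `toc_video`.
#' @param window_h `c(start, end)` interval in hours; only transmission
#'   frames inside it are rasterised and measured.
#' @param ... Passed to [proximity_records()].
#' @return A proximity tibble.
#' @export
truth_proximity_records <- function(video, window_h = c(0, 8), ...) {
  stopifnot(inherits(video, "toc_video"))
  cfg <- video$truth$config
  t_tr <- video$truth$t_trans_h
  sel <- which(t_tr >= window_h[1L] & t_tr <= window_h[2L])
  masks <- video$truth$caf_masks
  if (is.null(masks)) {
    masks <- rasterize_caf_masks(video$truth$caf, cfg, frames = sel)
  } else if (!is.null(attr(masks, "frames"))) {
    if (!all(sel %in% attr(masks, "frames")))
      abort("stored caf_masks do not cover the requested window")
    if (!identical(attr(masks, "frames"), as.integer(sel)))
      masks <- masks[, , match(sel, attr(masks, "frames")), drop = FALSE]
  } else {
    masks <- masks[, , sel, drop = FALSE]
  }
  rec <- proximity_records(truth_cells_table(video), masks,
                           frame_times_h = t_tr[sel],
                           pixel_size_um = cfg$pixel_size_um, ...)
  rec$frame <- sel[rec$frame]
  rec
}
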
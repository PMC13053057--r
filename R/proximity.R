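# Tumor-CAF proximity metrics and the early-window vs late-fate
# ("kiss-of-life") stratification.

# Boundary pixels: mask pixels with at least one non-mask 4-neighbour
# (image edges count as outside). Erosion with a 4-neighbour cross kernel
# removes exactly the boundary; EBImage pads with background, so edge pixels
# are boundary, matching the convention.
cross_kernel <- matrix(c(0L, 1L, 0L, 1L, 1L, 1L, 0L, 1L, 0L), 3L, 3L)
mask_boundary <- function(mask) {
  mask & !(EBImage::erode(mask * 1L, cross_kernel) > 0)
}

# 0-based (row, col) coordinates of TRUE pixels.
which_coords0 <- function(mask) {
  idx <- which(mask)
  cbind(row = (idx - 1L) %% nrow(mask), col = (idx - 1L) %/% nrow(mask))
}

# Minimum distance (px) from each point (rows of `pts0`, 0-based fractional
# (row, col)) to a set of pixel centres. Returns Inf for empty sets.
min_dist_to_pixels <- function(pts0, coords0) {
  if (nrow(coords0) == 0L) return(rep(Inf, nrow(pts0)))
  br <- coords0[, 1L]; bc <- coords0[, 2L]
  vapply(seq_len(nrow(pts0)), function(i)
    sqrt(min((br - pts0[i, 1L])^2 + (bc - pts0[i, 2L])^2)), numeric(1))
}

#' Minimum centroid-to-CAF-boundary distance in one frame
#'
#' The minimum, over all CAF boundary pixels (mask pixels with at least one
#' non-mask 4-neighbour), of the Euclidean distance to the tumor-cell
#' centroid, in micrometres. When the centroid lies outside every CAF this
#' equals the nearest-mask-pixel distance. Returns `NA` when the frame
#' contains no CAF pixels.
#'
#' @param centroid Cell centroid as 0-based `c(row, col)` pixel coordinates
#'   (fractional allowed), or a one-row cell tibble with `row`/`col` columns.
#' @param mask Logical matrix, one transmission frame of CAF masks.
#' @param pixel_size_um Micrometres per pixel.
#' @return Distance in micrometres, or `NA_real_`.
#' @export
min_caf_distance <- function(centroid, mask, pixel_size_um = 1.3) {
  if (is.data.frame(centroid)) centroid <- c(centroid$row[1L], centroid$col[1L])
  if (!any(mask)) return(NA_real_)
  b <- which_coords0(mask_boundary(mask))
  min_dist_to_pixels(matrix(centroid, 1L), b) * pixel_size_um
}

#' Count tumor-CAF contacts over a time window
#'
#' A contact is a transmission frame in which the nearest CAF mask pixel lies
#' strictly closer than `threshold_um` to the cell centroid (Euclidean
#' distance in physical units; a pixel at exactly the threshold is not a
#' contact). The result is the count of such frames inside the window.
#'
#' @inheritParams min_caf_distance
#' @param masks A `caf_masks` object from [segment_cafs()] (or a logical 3-D
#'   array plus `frame_times_h`).
#' @param threshold_um Contact distance threshold, default 18.
#' @param window_h Time interval `c(start, end)` in hours (inclusive), or
#'   `NULL` for all frames.
#' @param frame_times_h Frame times when `masks` is a plain array.
#' @return Integer contact count.
#' @export
count_contacts <- function(centroid, masks, threshold_um = 18,
                           window_h = NULL, frame_times_h = NULL,
                           pixel_size_um = NULL) {
  if (is.data.frame(centroid)) centroid <- c(centroid$row[1L], centroid$col[1L])
  if (inherits(masks, "caf_masks")) {
    frame_times_h <- masks$frame_times_h
    pixel_size_um <- pixel_size_um %||% masks$pixel_size_um
    masks <- masks$masks
  }
  pixel_size_um <- pixel_size_um %||% 1.3
  frame_times_h <- frame_times_h %||% (seq_len(dim(masks)[3L]) - 1)
  sel <- if (is.null(window_h)) seq_len(dim(masks)[3L]) else
    which(frame_times_h >= window_h[1L] & frame_times_h <= window_h[2L])
  if (length(sel) == 0L) abort("empty time window")
  hits <- 0L
  for (f in sel) {
    mk <- masks[, , f]
    if (!any(mk)) next
    d <- nearest_mask_distance_px(matrix(centroid, 1L), mk)
    if (d * pixel_size_um < threshold_um) hits <- hits + 1L
  }
  hits
}

# Exact nearest-mask-pixel distance (px) for points: equals the distance to
# the containing pixel centre when that pixel is masked, otherwise the
# nearest boundary pixel (provably the nearest mask pixel for outside
# points).
nearest_mask_distance_px <- function(pts0, mask, boundary_coords0 = NULL) {
  b <- boundary_coords0 %||% which_coords0(mask_boundary(mask))
  d <- min_dist_to_pixels(pts0, b)
  pr <- pmin(pmax(round(pts0[, 1L]), 0L), nrow(mask) - 1L)
  pc <- pmin(pmax(round(pts0[, 2L]), 0L), ncol(mask) - 1L)
  inside <- mask[cbind(pr + 1L, pc + 1L)]
  d_here <- sqrt((pts0[, 1L] - pr)^2 + (pts0[, 2L] - pc)^2)
  ifelse(inside, pmin(d, d_here), d)
}

#' Intersection-over-union with a disc around the cell
#'
#' `A_R` is the rasterised disc of radius `radius_um` centred on the cell
#' centroid (a pixel belongs to the disc iff its centre lies within the
#' radius), clipped at the field borders; `A_CAF` is the full CAF mask of the
#' frame. The value is `|A_CAF n A_R| / |A_CAF u A_R|` by pixel counting - the
#' fraction of the cell's neighborhood occupied by CAFs, penalised by CAF
#' area elsewhere. Defined as 0 when `A_CAF` is empty.
#'
#' @inheritParams min_caf_distance
#' @param radius_um Disc radius, default 82.
#' @return IOU in `[0, 1]`.
#' @export
iou_at_radius <- function(centroid, mask, radius_um = 82, pixel_size_um = 1.3) {
  if (is.data.frame(centroid)) centroid <- c(centroid$row[1L], centroid$col[1L])
  if (radius_um <= 0) abort("radius_um must be > 0")
  disc <- disc_indices(centroid, radius_um / pixel_size_um, dim(mask))
  a_caf <- sum(mask)
  if (a_caf == 0L) return(0)
  inter <- sum(mask[disc])
  inter / (a_caf + length(disc) - inter)
}

# Linear indices of the clipped disc of radius `radius_px` around a 0-based
# fractional centre.
disc_indices <- function(centroid0, radius_px, dims) {
  r0 <- max(0L, floor(centroid0[1L] - radius_px))
  r1 <- min(dims[1L] - 1L, ceiling(centroid0[1L] + radius_px))
  c0 <- max(0L, floor(centroid0[2L] - radius_px))
  c1 <- min(dims[2L] - 1L, ceiling(centroid0[2L] + radius_px))
  if (r1 < r0 || c1 < c0) return(integer())
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - centroid0[1L])^2, (cc - centroid0[2L])^2, "+")
  inside <- d2 <= radius_px^2
  (rep(cc, each = length(rr)) * dims[1L] + rep(rr, times = length(cc)))[inside] + 1L
}

#' Per-cell, per-frame proximity records
#'
#' For every detected tumor cell and transmission frame: whether a CAF is in
#' contact (nearest CAF pixel strictly closer than `contact_um` to the
#' centroid), the minimum centroid-to-CAF-boundary distance (recorded only
#' for cells not in contact, mirroring how the measurement is defined), and
#' the IOU against the `iou_radius_um` disc.
#'
#' @param cells Cell tibble from [detect_tumor_cells()].
#' @param masks A `caf_masks` object (or logical array; see
#'   [count_contacts()]).
#' @param contact_um Contact threshold, default 18.
#' @param iou_radius_um IOU disc radius, default 82.
#' @param window_h Optional `c(start, end)` interval restricting the frames.
#' @param frame_times_h,pixel_size_um Used when `masks` is a plain array.
#' @return Tibble with one row per (cell, frame): `label`, `frame`, `t_h`,
#'   `in_contact`, `min_dist_um` (`NA` when in contact or no CAF present),
#'   `iou`.
#' @export
proximity_records <- function(cells, masks, contact_um = 18,
                              iou_radius_um = 82, window_h = NULL,
                              frame_times_h = NULL, pixel_size_um = NULL) {
  if (inherits(masks, "caf_masks")) {
    frame_times_h <- masks$frame_times_h
    pixel_size_um <- pixel_size_um %||% masks$pixel_size_um
    masks <- masks$masks
  }
  pixel_size_um <- pixel_size_um %||% attr(cells, "pixel_size_um") %||% 1.3
  d <- dim(masks)
  frame_times_h <- frame_times_h %||% (seq_len(d[3L]) - 1)
  sel <- if (is.null(window_h)) seq_len(d[3L]) else
    which(frame_times_h >= window_h[1L] & frame_times_h <= window_h[2L])
  if (length(sel) == 0L) abort("empty time window")
  pts <- cbind(cells$row, cells$col)
  n <- nrow(cells)
  disc_px <- lapply(seq_len(n), function(i)
    disc_indices(pts[i, ], iou_radius_um / pixel_size_um, d[1:2]))
  disc_len <- lengths(disc_px)
  res <- vector("list", length(sel))
  for (k in seq_along(sel)) {
    f <- sel[k]
    mk <- masks[, , f]
    a_caf <- sum(mk)
    if (a_caf == 0L) {
      res[[k]] <- tibble(label = cells$label, frame = f, t_h = frame_times_h[f],
                         in_contact = FALSE, min_dist_um = NA_real_, iou = 0)
      next
    }
    bco <- which_coords0(mask_boundary(mk))
    d_bound <- min_dist_to_pixels(pts, bco)
    d_near <- nearest_mask_distance_px(pts, mk, bco)
    contact <- d_near * pixel_size_um < contact_um
    inter <- vapply(disc_px, function(ix) sum(mk[ix]), numeric(1))
    iou <- inter / (a_caf + disc_len - inter)
    res[[k]] <- tibble(label = cells$label, frame = f, t_h = frame_times_h[f],
                       in_contact = contact,
                       min_dist_um = ifelse(contact, NA_real_,
                                            d_bound * pixel_size_um),
                       iou = iou)
  }
  bind_rows(res)
}

#' Cell fates at a fixed horizon
#'
#' A cell is `dead` iff an apoptosis event was called at or before
#' `horizon_h`, else `alive`.
#'
#' @param cells Cell tibble (provides the full label set and border flags).
#' @param events Event tibble from [call_apoptosis_events()].
#' @param horizon_h Fate horizon in hours, default 72.
#' @return Tibble `label`, `fate` (factor dead/alive), `event_time_h`
#'   (`NA` when alive), `touches_border`.
#' @export
fate_table <- function(cells, events, horizon_h = 72) {
  ev <- events[is.finite(event_times_from(events)) &
                 event_times_from(events) <= horizon_h, , drop = FALSE]
  tibble(label = cells$label,
         touches_border = cells$touches_border %||% FALSE) %>%
    left_join(select(ev, "label", "event_time_h"), by = "label") %>%
    mutate(fate = factor(ifelse(is.na(.data$event_time_h), "alive", "dead"),
                         levels = c("dead", "alive")))
}

#' Early-proximity vs late-fate stratification ("kiss-of-life" analysis)
#'
#' Pools early-window proximity measurements into dead vs alive strata
#' (fate at the horizon) for three parameters: per-cell total contact counts,
#' and per-(cell, time point) minimum distances and IOU values - the latter
#' two mirror the per-measurement n of the original analysis. Cells dying
#' within the early window are kept in the dead stratum with their
#' measurements up to the event time, avoiding immortal-time bias;
#' border-touching cells are excluded by default.
#'
#' For each parameter a two-sample Kolmogorov-Smirnov statistic D is computed
#' on the pooled samples. Its p-value comes from a cell-level permutation
#' null (fates reshuffled across cells, D recomputed on the re-pooled
#' samples): per-time-point observations of one cell are strongly dependent,
#' so the iid sampling distribution of D is not valid for them, while
#' permuting whole cells preserves the dependence. The asymptotic iid KS
#' p-value is also reported for reference as `p_naive`. Direction is
#' `median(alive) - median(dead)`.
#'
#' @param records Proximity tibble from [proximity_records()].
#' @param fates Fate tibble from [fate_table()].
#' @param early_window_h `c(start, end)` hours, default `c(0, 8)`.
#' @param exclude_border Drop border-flagged cells (default TRUE).
#' @param n_perm Number of fate permutations for the p-value.
#' @param parameters Which of the three proximity parameters to pool and
#'   test (default all).
#' @return Object of class `kiss_of_life`; use [generics::tidy()] for the
#'   per-parameter test table, [generics::glance()] for a one-row summary,
#'   `$samples` for the pooled observations.
#' @export
stratify_by_fate <- function(records, fates, early_window_h = c(0, 8),
                             exclude_border = TRUE, n_perm = 999L,
                             parameters = c("contacts", "min_dist_um", "iou")) {
  parameters <- match.arg(parameters, several.ok = TRUE)
  if (exclude_border && any(fates$touches_border))
    fates <- fates[!fates$touches_border, , drop = FALSE]
  rec <- records %>%
    filter(.data$t_h >= early_window_h[1L], .data$t_h <= early_window_h[2L]) %>%
    dplyr::inner_join(select(fates, "label", "fate", "event_time_h"),
                      by = "label") %>%
    filter(is.na(.data$event_time_h) | .data$t_h <= .data$event_time_h)
  if (nrow(rec) == 0L) abort("no proximity records inside the early window")

  pools <- list(
    contacts = function() rec %>% group_by(.data$label, .data$fate) %>%
      summarise(value = sum(.data$in_contact), .groups = "drop") %>%
      mutate(parameter = "contacts"),
    min_dist_um = function() rec %>% filter(!is.na(.data$min_dist_um)) %>%
      transmute(label = .data$label, fate = .data$fate,
                value = .data$min_dist_um, parameter = "min_dist_um"),
    iou = function() rec %>% transmute(label = .data$label, fate = .data$fate,
                                       value = .data$iou, parameter = "iou")
  )
  samples <- bind_rows(lapply(pools[parameters], function(f) f()))

  test_one <- function(df) {
    by_cell <- split(df$value, df$label)
    cell_fate <- vapply(split(as.character(df$fate), df$label),
                        function(f) f[1L], character(1))
    dead <- cell_fate == "dead"
    if (sum(dead) == 0L) abort("stratum 'dead' is empty")
    if (sum(!dead) == 0L) abort("stratum 'alive' is empty")
    x_alive <- unlist(by_cell[!dead], use.names = FALSE)
    x_dead <- unlist(by_cell[dead], use.names = FALSE)
    D <- ks_statistic(x_alive, x_dead)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      pd <- sample(dead)
      Db <- ks_statistic(unlist(by_cell[!pd], use.names = FALSE),
                         unlist(by_cell[pd], use.names = FALSE))
      if (Db >= D) exceed <- exceed + 1L
    }
    p_naive <- suppressWarnings(
      stats::ks.test(x_alive, x_dead, exact = FALSE)$p.value)
    tibble(n_alive_cells = sum(!dead), n_dead_cells = sum(dead),
           n_alive = length(x_alive), n_dead = length(x_dead),
           median_alive = median(x_alive), median_dead = median(x_dead),
           direction = median(x_alive) - median(x_dead),
           ks_D = D, p_value = (1 + exceed) / (n_perm + 1), p_naive = p_naive)
  }
  tests <- samples %>%
    group_by(.data$parameter) %>%
    dplyr::group_modify(~ test_one(.x)) %>%
    ungroup()

  structure(list(samples = samples, tests = tests,
                 params = list(early_window_h = early_window_h,
                               exclude_border = exclude_border,
                               n_perm = n_perm)),
            class = "kiss_of_life")
}

#' @export
print.kiss_of_life <- function(x, ...) {
  cat(sprintf("<kiss_of_life> early window %.1f-%.1f h, %d permutations\n",
              x$params$early_window_h[1L], x$params$early_window_h[2L],
              x$params$n_perm))
  print(as.data.frame(x$tests), digits = 3)
  invisible(x)
}
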
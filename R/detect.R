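# Static-tumor-cell detection: adaptive Bradley thresholding of the red
# channel, a temporal-persistence tumor mask, 8-connected labelling, and
# dilation-based foreground/background rings for signal extraction.

#' Adaptive Bradley thresholding
#'
#' Binarises an image by comparing each pixel with the mean intensity of a
#' square neighborhood around it: a pixel is foreground iff
#' `intensity > local_mean * (1 + sensitivity)`. The window side is
#' `floor(min(rows, cols) * neighborhood_fraction)`, reduced to the next odd
#' number so windows are symmetric; windows overhanging the image are clipped
#' and renormalised by their true area, so border means are exact. Local
#' means are computed with summed-area tables and agree bit-for-bit with
#' direct summation. The mask is invariant under multiplication of the image
#' by any positive constant.
#'
#' @param image 2-D numeric matrix, at least 8x8, all values finite.
#' @param neighborhood_fraction Window side as a fraction of the smaller
#'   image dimension; the conventional 1/8 is the default.
#' @param sensitivity Relative threshold margin above the local mean
#'   (`0.05` = 5%). Zero makes the threshold the local mean itself.
#' @return Logical matrix (TRUE = foreground) with attributes `window_side`
#'   and `sensitivity`.
#' @export
bradley_threshold <- function(image, neighborhood_fraction = 1 / 8,
                              sensitivity = 0.05) {
  if (!is.matrix(image)) abort("image must be a matrix")
  if (nrow(image) < 8L || ncol(image) < 8L) abort("image must be at least 8x8")
  if (neighborhood_fraction <= 0 || neighborhood_fraction > 1)
    abort("neighborhood_fraction must be in (0, 1]")
  if (sensitivity < 0) abort("sensitivity must be >= 0")
  assert_finite_matrix(image)
  side <- floor(min(dim(image)) * neighborhood_fraction)
  if (side %% 2 == 0) side <- side - 1L
  if (side < 3L) abort(sprintf("neighborhood window side %d is below 3", side))
  mu <- box_mean(image, side)
  # summed-area cancellation can leave means at -eps over constant regions of
  # a non-negative image, which a relative threshold would misread
  if (min(image) >= 0) mu[mu < 0] <- 0
  mask <- image > mu * (1 + sensitivity)
  structure(mask, window_side = as.integer(side), sensitivity = sensitivity)
}

#' Temporal-persistence tumor mask
#'
#' A pixel belongs to the tumor mask iff it is classified as foreground in at
#' least `persistence` of the frames (inclusive comparison, so 95 foreground
#' frames out of 100 pass at the default 0.95). Static cells survive this
#' filter; transient detections (motile CAFs, noise flicker) are removed.
#'
#' @param binary_stack Logical/numeric 3-D array `[row, col, frame]` of
#'   per-frame foreground masks, at least 2 frames.
#' @param persistence Required fraction of foreground frames, in (0, 1].
#' @return Logical matrix with attributes `counts` (per-pixel foreground
#'   frame counts), `n_frames` and `persistence`.
#' @export
temporal_persistence_mask <- function(binary_stack, persistence = 0.95) {
  d <- dim(binary_stack)
  if (length(d) != 3L) abort("binary_stack must be a 3-D array [row, col, frame]")
  if (d[3L] < 2L) abort("at least 2 frames are required")
  if (persistence <= 0 || persistence > 1) abort("persistence must be in (0, 1]")
  counts <- rowSums(binary_stack != 0, dims = 2L)
  mask <- counts / d[3L] >= persistence
  structure(mask, counts = counts, n_frames = d[3L], persistence = persistence)
}

#' Label tumor cells in a binary mask
#'
#' Extracts 8-connected components with at least `min_area_px` pixels as
#' individual tumor-cell records. Labels are ordered by each component's
#' lexicographically first (top-most, then left-most) pixel. Coordinates are
#' 0-based `(row, col)` with pixel centres at integer positions; physical
#' coordinates are `index * pixel_size_um`.
#'
#' @param mask Logical matrix (e.g. from [temporal_persistence_mask()]).
#' @param min_area_px Minimum component area; smaller specks are dropped.
#' @param pixel_size_um Micrometres per pixel.
#' @return A tibble with one row per cell: `label`, `row`, `col` (centroid,
#'   px), `x_um`, `y_um` (centroid, `x` along columns), `area_px`,
#'   `touches_border`, and a list-column `fg_px` of linear pixel indices.
#'   The integer label image is attached as attribute `label_image`.
#' @export
label_tumor_cells <- function(mask, min_area_px = 20L, pixel_size_um = 1.3) {
  if (!is.matrix(mask)) abort("mask must be a matrix")
  lab <- label_components8(mask)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    drop <- which(areas < min_area_px)
    if (length(drop) > 0L) lab[lab %in% drop] <- 0L
    lab <- relabel_by_first_pixel(lab)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  nlab <- max(lab)
  if (nlab == 0L) {
    out <- tibble(label = integer(), row = numeric(), col = numeric(),
                  x_um = numeric(), y_um = numeric(), area_px = integer(),
                  touches_border = logical(), fg_px = list())
    attr(out, "label_image") <- lab
    attr(out, "pixel_size_um") <- pixel_size_um
    return(out)
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows0 <- (idx - 1L) %% nr
  cols0 <- (idx - 1L) %/% nr
  area <- tabulate(l, nlab)
  crow <- as.numeric(tapply(rows0, l, mean))
  ccol <- as.numeric(tapply(cols0, l, mean))
  border <- as.logical(tapply(rows0 == 0L | rows0 == nr - 1L |
                                cols0 == 0L | cols0 == nc - 1L, l, any))
  fg_px <- split(idx, l)
  out <- tibble(
    label = seq_len(nlab),
    row = crow, col = ccol,
    x_um = ccol * pixel_size_um, y_um = crow * pixel_size_um,
    area_px = as.integer(area),
    touches_border = border,
    fg_px = unname(fg_px)
  )
  attr(out, "label_image") <- lab
  attr(out, "pixel_size_um") <- pixel_size_um
  out
}

#' Foreground/background rings for signal extraction
#'
#' For each cell the background ring is the morphological dilation of its
#' foreground by a disc of radius `r_dilate = round(sqrt(area)/3)` (minimum
#' 1 px) minus the foreground itself, clipped to the field; larger cells get
#' proportionally larger background annuli. Ring pixels that fall on any
#' other cell's foreground are removed so background estimates are never
#' contaminated by a neighbour's signal.
#'
#' @param cells Tibble from [label_tumor_cells()] (needs the `fg_px`
#'   list-column and the `label_image` attribute).
#' @return `cells` with added `r_dilate` column and `ring_px` list-column
#'   (linear pixel indices; may be empty when neighbours swallow the whole
#'   ring).
#' @export
foreground_background_rings <- function(cells) {
  lab <- attr(cells, "label_image")
  if (is.null(lab)) abort("cells must carry a label_image attribute")
  nr <- nrow(lab); nc <- ncol(lab)
  any_fg <- lab > 0L
  r_dilate <- pmax(1L, as.integer(round(sqrt(cells$area_px) / 3)))
  ring_px <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r <- r_dilate[i]
    idx <- cells$fg_px[[i]]
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    r0 <- max(1L, min(rows) - r); r1 <- min(nr, max(rows) + r)
    c0 <- max(1L, min(cols) - r); c1 <- min(nc, max(cols) + r)
    patch <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
    patch[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- 1L
    dil <- EBImage::dilate(patch, disc_kernel(r)) > 0
    ring_local <- which(dil & patch == 0L)
    if (length(ring_local) > 0L) {
      pr <- (ring_local - 1L) %% nrow(patch) + r0
      pc <- (ring_local - 1L) %/% nrow(patch) + c0
      gidx <- (pc - 1L) * nr + pr
      gidx <- gidx[!any_fg[gidx]]   # drop pixels on any cell's foreground
      ring_px[[i]] <- gidx
    } else ring_px[[i]] <- integer()
  }
  cells$r_dilate <- r_dilate
  cells$ring_px <- ring_px
  cells
}

#' Detect static tumor cells in a red-channel stack
#'
#' Convenience wrapper chaining [bradley_threshold()] per frame,
#' [temporal_persistence_mask()], [label_tumor_cells()] and
#' [foreground_background_rings()].
#'
#' @param red 3-D array `[row, col, frame]` of red-channel intensities, or a
#'   [toc_stack()].
#' @param pixel_size_um Micrometres per pixel (taken from the stack when one
#'   is supplied).
#' @param neighborhood_fraction,sensitivity Passed to [bradley_threshold()].
#' @param persistence Passed to [temporal_persistence_mask()].
#' @param min_area_px Passed to [label_tumor_cells()].
#' @return The cell tibble (see [label_tumor_cells()]) with rings filled and
#'   the persistence mask attached as attribute `tumor_mask`.
#' @export
detect_tumor_cells <- function(red, pixel_size_um = 1.3,
                               neighborhood_fraction = 1 / 8,
                               sensitivity = 0.05,
                               persistence = 0.95,
                               min_area_px = 20L) {
  if (inherits(red, "toc_stack")) {
    pixel_size_um <- red$pixel_size_um
    red <- red$red %||% abort("stack has no red channel")
  }
  d <- dim(red)
  if (length(d) != 3L) abort("red must be a 3-D array [row, col, frame]")
  bin <- array(FALSE, d)
  for (f in seq_len(d[3L]))
    bin[, , f] <- bradley_threshold(red[, , f], neighborhood_fraction, sensitivity)
  tmask <- temporal_persistence_mask(bin, persistence)
  cells <- label_tumor_cells(tmask, min_area_px, pixel_size_um)
  cells <- foreground_background_rings(cells)
  attr(cells, "tumor_mask") <- tmask
  cells
}
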
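# Per-frame CAF segmentation from the transmission channel. The production
# segmenter for real videos is a CNN; here the backend is pluggable: a
# classical texture-based method for synthetic data and an import path for
# externally computed masks, so the downstream proximity analysis is
# independent of how the masks were produced.

#' Segment CAFs in the transmission channel
#'
#' Classical backend: a local-variance (texture) map per frame is binarised
#' with [bradley_threshold()] (cells are textured, the background is smooth),
#' closed with a small disc, eroded by a support-correction disc (the
#' variance window inflates textured regions beyond their true extent), and
#' filtered to components within `[min_area_px, max_area_px]`; pixels on the
#' persistent tumor mask are removed beforehand, since cancer cells are not
#' CAFs (detected cancer-cell specks then fall below the area floor).
#' Import backend: externally computed binary masks are validated
#' for matching geometry and passed through unchanged.
#'
#' @param trans 3-D array `[row, col, frame]` of transmission intensities, or
#'   a [toc_stack()] with a transmission channel.
#' @param method `"classical"` or `"import"`.
#' @param masks For `method = "import"`: logical 3-D array of per-frame CAF
#'   masks with the same geometry as `trans`.
#' @param tumor_mask Optional persistent tumor mask (logical matrix); its
#'   pixels are excluded from the CAF masks (classical backend only).
#' @param frame_times_h Transmission frame times (taken from the stack when
#'   one is supplied).
#' @param pixel_size_um Micrometres per pixel.
#' @param texture_window_px Local-variance window side (odd).
#' @param closing_radius_px Disc radius for morphological closing.
#' @param shrink_px Support-correction erosion radius; defaults to half the
#'   texture window, matching the support dilation of the variance map.
#' @param min_area_px,max_area_px Component area bounds.
#' @param sensitivity Bradley sensitivity on the variance map.
#' @param neighborhood_fraction Bradley window fraction for the variance
#'   map. Larger than the intensity-channel default because the local mean
#'   must average over a region big compared with one CAF, or textured cells
#'   would raise their own threshold.
#' @return An object of class `caf_masks`: list with `masks` (logical array),
#'   `frame_times_h`, `pixel_size_um`, `backend` descriptor.
#' @export
segment_cafs <- function(trans, method = c("classical", "import"),
                         masks = NULL, tumor_mask = NULL,
                         frame_times_h = NULL, pixel_size_um = 1.3,
                         texture_window_px = 7L, closing_radius_px = 2L,
                         shrink_px = NULL, min_area_px = 200L,
                         max_area_px = 20000L, sensitivity = 0.5,
                         neighborhood_fraction = 0.25) {
  method <- match.arg(method)
  if (inherits(trans, "toc_stack")) {
    frame_times_h <- frame_times_h %||% trans$frame_times_trans_h
    pixel_size_um <- trans$pixel_size_um
    trans <- trans$trans %||% abort("stack has no transmission channel")
  }
  d <- dim(trans)
  if (length(d) != 3L) abort("trans must be a 3-D array [row, col, frame]")
  frame_times_h <- frame_times_h %||% (seq_len(d[3L]) - 1)

  if (method == "import") {
    if (is.null(masks)) abort("method = 'import' requires masks")
    if (!all(dim(masks) == d))
      abort("imported masks do not match the transmission geometry")
    out <- masks != 0
    backend <- list(method = "import")
  } else {
    shrink_px <- shrink_px %||% (texture_window_px %/% 2L)
    kern_close <- disc_kernel(closing_radius_px)
    kern_shrink <- if (shrink_px > 0) disc_kernel(shrink_px) else NULL
    out <- array(FALSE, d)
    for (f in seq_len(d[3L])) {
      v <- box_var(trans[, , f], texture_window_px)
      m <- bradley_threshold(v, neighborhood_fraction = neighborhood_fraction,
                             sensitivity = sensitivity)
      m <- EBImage::closing(m * 1L, kern_close) > 0
      if (!is.null(kern_shrink)) m <- EBImage::erode(m * 1L, kern_shrink) > 0
      # cancer cells are not CAFs: remove tumor pixels before labelling, so a
      # CAF brushing past a cancer cell keeps its own pixels
      if (!is.null(tumor_mask)) m <- m & !tumor_mask
      if (any(m)) {
        lab <- label_components8(m)
        areas <- tabulate(lab[lab > 0L])
        keep <- which(areas >= min_area_px & areas <= max_area_px)
        m <- matrix(lab %in% keep & lab > 0L, d[1L], d[2L])
      }
      out[, , f] <- m
    }
    if (!any(out)) warn("CAF segmentation produced empty masks on every frame")
    backend <- list(method = "classical", texture_window_px = texture_window_px,
                    closing_radius_px = closing_radius_px, shrink_px = shrink_px,
                    min_area_px = min_area_px, max_area_px = max_area_px,
                    sensitivity = sensitivity,
                    neighborhood_fraction = neighborhood_fraction)
  }
  structure(list(masks = out, frame_times_h = frame_times_h,
                 pixel_size_um = pixel_size_um, backend = backend),
            class = "caf_masks")
}

#' @export
print.caf_masks <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("<caf_masks> %d x %d px, %d frames (%s backend)\n",
              d[1L], d[2L], d[3L], x$backend$method))
  invisible(x)
}
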
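#' Multi-channel time-lapse stack
#'
#' Container for a tumor-on-chip acquisition: up to three pixel channels
#' (`red` = pre-stained cancer cells, `green` = caspase-3/7 reporter,
#' `trans` = transmission/brightfield), each a 3-D array indexed
#' `[row, col, frame]`, together with per-channel frame times in hours and the
#' physical pixel size. Red and green share frame times (same fluorescence
#' acquisition); the transmission channel is typically acquired at a higher
#' cadence.
#'
#' @param red,green,trans 3-D numeric arrays `[row, col, frame]`, or `NULL`
#'   for channels that were not acquired.
#' @param frame_times_fluor_h Numeric vector of fluorescence frame times
#'   (hours), strictly increasing; required when `red` or `green` is present.
#' @param frame_times_trans_h Frame times for the transmission channel.
#' @param pixel_size_um Physical pixel size, micrometres per pixel.
#' @return An object of class `toc_stack`.
#' @export
toc_stack <- function(red = NULL, green = NULL, trans = NULL,
                      frame_times_fluor_h = NULL, frame_times_trans_h = NULL,
                      pixel_size_um = 1.3) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    abort("pixel_size_um must be a single positive number")
  chk_chan <- function(x, times, name) {
    if (is.null(x)) return(invisible(NULL))
    if (length(dim(x)) != 3L) abort(sprintf("%s must be a 3-D array", name))
    if (is.null(times)) abort(sprintf("frame times missing for channel %s", name))
    if (dim(x)[3L] != length(times))
      abort(sprintf("%s has %d frames but %d frame times", name, dim(x)[3L], length(times)))
    if (any(diff(times) <= 0)) abort("frame times must be strictly increasing")
    invisible(NULL)
  }
  chk_chan(red, frame_times_fluor_h, "red")
  chk_chan(green, frame_times_fluor_h, "green")
  chk_chan(trans, frame_times_trans_h, "trans")
  dims <- lapply(Filter(Negate(is.null), list(red, green, trans)), function(a) dim(a)[1:2])
  if (length(dims) == 0L) abort("at least one channel is required")
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    abort("all channels must share the same field size")
  structure(
    list(red = red, green = green, trans = trans,
         frame_times_fluor_h = frame_times_fluor_h,
         frame_times_trans_h = frame_times_trans_h,
         pixel_size_um = pixel_size_um),
    class = "toc_stack"
  )
}

#' @export
print.toc_stack <- function(x, ...) {
  dims <- dim(x$red %||% x$green %||% x$trans)
  cat(sprintf("<toc_stack> %d x %d px, %.3g um/px\n", dims[1L], dims[2L], x$pixel_size_um))
  for (ch in c("red", "green", "trans")) {
    if (!is.null(x[[ch]])) {
      t <- if (ch == "trans") x$frame_times_trans_h else x$frame_times_fluor_h
      cat(sprintf("  %-5s %4d frames, %.1f-%.1f h\n", ch, dim(x[[ch]])[3L], min(t), max(t)))
    }
  }
  invisible(x)
}

# uint16 multi-page TIFF helpers (tiff stores [0,1] floats; integer
# intensities round-trip exactly through value/65535).
write_stack_tiff <- function(arr, path) {
  pages <- lapply(seq_len(dim(arr)[3L]), function(f) {
    pmin(pmax(arr[, , f], 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1L]])[1:2], length(pages)))
  for (f in seq_along(pages)) {
    pg <- pages[[f]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]
    arr[, , f] <- round(pg * 65535)
  }
  arr
}

write_mask_tiff <- function(mask, path) {
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  pages <- lapply(seq_len(dim(mask)[3L]), function(f) (mask[, , f] != 0) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

read_mask_tiff <- function(path) {
  arr <- read_stack_tiff(path)
  arr > (65535 / 2)
}

#' Write a time-lapse stack to a directory
#'
#' One uint16 multi-page TIFF per channel (`red.tif`, `green.tif`,
#' `trans.tif`) plus `stack_meta.json` holding frame times and pixel size.
#'
#' @param stack A [toc_stack()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toc_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "toc_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in c("red", "green", "trans")) {
    if (!is.null(stack[[ch]]))
      write_stack_tiff(stack[[ch]], file.path(dir, paste0(ch, ".tif")))
  }
  meta <- list(
    frame_times_fluor_h = stack$frame_times_fluor_h,
    frame_times_trans_h = stack$frame_times_trans_h,
    pixel_size_um = stack$pixel_size_um,
    channels = Filter(function(ch) !is.null(stack[[ch]]), c("red", "green", "trans"))
  )
  jsonlite::write_json(meta, file.path(dir, "stack_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a time-lapse stack written by [write_toc_stack()]
#'
#' @param dir Directory containing per-channel TIFFs and `stack_meta.json`.
#' @return A [toc_stack()].
#' @export
read_toc_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack_meta.json"), simplifyVector = TRUE)
  get_ch <- function(ch) {
    p <- file.path(dir, paste0(ch, ".tif"))
    if (file.exists(p)) read_stack_tiff(p) else NULL
  }
  toc_stack(red = get_ch("red"), green = get_ch("green"), trans = get_ch("trans"),
            frame_times_fluor_h = meta$frame_times_fluor_h,
            frame_times_trans_h = meta$frame_times_trans_h,
            pixel_size_um = meta$pixel_size_um)
}
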
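# Green caspase-signal extraction from fixed cell regions, apoptosis event
# calling, and the windowed survival / apoptosis-rate statistics.

#' Extract background-corrected green traces from fixed cell regions
#'
#' Because tumor cells are static, the regions segmented on the red channel
#' are transposed unchanged onto every green frame: for each cell and frame
#' the mean intensity over the foreground mask and over the background ring
#' are recorded, and the corrected signal is their difference (which may be
#' negative). Cells whose ring was entirely removed by neighbour collisions
#' fall back to a global background estimate (median intensity outside all
#' cell foregrounds) and are flagged.
#'
#' @param green 3-D array `[row, col, frame]` of green-channel intensities,
#'   or a [toc_stack()] with a green channel.
#' @param cells Cell tibble from [detect_tumor_cells()] /
#'   [foreground_background_rings()].
#' @param frame_times_h Frame times in hours (taken from the stack when one
#'   is supplied).
#' @return A tibble with one row per (cell, frame): `label`, `frame`, `t_h`,
#'   `fg`, `bg`, `corrected`, `bg_fallback`.
#' @export
extract_green_traces <- function(green, cells, frame_times_h = NULL) {
  if (inherits(green, "toc_stack")) {
    frame_times_h <- frame_times_h %||% green$frame_times_fluor_h
    green <- green$green %||% abort("stack has no green channel")
  }
  d <- dim(green)
  if (length(d) != 3L) abort("green must be a 3-D array [row, col, frame]")
  frame_times_h <- frame_times_h %||% (seq_len(d[3L]) - 1)
  if (length(frame_times_h) != d[3L]) abort("frame_times_h length mismatch")
  lab <- attr(cells, "label_image")
  if (!is.null(lab) && !all(dim(lab) == d[1:2]))
    abort("green frames do not match the geometry of the cell masks")
  if (is.null(cells$ring_px)) abort("cells need rings; run foreground_background_rings()")
  n <- nrow(cells)
  empty_ring <- lengths(cells$ring_px) == 0L
  outside <- if (any(empty_ring)) {
    all_fg <- unlist(cells$fg_px, use.names = FALSE)
    setdiff(seq_len(d[1L] * d[2L]), all_fg)
  } else NULL
  res <- vector("list", d[3L])
  for (f in seq_len(d[3L])) {
    frame <- green[, , f]
    fg <- vapply(cells$fg_px, function(ix) mean(frame[ix]), numeric(1))
    bg <- vapply(cells$ring_px, function(ix)
      if (length(ix) > 0L) mean(frame[ix]) else NA_real_, numeric(1))
    if (any(empty_ring)) bg[empty_ring] <- median(frame[outside])
    res[[f]] <- tibble(label = cells$label, frame = f, t_h = frame_times_h[f],
                       fg = fg, bg = bg, corrected = fg - bg,
                       bg_fallback = empty_ring)
  }
  dplyr::arrange(bind_rows(res), .data$label, .data$frame)
}

# Event call on a single corrected-signal vector. For each candidate event
# frame e the baseline is every frame before it (always including the first
# 3): the event is the earliest e whose m_consec frames all exceed
# median + k_sigma * MAD of that pre-event baseline. Because the caspase
# signal is persistent, pre-event frames are signal-free by construction,
# and the baseline grows with e so its robust scale estimate stabilises.
call_event_vector <- function(corrected, k_sigma = 5, m_consec = 3L) {
  nf <- length(corrected)
  if (nf < m_consec) abort("trace shorter than m_consec frames")
  if (nf < m_consec + 3L) return(NA_integer_)
  # global robust scale from first differences: insensitive to the single
  # persistent step, and it floors the prefix MAD, whose small-sample
  # fluctuations would otherwise produce spurious calls on short baselines
  sig_floor <- mad(diff(corrected)) / sqrt(2)
  for (e in 4L:(nf - m_consec + 1L)) {
    base <- corrected[seq_len(e - 1L)]
    th <- median(base) + k_sigma * max(mad(base), sig_floor)
    if (all(corrected[e:(e + m_consec - 1L)] > th)) return(e)
  }
  NA_integer_
}

#' Call apoptosis events from green traces
#'
#' The caspase reporter is irreversible, so an event is called at the first
#' frame where the corrected signal exceeds `baseline_median +
#' k_sigma * sigma` for `m_consec` consecutive frames; the baseline median
#' and robust sigma (MAD) are estimated from all frames preceding the
#' candidate frame (at least the first three), with the sigma floored by a
#' global first-difference MAD so short baselines cannot underestimate the
#' noise scale. At most one event
#' per cell; cells with no qualifying crossing are absent from the result
#' (alive at the end of the video).
#'
#' @param traces Trace tibble from [extract_green_traces()].
#' @param k_sigma Threshold in robust-sigma units above baseline.
#' @param m_consec Required number of consecutive supra-threshold frames.
#' @return A tibble `label`, `event_frame`, `event_time_h` plus the call
#'   parameters as attributes.
#' @export
call_apoptosis_events <- function(traces, k_sigma = 5, m_consec = 3L) {
  stopifnot(all(c("label", "frame", "t_h", "corrected") %in% names(traces)))
  traces <- dplyr::arrange(traces, .data$label, .data$frame)
  out <- traces %>%
    group_by(.data$label) %>%
    summarise(
      event_frame = call_event_vector(.data$corrected, k_sigma, m_consec),
      event_time_h = if (is.na(event_frame[1L])) NA_real_ else
        .data$t_h[event_frame[1L]],
      .groups = "drop") %>%
    filter(!is.na(.data$event_frame))
  attr(out, "k_sigma") <- k_sigma
  attr(out, "m_consec") <- m_consec
  out
}

event_times_from <- function(events) {
  if (is.data.frame(events)) {
    if (!"event_time_h" %in% names(events)) abort("events needs an event_time_h column")
    events$event_time_h
  } else as.numeric(events)
}

#' Windowed survival curve
#'
#' Survival at each window start `t_n` in `{0, window_h, 2*window_h, ...}` is
#' `(n_alive_t0 - events in (t_0, t_n]) / n_alive_t0 * 100`; survival at
#' `t_0` is 100 by construction and the curve is non-increasing.
#'
#' @param events Event times in hours (numeric vector, or a tibble with an
#'   `event_time_h` column such as [call_apoptosis_events()] output).
#'   `Inf`/`NA` entries are ignored.
#' @param n_alive_t0 Number of cells alive at acquisition start, `> 0`.
#' @param duration_h Acquisition span; windows cover `[0, duration_h]`.
#' @param window_h Window length, default 10 h.
#' @return Tibble `t_n`, `alive`, `survival_pct`.
#' @export
survival_curve <- function(events, n_alive_t0, duration_h, window_h = 10) {
  if (n_alive_t0 <= 0) abort("n_alive_t0 must be > 0")
  t <- event_times_from(events)
  t <- t[is.finite(t)]
  if (any(t < 0) || any(t > duration_h)) abort("event times must lie in [0, duration_h]")
  if (length(t) > n_alive_t0) abort("more events than cells alive at t0")
  t_n <- seq(0, duration_h, by = window_h)
  cum <- vapply(t_n, function(tn) sum(t > 0 & t <= tn), numeric(1))
  tibble(t_n = t_n,
         alive = n_alive_t0 - cum,
         survival_pct = (n_alive_t0 - cum) / n_alive_t0 * 100)
}

#' Windowed apoptosis-rate curve
#'
#' The apoptosis rate of window `(t_n, t_n + window_h]` is the number of
#' events inside the window divided by the number of cells alive at `t_n`,
#' times 100. Windows whose denominator is zero (all cells already dead)
#' yield `NA` with a warning, not 0: the printed formula is undefined there.
#'
#' @inheritParams survival_curve
#' @param alive Optional per-window alive counts; when given they are checked
#'   against the event record, otherwise they are derived from it.
#' @return Tibble `t_n`, `alive`, `events_in_window`, `rate_pct`.
#' @export
apoptosis_rate_curve <- function(events, n_alive_t0, duration_h, window_h = 10,
                                 alive = NULL) {
  if (n_alive_t0 <= 0) abort("n_alive_t0 must be > 0")
  t <- event_times_from(events)
  t <- t[is.finite(t)]
  if (length(t) > n_alive_t0) abort("more events than cells alive at t0")
  t_n <- seq(0, duration_h, by = window_h)
  t_n <- t_n[t_n < duration_h | length(t_n) == 1L]
  cum <- vapply(t_n, function(tn) sum(t > 0 & t <= tn), numeric(1))
  alive_derived <- n_alive_t0 - cum
  if (!is.null(alive)) {
    if (any(alive < 0)) abort("alive counts must be non-negative")
    if (!isTRUE(all.equal(as.numeric(alive), as.numeric(alive_derived))))
      abort("alive counts are inconsistent with the event record")
  }
  ev_in <- vapply(t_n, function(tn) sum(t > tn & t <= tn + window_h), numeric(1))
  rate <- ifelse(alive_derived > 0, ev_in / alive_derived * 100, NA_real_)
  if (any(alive_derived == 0))
    warn("apoptosis rate undefined for windows with no cells alive at the window start")
  tibble(t_n = t_n, alive = alive_derived,
         events_in_window = ev_in, rate_pct = rate)
}

#' Combined kinetics table for one video
#'
#' Joins [survival_curve()] and [apoptosis_rate_curve()] on the window start
#' and stamps condition/video identifiers, giving the per-video table the
#' paired condition comparison consumes.
#'
#' @inheritParams survival_curve
#' @param condition,video Identifier columns stamped onto the result.
#' @return Tibble `condition`, `video`, `t_n`, `alive`, `events_in_window`,
#'   `survival_pct`, `rate_pct`.
#' @export
kinetics_table <- function(events, n_alive_t0, duration_h, window_h = 10,
                           condition = NA_character_, video = NA_character_) {
  s <- survival_curve(events, n_alive_t0, duration_h, window_h)
  r <- apoptosis_rate_curve(events, n_alive_t0, duration_h, window_h)
  out <- left_join(s, select(r, "t_n", "events_in_window", "rate_pct"), by = "t_n")
  mutate(out, condition = condition, video = video, .before = 1L)
}

# Exact sign-flip (signed-rank) distribution by dynamic programming over
# doubled ranks (integers even under midranks); exact for any n, with ties
# and zero differences handled by the standard reduction.
signflip_wilcoxon <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p_value = 1, n = 0L, method = "exact sign-flip"))
  r2 <- as.integer(round(2 * rank(abs(d))))   # doubled midranks are integers
  W2 <- sum(r2[d > 0])
  tot <- sum(r2)
  # distribution of sum of a random subset of r2 (each included w.p. 1/2)
  f <- numeric(tot + 1L); f[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), f[seq_len(tot + 1L - r)])
    f <- f + shifted
  }
  f <- f / 2^n
  p_ge <- sum(f[(W2 + 1L):(tot + 1L)])
  p_le <- sum(f[1L:(W2 + 1L)])
  p <- switch(alternative,
              greater = p_ge, less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  list(statistic = W2 / 2, p_value = p, n = n, method = "exact sign-flip")
}

#' Paired comparison of kinetics between two conditions
#'
#' Performs, per time window, a Wilcoxon matched-pair signed-rank test
#' between two conditions with replicate videos matched by identifier
#' (coculture vs monoculture videos from the same experiment, in the
#' intended use). With `n <= 25` pairs the exact sign-flip distribution of
#' the signed-rank statistic is enumerated (replicate counts of 3-6 videos
#' make the normal approximation meaningless); identical pairs give
#' statistic 0 and p = 1. Larger n falls back to [stats::wilcox.test()].
#'
#' @param a,b Kinetics tables (see [kinetics_table()]) for the two
#'   conditions, with matching `video` replicates; or plain tibbles with the
#'   columns named in `by` and `value`.
#' @param value Column compared, e.g. `"survival_pct"` or `"rate_pct"`.
#' @param by Matching keys; the first element is the window variable, the
#'   remainder identify replicates.
#' @param alternative `"two.sided"` (default), `"greater"` (a above b) or
#'   `"less"`.
#' @return Tibble of class `toc_paired_test`: `t_n`, `n_pairs`, `statistic`,
#'   `p_value`, `direction` (median paired difference a - b), `method`.
#' @export
compare_conditions <- function(a, b, value = "survival_pct",
                               by = c("t_n", "video"),
                               alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  for (tb in list(a, b))
    if (!all(c(by, value) %in% names(tb)))
      abort("kinetics tables need the matching and value columns")
  keys <- by[1L]
  m <- dplyr::inner_join(
    select(a, dplyr::all_of(c(by, value))),
    select(b, dplyr::all_of(c(by, value))),
    by = by, suffix = c("_a", "_b"))
  if (nrow(m) == 0L) abort("no matched replicates between the two tables")
  n_a <- nrow(select(a, dplyr::all_of(by)))
  if (nrow(m) != n_a || nrow(m) != nrow(select(b, dplyr::all_of(by))))
    abort("replicates are not fully matched between conditions")
  va <- paste0(value, "_a"); vb <- paste0(value, "_b")
  out <- m %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(
      n_pairs = sum(!is.na(.data[[va]]) & !is.na(.data[[vb]])),
      res = list(if (n_pairs[1L] <= 25L)
        signflip_wilcoxon(.data[[va]], .data[[vb]], alternative)
        else {
          w <- suppressWarnings(stats::wilcox.test(
            .data[[va]], .data[[vb]], paired = TRUE, exact = FALSE,
            alternative = alternative))
          list(statistic = unname(w$statistic), p_value = w$p.value,
               method = "wilcox.test normal approx")
        }),
      direction = median(.data[[va]] - .data[[vb]], na.rm = TRUE),
      .groups = "drop") %>%
    mutate(statistic = vapply(.data$res, `[[`, numeric(1), "statistic"),
           p_value = vapply(.data$res, `[[`, numeric(1), "p_value"),
           method = vapply(.data$res, `[[`, character(1), "method")) %>%
    select(-"res")
  class(out) <- c("toc_paired_test", class(out))
  attr(out, "value") <- value
  attr(out, "alternative") <- alternative
  out
}
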
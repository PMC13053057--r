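# broom-style accessors and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_step
#'   facet_wrap labs stat_ecdf theme_bw
#' @export
ggplot2::autoplot

#' Tidy the kiss-of-life stratification
#'
#' @param x A `kiss_of_life` object from [stratify_by_fate()].
#' @param ... Unused.
#' @return One row per proximity parameter with strata sizes, medians, the
#'   KS statistic, the cell-permutation p-value and the naive iid p-value.
#' @export
tidy.kiss_of_life <- function(x, ...) x$tests

#' @rdname tidy.kiss_of_life
#' @export
glance.kiss_of_life <- function(x, ...) {
  cells <- dplyr::distinct(x$samples, .data$label, .data$fate)
  tibble(n_cells = nrow(cells),
         n_dead = sum(cells$fate == "dead"),
         n_alive = sum(cells$fate == "alive"),
         early_start_h = x$params$early_window_h[1L],
         early_end_h = x$params$early_window_h[2L],
         n_perm = x$params$n_perm)
}

#' @rdname tidy.kiss_of_life
#' @param object A `kiss_of_life` object.
#' @export
autoplot.kiss_of_life <- function(object, ...) {
  ggplot(object$samples, aes(x = .data$value, colour = .data$fate)) +
    stat_ecdf() +
    facet_wrap(~parameter, scales = "free_x") +
    labs(x = "early-window measurement", y = "ECDF",
         colour = "fate at horizon") +
    theme_bw()
}

#' Tidy a paired condition comparison
#'
#' @param x A `toc_paired_test` from [compare_conditions()].
#' @param ... Unused.
#' @export
tidy.toc_paired_test <- function(x, ...) as_tibble(unclass(x))

#' @rdname tidy.toc_paired_test
#' @export
glance.toc_paired_test <- function(x, ...) {
  tibble(n_windows = nrow(x),
         n_significant_05 = sum(x$p_value < 0.05, na.rm = TRUE),
         min_p = min(x$p_value, na.rm = TRUE),
         value = attr(x, "value"),
         alternative = attr(x, "alternative"))
}

#' Plot windowed kinetics curves
#'
#' @param kinetics A kinetics tibble (see [kinetics_table()]), possibly
#'   covering several conditions/videos.
#' @param value `"survival_pct"` or `"rate_pct"`.
#' @return A ggplot object.
#' @export
plot_kinetics <- function(kinetics, value = c("survival_pct", "rate_pct")) {
  value <- match.arg(value)
  has_cond <- "condition" %in% names(kinetics) && !all(is.na(kinetics$condition))
  p <- ggplot(kinetics, aes(x = .data$t_n, y = .data[[value]])) +
    labs(x = "window start (h)",
         y = if (value == "survival_pct") "survival (%)" else "apoptosis rate (%)") +
    theme_bw()
  if (has_cond) {
    grp <- interaction(kinetics$condition, kinetics$video %||% 1)
    p + geom_step(aes(colour = .data$condition, group = !!grp))
  } else p + geom_step()
}
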
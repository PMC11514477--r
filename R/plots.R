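#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a loading-coefficient time curve
#'
#' @param object A [loading_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xirep_loading_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time_point, y = .data$value,
                               colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "G1 time point",
                  y = sprintf("%s loading coefficient (control t1 = 1)",
                              attr(object, "target")),
                  colour = "condition") +
    ggplot2::theme_minimal()
}

#' Plot an RPA coefficient-of-variation time course
#'
#' @param object A [rpa_cv_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xirep_cv_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$time_min, y = .data$cv_norm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)",
                  y = "cV (normalised to pretreatment)") +
    ggplot2::theme_minimal()
}

#' Plot a FISH radial line profile
#'
#' @param object A [fish_line_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xirep_line_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$distance_um,
                               y = .data$intensity_norm)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "background"),
                        linetype = "dashed") +
    ggplot2::labs(x = "distance from scaffold border (um)",
                  y = "FISH intensity (max = 1)") +
    ggplot2::theme_minimal()
}

#' Plot per-condition metric summaries
#'
#' Bar-and-error (mean +/- SEM) panels per metric.
#'
#' @param object A [build_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xirep_report <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$mean,
                                   fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
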
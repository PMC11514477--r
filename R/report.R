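#' Significance stars for a p-value
#'
#' The printed star bands: `n.s.` for p >= 0.05, `*` for p in
#' [0.005, 0.05), `**` for p in [0.0005, 0.005), `***` for p < 0.0005.
#'
#' @param p P-value(s).
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.0005 ~ "***",
    p < 0.005 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "n.s.")
}

#' Rank-based two-group comparison
#'
#' Wilcoxon rank test between two samples with the star bands used
#' throughout the figures. The unpaired (Mann-Whitney) form is the
#' default since group sizes usually differ; a paired variant is
#' available. P-values are exact for combined n <= `exact_max_n`
#' without ties, normal-approximated with continuity and tie correction
#' otherwise.
#'
#' @param values_a,values_b Numeric samples (>= 3 values each).
#' @param paired Use the paired signed-rank form (requires equal
#'   lengths).
#' @param exact_max_n Combined-size limit for exact p-values.
#' @return A `xirep_group_compare` list: `statistic`, `p_value`,
#'   `stars`, `method`, `n_a`, `n_b`.
#' @examples
#' group_compare(rnorm(10), rnorm(10, 2))
#' @export
group_compare <- function(values_a, values_b, paired = FALSE,
                          exact_max_n = 25) {
  if (length(values_a) < 3L || length(values_b) < 3L) {
    stop("each sample needs >= 3 values", call. = FALSE)
  }
  exact <- (length(values_a) + length(values_b)) <= exact_max_n
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, paired = paired,
                       exact = exact, correct = TRUE))
  structure(list(statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 stars = significance_stars(ht$p.value),
                 method = ht$method,
                 n_a = length(values_a), n_b = length(values_b)),
            class = "xirep_group_compare")
}

#' @export
print.xirep_group_compare <- function(x, ...) {
  cat(sprintf("%s: W = %g, p = %.4g %s (n = %d, %d)\n", x$method,
              x$statistic, x$p_value, x$stars, x$n_a, x$n_b))
  invisible(x)
}

#' Assemble a per-metric summary report
#'
#' One row per (metric, condition) with N, mean, SD, SEM and 95% CI, and
#' — when a control condition is named — a rank-based comparison of each
#' condition against the control.
#'
#' @param metrics Long tibble with columns `metric, condition, value`.
#' @param control Optional control condition label; must be present in
#'   the data when given.
#' @return A `xirep_report` tibble.
#' @export
build_report <- function(metrics, control = NULL) {
  stopifnot(all(c("metric", "condition", "value") %in% names(metrics)))
  if (!is.null(control) && !control %in% metrics$condition) {
    stop("control condition '", control, "' missing from the data",
         call. = FALSE)
  }
  summ <- metrics |>
    dplyr::group_by(.data$metric, .data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      .groups = "drop") |>
    dplyr::mutate(
      sem = .data$sd / sqrt(.data$n),
      ci_lo = .data$mean - stats::qt(0.975, pmax(.data$n - 1, 1)) *
        .data$sem,
      ci_hi = .data$mean + stats::qt(0.975, pmax(.data$n - 1, 1)) *
        .data$sem)
  if (!is.null(control)) {
    cmp <- function(metric, condition) {
      if (condition == control) return(NA_real_)
      a <- metrics$value[metrics$metric == metric &
                           metrics$condition == condition]
      b <- metrics$value[metrics$metric == metric &
                           metrics$condition == control]
      if (length(a) < 3L || length(b) < 3L) return(NA_real_)
      group_compare(a, b)$p_value
    }
    summ$p_value <- mapply(cmp, summ$metric, summ$condition)
    summ$stars <- ifelse(is.na(summ$p_value), "",
                         significance_stars(summ$p_value))
  }
  summ <- dplyr::arrange(summ, .data$metric, .data$condition)
  structure(summ, class = c("xirep_report", class(summ)),
            control = control)
}

#' Write a report to CSV (byte-stable for fixed inputs)
#'
#' @param report A [build_report()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  readr::write_csv(as.data.frame(report), path)
  invisible(path)
}
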
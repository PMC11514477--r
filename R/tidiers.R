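#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fork-speed model
#'
#' @param x A [fork_speed_model()].
#' @param ... Unused.
#' @return Tibble of model terms and values.
#' @export
tidy.xirep_fork_speed_model <- function(x, ...) {
  tibble::tibble(
    term = c("length_bp", "duration_min", "n_origins", "forks", "waves"),
    value = c(x$length_bp, x$duration_min, x$n_origins,
              x$n_origins * (if (x$bidirectional) 2 else 1), x$waves))
}

#' One-row summary of a fork-speed model
#'
#' @param x A [fork_speed_model()].
#' @param ... Unused.
#' @return Tibble with the fork speed (full precision and rounded to 2
#'   significant figures, the presentation convention).
#' @export
glance.xirep_fork_speed_model <- function(x, ...) {
  sp <- fork_speed(x)
  tibble::tibble(fork_speed_nt_min = sp,
                 fork_speed_2sf = signif(sp, 2))
}

#' Tidy a two-group comparison
#'
#' @param x A [group_compare()] result.
#' @param ... Unused.
#' @return One-row tibble `statistic, p_value, stars, method, n_a, n_b`.
#' @export
tidy.xirep_group_compare <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 stars = x$stars, method = x$method, n_a = x$n_a,
                 n_b = x$n_b)
}

#' Tidy a loading curve
#'
#' @param x A [loading_curve()].
#' @param ... Unused.
#' @return The underlying tibble with target/scope metadata columns.
#' @export
tidy.xirep_loading_curve <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  out$target <- attr(x, "target")
  out$scope <- attr(x, "scope")
  out
}
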
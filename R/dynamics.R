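#' Duration of the synchronous Xi replication pattern
#'
#' Length of the contiguous `xi_pattern` run in a per-cell frame-label
#' sequence, in minutes. Runs touching the first or last frame are
#' censored (flagged via attribute); multiple disjoint runs are an error
#' (reported, never silently merged).
#'
#' @param labels Character vector of frame labels for one cell.
#' @param frame_interval_min Minutes between frames.
#' @return Minutes (0 when no `xi_pattern` frame exists), with attribute
#'   `"censored"`.
#' @examples
#' xi_persistence_minutes(c("early", rep("xi_pattern", 4), "late"), 20)
#' @export
xi_persistence_minutes <- function(labels, frame_interval_min = 20) {
  r <- rle(labels == "xi_pattern")
  runs <- r$lengths[r$values]
  if (length(runs) > 1L) {
    stop("ambiguous: ", length(runs), " disjoint xi_pattern runs",
         call. = FALSE)
  }
  if (length(runs) == 0L) {
    return(structure(0, censored = FALSE))
  }
  censored <- labels[1] == "xi_pattern" ||
    labels[length(labels)] == "xi_pattern"
  structure(runs * frame_interval_min, censored = censored)
}

#' Cohort Xi-pattern persistence
#'
#' Per-cell persistence over a tidy label table; censored runs (pattern
#' present in the first or last frame) are excluded from means by
#' default.
#'
#' @param labels Tibble `cell_id, frame, label` as from
#'   [make_timelapse_labels()].
#' @param frame_interval_min Minutes between frames.
#' @param drop_censored Exclude censored runs from the summary.
#' @return Tibble `cell_id, frames, minutes, censored` with attribute
#'   `"mean_minutes"`.
#' @export
xi_persistence <- function(labels, frame_interval_min = 20,
                           drop_censored = TRUE) {
  out <- labels |>
    dplyr::arrange(.data$cell_id, .data$frame) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(minutes = as.numeric(
      xi_persistence_minutes(.data$label, frame_interval_min)),
      censored = attr(xi_persistence_minutes(.data$label,
                                             frame_interval_min),
                      "censored"),
      .groups = "drop") |>
    dplyr::mutate(frames = .data$minutes / frame_interval_min)
  use <- if (drop_censored) !out$censored else rep(TRUE, nrow(out))
  structure(out[, c("cell_id", "frames", "minutes", "censored")],
            mean_minutes = mean(out$minutes[use]))
}

#' Time from S-phase start to Xi replication onset
#'
#' @param labels Character frame labels for one cell.
#' @param frame_interval_min Minutes between frames.
#' @return Minutes from the first S frame to the first `xi_pattern`
#'   frame.
#' @export
xi_onset_minutes <- function(labels, frame_interval_min = 20) {
  s_lab <- c("early", "xi_pattern", "late")
  s0 <- match(TRUE, labels %in% s_lab)
  x0 <- match(TRUE, labels == "xi_pattern")
  if (is.na(s0) || is.na(x0)) {
    stop("sequence lacks an S-phase or xi_pattern start", call. = FALSE)
  }
  if (x0 < s0) {
    stop("xi_pattern precedes the S-phase start", call. = FALSE)
  }
  (x0 - s0) * frame_interval_min
}

#' Population doubling time from a growth series
#'
#' The growth rate is `log2(nx/n0)/t` (doublings per hour, between the
#' first and last counts); the doubling time is its reciprocal,
#' `t / log2(nx/n0)` hours. Both are returned.
#'
#' @param series Tibble `t_h, cell_count` (e.g. [make_growth_table()]).
#' @return One-row tibble `doubling_time_h, rate_per_h`.
#' @examples
#' doubling_time(make_growth_table(2e5, 24, 4))
#' @export
doubling_time <- function(series) {
  stopifnot(all(c("t_h", "cell_count") %in% names(series)))
  series <- series[order(series$t_h), ]
  n0 <- series$cell_count[1]
  nx <- series$cell_count[nrow(series)]
  dt <- series$t_h[nrow(series)] - series$t_h[1]
  if (nx <= n0 || dt <= 0) {
    stop("undefined doubling time: no net growth", call. = FALSE)
  }
  rate <- log2(nx / n0) / dt
  tibble::tibble(doubling_time_h = 1 / rate, rate_per_h = rate)
}

#' S-phase duration from doubling time and S-phase fraction
#'
#' Doubling time multiplied by the fraction of cells in S phase.
#'
#' @param doubling_time_h Hours per population doubling.
#' @param fraction_s Fraction of cells in S, in `[0, 1]`.
#' @return Hours.
#' @export
sphase_duration <- function(doubling_time_h, fraction_s) {
  if (fraction_s < 0 || fraction_s > 1) {
    stop("`fraction_s` must lie in [0, 1]", call. = FALSE)
  }
  doubling_time_h * fraction_s
}

#' Replication fork-speed arithmetic model
#'
#' The Xi fork-speed estimate from chromosome length, replication
#' duration, the number of simultaneously active origins, fork
#' bidirectionality and the number of consecutive origin-activation
#' waves: `speed = L / (T * forks * waves)` with
#' `forks = N * 2` for bidirectional origins. Defaults describe the
#' mouse X chromosome (171.03 Mb) replicated in 80 min by 138
#' bidirectional origins in a single wave.
#'
#' @param length_bp Chromosome length in base pairs.
#' @param duration_min Replication duration in minutes.
#' @param n_origins Simultaneously active origins.
#' @param bidirectional Two forks per origin?
#' @param waves Consecutive origin-activation waves (>= 1).
#' @return A `xirep_fork_speed_model`.
#' @examples
#' fork_speed(fork_speed_model())
#' @export
fork_speed_model <- function(length_bp = 171.03e6, duration_min = 80,
                             n_origins = 138, bidirectional = TRUE,
                             waves = 1) {
  if (any(c(length_bp, duration_min, n_origins, waves) <= 0)) {
    stop("all model parameters must be positive", call. = FALSE)
  }
  structure(list(length_bp = length_bp, duration_min = duration_min,
                 n_origins = n_origins,
                 bidirectional = isTRUE(bidirectional), waves = waves),
            class = "xirep_fork_speed_model")
}

#' @export
print.xirep_fork_speed_model <- function(x, ...) {
  cat(sprintf(
    "<fork speed model> L = %.4g Mb, T = %g min, N = %g origin(s)%s, %g wave(s)\n",
    x$length_bp / 1e6, x$duration_min, x$n_origins,
    if (x$bidirectional) " (bidirectional)" else "", x$waves))
  cat(sprintf("  fork speed = %.2g nt/min\n", fork_speed(x)))
  invisible(x)
}

#' Replication fork speed of a model
#'
#' @param model A [fork_speed_model()].
#' @return Nucleotides per minute per fork (full precision; round to 2
#'   significant figures for presentation).
#' @export
fork_speed <- function(model) {
  stopifnot(inherits(model, "xirep_fork_speed_model"))
  forks <- model$n_origins * (if (model$bidirectional) 2 else 1)
  model$length_bp / (model$duration_min * forks * model$waves)
}

#' Origin-number / fork-speed compensation index
#'
#' `(n_kd / n_ctrl) * speed_kd_rel`: the product of the relative origin
#' number and the relative fork speed after a knockdown. A value near 1
#' means the origin loss is exactly compensated by faster forks, leaving
#' the total Xi replication duration unchanged.
#'
#' @param n_kd,n_ctrl Active origin counts (knockdown, control).
#' @param speed_kd_rel Knockdown fork speed relative to control.
#' @return Unitless index.
#' @examples
#' compensation_index(95, 138, 1.43)
#' @export
compensation_index <- function(n_kd, n_ctrl, speed_kd_rel) {
  if (any(c(n_kd, n_ctrl, speed_kd_rel) <= 0)) {
    stop("all inputs must be positive", call. = FALSE)
  }
  (n_kd / n_ctrl) * speed_kd_rel
}

#' Percent change relative to a reference
#'
#' @param value,reference Numeric; `reference` must be non-zero.
#' @return `100 * (value - reference) / reference`.
#' @examples
#' percent_change(52, 80)
#' @export
percent_change <- function(value, reference) {
  if (any(reference == 0)) stop("zero reference", call. = FALSE)
  100 * (value - reference) / reference
}
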
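#' Exact sum intensity over a region
#'
#' The raw integrated density of a channel over the true voxels of a
#' mask.
#'
#' @param image A [voxel_image()].
#' @param channel Channel name.
#' @param mask A [region_mask()] aligned to the image.
#' @return Numeric sum (0 for an empty mask).
#' @export
region_sum <- function(image, channel, mask) {
  arr <- get_channel(image, channel)
  check_aligned(image, mask)
  sum(arr[mask$mask])
}

#' Measure per-region channel statistics for one cell
#'
#' Builds tidy cell records: one row per (region, channel) holding the
#' sum and mean intensity, voxel count and physical size. These long
#' tables are the common currency of all ratio metrics.
#'
#' @param image A [voxel_image()].
#' @param regions Named list of [region_mask()]s, e.g.
#'   `list(nucleus = ..., xi = ...)`.
#' @param cell_id,condition,time_point Identifiers copied into the rows.
#' @param channels Channels to measure (default: all).
#' @return Tibble `cell_id, condition, time_point, region, channel, sum,
#'   mean, voxels, size_um`.
#' @export
measure_regions <- function(image, regions, cell_id = 1L,
                            condition = NA_character_,
                            time_point = NA_real_, channels = NULL) {
  stopifnot(is.list(regions), !is.null(names(regions)))
  channels <- channels %||% names(image$channels)
  out <- list()
  for (rg in names(regions)) {
    m <- regions[[rg]]
    check_aligned(image, m)
    for (ch in channels) {
      arr <- get_channel(image, ch)
      v <- arr[m$mask]
      out[[length(out) + 1L]] <- tibble::tibble(
        cell_id = cell_id, condition = condition, time_point = time_point,
        region = rg, channel = ch, sum = sum(v),
        mean = if (length(v)) mean(v) else NA_real_,
        voxels = length(v), size_um = mask_size(m))
    }
  }
  dplyr::bind_rows(out)
}

records_wide <- function(cells, region, channels) {
  need <- c("cell_id", "region", "channel", "sum")
  stopifnot(all(need %in% names(cells)))
  sub <- cells[cells$region == region & cells$channel %in% channels, ]
  tidyr::pivot_wider(
    sub[, intersect(names(sub),
                    c("cell_id", "condition", "time_point", "channel",
                      "sum"))],
    names_from = "channel", values_from = "sum")
}

#' EdU/PCNA replication progression ratio
#'
#' The total nucleotide signal incorporated during the labelling pulse
#' divided by the total PCNA signal over a region (sum intensities): a
#' per-cell replication progression rate independent of the number of
#' active replisomes. With a `control` condition given, each cell's ratio
#' is additionally normalised by the control mean (`ratio_norm`).
#'
#' @param cells Long records from [measure_regions()] holding EdU and
#'   PCNA sums for `region`.
#' @param region Region to evaluate, typically `"xi"` or `"nucleus"`.
#' @param control Optional control condition label (e.g. `"scramble"`).
#' @return Tibble `cell_id, condition, region, ratio` (+ `ratio_norm`).
#' @export
edu_pcna_ratio <- function(cells, region = "xi", control = NULL) {
  w <- records_wide(cells, region, c("EdU", "PCNA"))
  if (!all(c("EdU", "PCNA") %in% names(w))) {
    stop("EdU and PCNA sums required for region '", region, "'",
         call. = FALSE)
  }
  if (any(w$PCNA <= 0)) {
    stop("undefined EdU/PCNA ratio: zero PCNA sum", call. = FALSE)
  }
  out <- tibble::tibble(cell_id = w$cell_id,
                        condition = w$condition %||% NA_character_,
                        region = region, ratio = w$EdU / w$PCNA)
  if (!is.null(control)) {
    ctrl <- out$ratio[out$condition == control]
    if (!length(ctrl)) stop("control condition '", control,
                            "' absent", call. = FALSE)
    out$ratio_norm <- out$ratio / mean(ctrl)
  }
  out
}

#' Coefficient-of-variation time course of RPA accumulation
#'
#' For each time frame, the coefficient of variation cV = sigma/mu of the
#' channel intensities inside the mask; all values are normalised to the
#' pretreatment frame (frame 1), so `cv_norm[1] = 1`. Focal accumulation
#' of RPA on stalled forks raises sigma faster than mu, so cv_norm grows.
#'
#' @param frames List of [voxel_image()]s, pretreatment first.
#' @param masks A single [region_mask()] or a list (one per frame).
#' @param channel Channel to evaluate (default `"RPA"`).
#' @param time_points_min Optional frame times in minutes.
#' @param sd_divisor_n Use the population standard deviation (divisor n,
#'   default) or the sample one.
#' @return A `xirep_cv_curve` tibble `time_min, cv_raw, cv_norm`.
#' @export
rpa_cv_curve <- function(frames, masks, channel = "RPA",
                         time_points_min = NULL, sd_divisor_n = TRUE) {
  if (length(frames) < 2L) stop("need at least 2 frames", call. = FALSE)
  if (inherits(masks, "region_mask")) {
    masks <- rep(list(masks), length(frames))
  }
  stopifnot(length(masks) == length(frames))
  cv <- vapply(seq_along(frames), function(i) {
    v <- get_channel(frames[[i]], channel)[masks[[i]]$mask]
    mu <- mean(v)
    if (mu == 0) stop("undefined cV: zero mean intensity in frame ", i,
                      call. = FALSE)
    s <- if (sd_divisor_n) sqrt(mean((v - mu)^2)) else stats::sd(v)
    s / mu
  }, numeric(1))
  tp <- time_points_min %||% (seq_along(frames) - 1)
  if (cv[1] == 0) {
    warning("pretreatment cV is zero: cv_norm undefined", call. = FALSE)
    cvn <- rep(NA_real_, length(cv))
  } else {
    cvn <- cv / cv[1]
  }
  structure(tibble::tibble(time_min = tp, cv_raw = cv, cv_norm = cvn),
            class = c("xirep_cv_curve", "tbl_df", "tbl", "data.frame"))
}

#' Pre-RC loading coefficient (double-ROI, DAPI-normalised)
#'
#' On the maximum-intensity projection, the target (Mcm2/ORC1/Cdc6/Cdt1)
#' sum intensity in the Xi ROI is normalised by its DAPI sum, the same is
#' done in the size-matched control ROI outside the Xi, and the two
#' normalised values are divided:
#' `[S(target,ROI1)/S(DAPI,ROI1)] / [S(target,ROI2)/S(DAPI,ROI2)]`.
#'
#' @param image A [voxel_image()] (projected internally).
#' @param target_channel Loading-factor channel, e.g. `"Mcm2"`.
#' @param xi Xi [region_mask()] (ROI1).
#' @param roi2 Control [region_mask()] from [control_roi()].
#' @param dapi_channel DNA counterstain channel.
#' @return Unitless coefficient.
#' @export
loading_coefficient <- function(image, target_channel, xi, roi2,
                                dapi_channel = "DAPI") {
  proj <- max_project(image)
  m1 <- max_project(xi)
  m2 <- max_project(roi2)
  s <- c(region_sum(proj, target_channel, m1),
         region_sum(proj, dapi_channel, m1),
         region_sum(proj, target_channel, m2),
         region_sum(proj, dapi_channel, m2))
  if (any(s <= 0)) {
    stop("undefined loading coefficient: zero ROI sum", call. = FALSE)
  }
  (s[1] / s[2]) / (s[3] / s[4])
}

#' Loading-coefficient time curves normalised to control at t1
#'
#' Per-(condition, time point) mean loading coefficient divided by the
#' control-condition mean at the earliest time point.
#'
#' @param cells Tibble with columns `condition`, `time_point`,
#'   `coefficient` (one row per cell).
#' @param control Control condition label anchoring the normalisation.
#' @param target,scope Metadata recorded on the curve (e.g. `"Mcm2"`,
#'   `"xi"`).
#' @return A `xirep_loading_curve` tibble `condition, time_point, n,
#'   mean_raw, value` where `value` is the normalised mean.
#' @export
loading_curve <- function(cells, control = "scramble", target = "Mcm2",
                          scope = "xi") {
  stopifnot(all(c("condition", "time_point", "coefficient") %in%
                  names(cells)))
  if (length(unique(cells$time_point)) < 2L) {
    stop("need >= 2 time points", call. = FALSE)
  }
  t1 <- min(cells$time_point)
  anchor <- cells$coefficient[cells$condition == control &
                                cells$time_point == t1]
  if (!length(anchor)) {
    stop("normalisation anchor missing: no '", control,
         "' cells at the first time point", call. = FALSE)
  }
  out <- cells |>
    dplyr::group_by(.data$condition, .data$time_point) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_raw = mean(.data$coefficient),
                     .groups = "drop") |>
    dplyr::mutate(value = .data$mean_raw / mean(anchor)) |>
    dplyr::arrange(.data$condition, .data$time_point)
  structure(out, class = c("xirep_loading_curve", class(out)),
            target = target, scope = scope, control = control)
}

#' Per-cell sum(target)/sum(DAPI) over the nucleus
#'
#' The nuclear loading variant: target sum intensity normalised by the
#' DAPI sum over the whole nucleus, one value per cell.
#'
#' @param cells Long records from [measure_regions()].
#' @param target Target channel name.
#' @param region Region to evaluate (default `"nucleus"`).
#' @return Tibble `cell_id, condition, time_point, coefficient`.
#' @export
nuclear_loading <- function(cells, target = "Mcm2", region = "nucleus") {
  w <- records_wide(cells, region, c(target, "DAPI"))
  if (any(w$DAPI <= 0)) stop("zero DAPI sum", call. = FALSE)
  tibble::tibble(cell_id = w$cell_id, condition = w$condition,
                 time_point = w$time_point,
                 coefficient = w[[target]] / w$DAPI)
}

#' PLA spot density per DNA amount
#'
#' Spots divided by the DAPI sum intensity of the region; densities are
#' normalised by the control condition's mean nuclear density, so a
#' cell's normalised Xi density is its Xi fold-enrichment.
#'
#' @param cells Tibble with columns `cell_id, condition, region, spots,
#'   dapi_sum` (regions `"nucleus"` and optionally `"xi"`).
#' @param control Control condition label.
#' @return Input tibble with `density` and `density_norm` columns.
#' @export
pla_density <- function(cells, control = "scramble") {
  stopifnot(all(c("cell_id", "condition", "region", "spots", "dapi_sum")
                %in% names(cells)))
  if (any(cells$dapi_sum <= 0)) {
    stop("undefined PLA density: zero DAPI sum", call. = FALSE)
  }
  cells$density <- cells$spots / cells$dapi_sum
  ref <- cells$density[cells$condition == control &
                         cells$region == "nucleus"]
  if (!length(ref)) {
    stop("control condition '", control, "' has no nuclear densities",
         call. = FALSE)
  }
  cells$density_norm <- cells$density / mean(ref)
  cells
}

#' Xi relative area by DAPI share
#'
#' The DAPI sum intensity of the Xi divided by the total nuclear DAPI sum
#' (maximum-intensity projections): the fraction of nuclear DNA signal in
#' the Xi, a proxy for Xi (de)condensation.
#'
#' @param cells Long records from [measure_regions()] holding DAPI sums
#'   for regions `"xi"` and `"nucleus"` (computed on projections).
#' @return Tibble `cell_id, condition, xi_relative_area`.
#' @export
xi_relative_area <- function(cells) {
  xi <- records_wide(cells, "xi", "DAPI")
  nuc <- records_wide(cells, "nucleus", "DAPI")
  keys <- intersect(c("cell_id", "condition", "time_point"),
                    intersect(names(xi), names(nuc)))
  m <- dplyr::inner_join(xi, nuc, by = keys,
                         suffix = c("_xi", "_nucleus"))
  if (any(m$DAPI_xi > m$DAPI_nucleus)) {
    stop("Xi DAPI sum exceeds nuclear DAPI sum: inconsistent masks",
         call. = FALSE)
  }
  tibble::tibble(cell_id = m$cell_id,
                 condition = m$condition %||% NA_character_,
                 xi_relative_area = m$DAPI_xi / m$DAPI_nucleus)
}

#' Control-normalised histone / protein level
#'
#' A region's channel sum (or mean) divided by the average of the control
#' cells — the normalisation used for macroH2A1, H3K27me3, H4K20me,
#' Mcm2 and Mcm2-phosphoS108 levels.
#'
#' @param cells Long records from [measure_regions()].
#' @param channel Channel to evaluate.
#' @param region Region to evaluate.
#' @param control Control condition label.
#' @param statistic `"sum"` (default) or `"mean"` intensities.
#' @return Tibble `cell_id, condition, level` where the control mean is 1.
#' @export
histone_level <- function(cells, channel, region = "xi",
                          control = "scramble", statistic = c("sum",
                                                              "mean")) {
  statistic <- match.arg(statistic)
  sub <- cells[cells$region == region & cells$channel == channel, ]
  if (!nrow(sub)) stop("no records for ", channel, "/", region,
                       call. = FALSE)
  val <- sub[[statistic]]
  ref <- val[sub$condition == control]
  if (!length(ref) || mean(ref) <= 0) {
    stop("zero or missing control mean", call. = FALSE)
  }
  tibble::tibble(cell_id = sub$cell_id, condition = sub$condition,
                 level = val / mean(ref))
}

#' DAPI standard deviation (chromatin texture)
#'
#' Population standard deviation of the DNA-stain intensities inside the
#' nucleus; chromatin decondensation (e.g. hypotonic treatment) smooths
#' the texture and lowers it.
#'
#' @param image A [voxel_image()].
#' @param nucleus Nucleus [region_mask()].
#' @param channel DNA stain channel.
#' @return Numeric standard deviation.
#' @export
dapi_sd <- function(image, nucleus, channel = "DAPI") {
  v <- get_channel(image, channel)[nucleus$mask]
  if (!length(v)) stop("empty nucleus mask", call. = FALSE)
  sqrt(mean((v - mean(v))^2))
}
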
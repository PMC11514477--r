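#' Measure a DNA-halo preparation
#'
#' Segments the bright nuclear scaffold and the total area (scaffold +
#' halo) from a 2D DNA-stain image, then derives the halo area
#' `Ah = At - As`, the halo radius `R = sqrt(Ah / pi)` and the
#' circularity `4*pi*area/perimeter^2` of the total-area contour
#' (Crofton perimeter; digitisation overshoot above 1 is clamped, the
#' raw value is kept in `circularity_raw`).
#'
#' The total area is thresholded above the estimated background (border
#' mean + 3 SD); the scaffold is the triangle threshold restricted to the
#' foreground pixels, where halo and scaffold form the two populations.
#' Both thresholds can be overridden.
#'
#' @param image 2D [voxel_image()] with the DNA channel.
#' @param channel DNA stain channel.
#' @param total_threshold,scaffold_threshold Optional manual thresholds.
#' @return One-row tibble `At_um2, As_um2, Ah_um2, R_um, circularity,
#'   circularity_raw`.
#' @export
measure_halo <- function(image, channel = "DAPI", total_threshold = NULL,
                         scaffold_threshold = NULL) {
  arr <- get_channel(image, channel)
  d <- dim(arr)
  if (d[3] != 1L) stop("halo images must be 2D", call. = FALSE)
  px <- image$voxel_size[["y"]] * image$voxel_size[["x"]]
  if (!is.null(total_threshold) && !is.null(scaffold_threshold) &&
      scaffold_threshold < total_threshold) {
    stop("inconsistent thresholds: the scaffold threshold must not lie ",
         "below the total-area threshold (As would exceed At)",
         call. = FALSE)
  }
  border <- c(arr[1, , 1], arr[d[1], , 1], arr[, 1, 1], arr[, d[2], 1])
  tt <- total_threshold %||% (mean(border) + 3 * stats::sd(border))
  total <- arr > tt
  if (!any(total)) stop("no foreground above the total threshold",
                        call. = FALSE)
  lab <- cc_label_cpp(total, d, 26L)
  total <- lab == which.max(tabulate(lab[lab > 0L]))
  total <- fill_holes(total)
  st <- scaffold_threshold %||% triangle_thr(arr[total])
  scaffold <- arr > st & total
  if (any(scaffold)) {
    lab <- cc_label_cpp(scaffold, d, 26L)
    scaffold <- lab == which.max(tabulate(lab[lab > 0L]))
    scaffold <- fill_holes(scaffold)
  }
  At <- sum(total) * px
  As <- sum(scaffold) * px
  if (As > At) {
    stop("inconsistent thresholds: scaffold area exceeds total area",
         call. = FALSE)
  }
  Ah <- At - As
  per <- crofton_perimeter(total[, , 1], image$voxel_size[["y"]])
  circ_raw <- 4 * pi * At / per^2
  tibble::tibble(At_um2 = At, As_um2 = As, Ah_um2 = Ah,
                 R_um = sqrt(Ah / pi),
                 circularity = min(1, circ_raw),
                 circularity_raw = circ_raw)
}

# Cauchy-Crofton perimeter with 4 directions: P = (pi/8) * sum of
# direction widths, estimated from boundary-crossing counts along rows,
# columns and both diagonals (diagonal line spacing h = px/sqrt(2)).
crofton_perimeter <- function(m, px) {
  m <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  nr <- nrow(m); nc <- ncol(m)
  n_h <- sum(m[, -1] != m[, -nc])
  n_v <- sum(m[-1, ] != m[-nr, ])
  n_d1 <- sum(m[-1, -1] != m[-nr, -nc])
  n_d2 <- sum(m[-1, -nc] != m[-nr, -1])
  (pi / 8) * (n_h + n_v + (n_d1 + n_d2) / sqrt(2)) * px
}

#' Compare halo radii across conditions
#'
#' Per-condition mean halo radius and circularity, the ratio of each
#' condition's mean radius to the control, and a rank-based two-group
#' test against the control (reported, not asserted).
#'
#' @param halos Tibble of per-cell [measure_halo()] rows with a
#'   `condition` column.
#' @param control Control condition label.
#' @param min_cells Minimum cells per condition.
#' @return Tibble `condition, n, mean_R_um, mean_circularity,
#'   radius_ratio, p_value`.
#' @export
compare_halo_radii <- function(halos, control = "scramble",
                               min_cells = 5) {
  stopifnot(all(c("condition", "R_um") %in% names(halos)))
  conds <- unique(halos$condition)
  if (length(conds) < 2L) {
    stop("need >= 2 conditions to compare", call. = FALSE)
  }
  cnt <- table(halos$condition)
  if (any(cnt < min_cells)) {
    stop("every condition needs >= ", min_cells, " cells", call. = FALSE)
  }
  if (!control %in% conds) stop("control condition absent", call. = FALSE)
  ctrl_r <- halos$R_um[halos$condition == control]
  halos |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_R_um = mean(.data$R_um),
      mean_circularity = if ("circularity" %in% names(halos))
        mean(.data$circularity) else NA_real_,
      p_value = if (.data$condition[1] == control) NA_real_ else
        group_compare(.data$R_um, ctrl_r)$p_value,
      .groups = "drop") |>
    dplyr::mutate(radius_ratio = .data$mean_R_um / mean(ctrl_r))
}

bilinear <- function(arr2, y, x) {
  nr <- nrow(arr2); nc <- ncol(arr2)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  y0 <- pmin(pmax(y0, 1L), nr); x0 <- pmin(pmax(x0, 1L), nc)
  y1 <- pmin(y0 + 1L, nr); x1 <- pmin(x0 + 1L, nc)
  arr2[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    arr2[cbind(y1, x0)] * fy * (1 - fx) +
    arr2[cbind(y0, x1)] * (1 - fy) * fx +
    arr2[cbind(y1, x1)] * fy * fx
}

#' FISH radial line profile from the nuclear scaffold border
#'
#' Casts rays outward from evenly spaced points on the scaffold boundary
#' (direction: from the scaffold centroid through the boundary point,
#' i.e. approximately normal to the border for near-convex scaffolds),
#' samples the FISH channel along each ray, averages across rays and
#' max-normalises per cell, with distance 0 at the scaffold border.
#' Background is estimated from seeded random line profiles in areas
#' without cells.
#'
#' @param image 2D [voxel_image()] with a FISH channel.
#' @param scaffold Scaffold [region_mask()].
#' @param length_um Ray length in um (default 30).
#' @param n_lines Number of rays.
#' @param seed Seed for the background line placement.
#' @param channel FISH channel name.
#' @param step_um Sampling step along the ray.
#' @param report_to_um Report the profile from 0 to this distance.
#' @return A `xirep_line_profile` tibble `distance_um, intensity_norm`
#'   with attribute `"background"` (mean off-cell level on the same
#'   normalised scale).
#' @export
fish_line_profile <- function(image, scaffold, length_um = 30,
                              n_lines = 36, seed = 1, channel = "FISH",
                              step_um = 0.1, report_to_um = 20) {
  if (length_um <= 0) stop("`length_um` must be > 0", call. = FALSE)
  if (sum(scaffold$mask) == 0L) stop("empty scaffold mask", call. = FALSE)
  arr <- get_channel(image, channel)
  d <- dim(arr)
  if (d[3] != 1L) stop("line profiles need a 2D image", call. = FALSE)
  a2 <- arr[, , 1]
  px <- image$voxel_size[["y"]]
  m <- scaffold$mask[, , 1]
  # boundary pixels: in mask with at least one 4-neighbour outside
  pad <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  inner <- pad[-c(1, nrow(pad)), -c(1, ncol(pad))]
  shifted <- pad[-c(1, 2), -c(1, ncol(pad))] &
    pad[-c(nrow(pad) - 1, nrow(pad)), -c(1, ncol(pad))] &
    pad[-c(1, nrow(pad)), -c(1, 2)] &
    pad[-c(1, nrow(pad)), -c(ncol(pad) - 1, ncol(pad))]
  bnd <- which(inner & !shifted, arr.ind = TRUE)
  ctr <- colMeans(which(m, arr.ind = TRUE))
  ang <- atan2(bnd[, 1] - ctr[1], bnd[, 2] - ctr[2])
  ord <- order(ang)
  take <- ord[round(seq(1, length(ord), length.out = n_lines + 1))[-1]]
  dists <- seq(0, length_um, by = step_um)
  prof <- matrix(NA_real_, length(take), length(dists))
  truncated <- FALSE
  for (i in seq_along(take)) {
    p0 <- bnd[take[i], ]
    dir <- (p0 - ctr) / sqrt(sum((p0 - ctr)^2))
    yy <- p0[1] + dir[1] * dists / px
    xx <- p0[2] + dir[2] * dists / px
    ok <- yy >= 1 & yy <= d[1] & xx >= 1 & xx <= d[2]
    if (!all(ok)) truncated <- TRUE
    prof[i, ok] <- bilinear(a2, yy[ok], xx[ok])
  }
  if (truncated) {
    warning("some rays left the image bounds and were truncated",
            call. = FALSE)
  }
  avg <- colMeans(prof, na.rm = TRUE)
  mx <- max(avg, na.rm = TRUE)
  if (mx <= 0) stop("no FISH signal along the rays", call. = FALSE)
  # background: random rays fully outside the cell (below the off-cell
  # intensity criterion)
  off <- a2 <= (mean(c(a2[1, ], a2[nrow(a2), ])) +
                  3 * stats::sd(c(a2[1, ], a2[nrow(a2), ])) + 1e-9)
  bg <- withr::with_seed(seed, {
    cand <- which(off, arr.ind = TRUE)
    if (nrow(cand) < 10L) {
      stop("no off-cell area available for background estimation",
           call. = FALSE)
    }
    vals <- c()
    for (i in seq_len(10L)) {
      p0 <- cand[sample.int(nrow(cand), 1L), ]
      th <- stats::runif(1, 0, 2 * pi)
      yy <- p0[1] + sin(th) * dists / px
      xx <- p0[2] + cos(th) * dists / px
      ok <- yy >= 1 & yy <= d[1] & xx >= 1 & xx <= d[2] &
        off[cbind(pmin(pmax(round(yy), 1), d[1]),
                  pmin(pmax(round(xx), 1), d[2]))]
      vals <- c(vals, bilinear(a2, yy[ok], xx[ok]))
    }
    mean(vals) / mx
  })
  keep <- dists <= report_to_um
  structure(tibble::tibble(distance_um = dists[keep],
                           intensity_norm = avg[keep] / mx),
            class = c("xirep_line_profile", "tbl_df", "tbl",
                      "data.frame"),
            background = bg)
}

#' Morphometrics of a hypotonically swollen 3D nucleus
#'
#' Equivalent-sphere diameter from the voxel volume, surface area from a
#' smoothed-gradient (coarea) estimator, the bounding z extent and the
#' mean lateral (XY) bounding extent — flattened (hypotonically spread)
#' nuclei show a larger lateral extent and a smaller z extent than a
#' sphere of equal volume.
#'
#' @param nucleus 3D [region_mask()].
#' @return One-row tibble `diameter_um, surface_um2, z_extent_um,
#'   lateral_extent_um, volume_um3`.
#' @export
hypotonic_morphometrics <- function(nucleus) {
  m <- nucleus$mask
  if (!any(m)) stop("empty mask", call. = FALSE)
  d <- dim(m)
  vs <- nucleus$voxel_size
  vol <- sum(m) * prod(vs)
  diam <- 2 * (3 * vol / (4 * pi))^(1 / 3)
  # coarea surface: |grad of smoothed indicator| integrated over volume;
  # smoothing is isotropic in physical units (sigma in voxels per axis)
  sg_um <- 1.2 * max(vs)
  sm <- gauss_blur_cpp(array(as.numeric(m), d), d,
                       c(sg_um / vs[["y"]], sg_um / vs[["x"]],
                         if (d[3] > 1L) sg_um / vs[["z"]] else 0))
  gy <- (sm[c(2:d[1], d[1]), , , drop = FALSE] -
           sm[c(1, 1:(d[1] - 1)), , , drop = FALSE]) / (2 * vs[["y"]])
  gx <- (sm[, c(2:d[2], d[2]), , drop = FALSE] -
           sm[, c(1, 1:(d[2] - 1)), , drop = FALSE]) / (2 * vs[["x"]])
  gz <- if (d[3] > 1L) {
    (sm[, , c(2:d[3], d[3]), drop = FALSE] -
       sm[, , c(1, 1:(d[3] - 1)), drop = FALSE]) / (2 * vs[["z"]])
  } else array(0, d)
  surf <- sum(sqrt(gy^2 + gx^2 + gz^2)) * prod(vs)
  zidx <- which(apply(m, 3, any))
  yext <- sum(apply(m, 1, any)) * vs[["y"]]
  xext <- sum(apply(m, 2, any)) * vs[["x"]]
  tibble::tibble(diameter_um = diam, surface_um2 = surf,
                 z_extent_um = length(zidx) * vs[["z"]],
                 lateral_extent_um = (yext + xext) / 2,
                 volume_um3 = vol)
}

#' Nuclear roundness of a 2D projection
#'
#' `4 * area / (pi * major_axis^2)` with the major axis length derived
#' from the second central moments (the Operetta-style roundness
#' readout): 1 for a circle, b/a for an a:b ellipse.
#'
#' @param nucleus 2D [region_mask()] (or a 3D one, projected).
#' @return Unitless roundness in (0, 1].
#' @export
nuclear_roundness <- function(nucleus) {
  m <- max_project(nucleus)$mask[, , 1]
  n <- sum(m)
  if (n < 5L) stop("degenerate mask: too few pixels", call. = FALSE)
  px <- nucleus$voxel_size[["y"]]
  co <- which(m, arr.ind = TRUE) * px
  co <- sweep(co, 2, colMeans(co))
  cv <- crossprod(co) / n + diag(px^2 / 12, 2) # pixel self-moment
  ev <- eigen(cv, symmetric = TRUE)$values
  if (ev[2] <= px^2 / 10) stop("degenerate (line-like) mask",
                               call. = FALSE)
  major <- 4 * sqrt(ev[1])
  area <- n * px * nucleus$voxel_size[["x"]]
  4 * area / (pi * major^2)
}
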
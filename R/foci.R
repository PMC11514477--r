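#' Parameters for 3D foci picking
#'
#' Mirrors the interactive spot-picker parameters: the background
#' intensity around a focus, a tolerance (the minimum intensity range a
#' focus must span before it counts as separate from its neighbour), the
#' minimum voxel count of a focus, and "fraction f" — the brightest
#' percentage of a grown focus region that is kept as the focus body.
#'
#' When `background` or `tolerance` are `NULL`, [pick_foci_3d()] derives
#' them from the data: background = triangle threshold of the channel
#' inside the search mask, tolerance = 10% of the in-mask dynamic range.
#'
#' @param background Background intensity (>= 0) or `NULL`.
#' @param tolerance Minimum intensity range inside a focus (> 0) or
#'   `NULL`.
#' @param minimum_voxels Minimum voxels a focus body must contain.
#' @param fraction_f Brightest percentage of each focus region kept, in
#'   (0, 100].
#' @param min_volume_um3 Volume filter applied by [count_nano_rfi()].
#' @param separate_touching Keep touching foci as separate objects
#'   (watershed basins seeded at their maxima); if `FALSE`, touching
#'   basins are merged into one focus.
#' @param smooth Apply a Gaussian blur (sigma 1 voxel) before picking, as
#'   done to suppress single-pixel noise spikes.
#' @param stretch Linearly stretch in-mask intensities to the 16-bit
#'   range before picking.
#' @return A `foci_params` list.
#' @export
foci_params <- function(background = NULL, tolerance = NULL,
                        minimum_voxels = 2, fraction_f = 50,
                        min_volume_um3 = 0.0002, separate_touching = TRUE,
                        smooth = FALSE, stretch = FALSE) {
  if (!is.null(background) && background < 0) {
    stop("`background` must be >= 0", call. = FALSE)
  }
  if (!is.null(tolerance) && tolerance <= 0) {
    stop("`tolerance` must be > 0", call. = FALSE)
  }
  if (fraction_f <= 0 || fraction_f > 100) {
    stop("`fraction_f` must lie in (0, 100]", call. = FALSE)
  }
  if (min_volume_um3 < 0) stop("`min_volume_um3` must be >= 0",
                               call. = FALSE)
  if (minimum_voxels < 1) stop("`minimum_voxels` must be >= 1",
                               call. = FALSE)
  structure(list(background = background, tolerance = tolerance,
                 minimum_voxels = as.integer(minimum_voxels),
                 fraction_f = fraction_f, min_volume_um3 = min_volume_um3,
                 separate_touching = isTRUE(separate_touching),
                 smooth = isTRUE(smooth), stretch = isTRUE(stretch)),
            class = "foci_params")
}

#' Pick replication foci in a 3D stack by plateau-aware local maxima
#'
#' Detects fluorescent foci inside a search mask: optional Gaussian
#' smoothing and contrast stretch, plateau-aware local maxima above the
#' background (a maximum centre is one voxel or a group of contiguous
#' equal-intensity voxels brighter than all 26-neighbours), watershed
#' region growing from each centre down to the surrounding minima or
#' background, prominence-based merging of maxima whose intensity range
#' is below the tolerance, per-focus retention of the brightest
#' `fraction_f` percent of voxels, and a minimum-voxel filter. Each
#' returned focus corresponds to exactly one maximum centre.
#'
#' @param image A [voxel_image()].
#' @param channel Channel holding the spots (e.g. `"EdU"`).
#' @param mask Search [region_mask()] (e.g. the Xi territory).
#' @param params A [foci_params()].
#' @return Tibble with one row per focus: `focus_id`, centre coordinates
#'   (`z_um,y_um,x_um`), `voxels`, `volume_um3`, `peak_intensity`,
#'   `sum_intensity`.
#' @export
pick_foci_3d <- function(image, channel, mask, params = foci_params()) {
  stopifnot(inherits(params, "foci_params"))
  arr <- get_channel(image, channel)
  check_aligned(image, mask)
  empty <- tibble::tibble(focus_id = integer(), z_um = numeric(),
                          y_um = numeric(), x_um = numeric(),
                          voxels = integer(), volume_um3 = numeric(),
                          peak_intensity = numeric(),
                          sum_intensity = numeric())
  if (!any(mask$mask)) return(empty)
  d <- dim(arr)
  vs <- image$voxel_size
  if (params$smooth) {
    arr <- gauss_blur_cpp(arr, d, c(1, 1, if (d[3] > 1L) 1 else 0))
  }
  inmask <- arr[mask$mask]
  rng <- range(inmask)
  if (diff(rng) == 0) return(empty) # flat field holds no foci
  if (params$stretch && diff(rng) > 0) {
    arr <- (arr - rng[1]) / diff(rng) * 65535
    inmask <- arr[mask$mask]
    rng <- c(0, 65535)
  }
  background <- params$background %||% triangle_thr(inmask)
  tolerance <- params$tolerance %||% (0.1 * diff(rng))
  if (tolerance <= 0) tolerance <- .Machine$double.eps
  pk <- find_peaks_cpp(arr, mask$mask, d, background, tolerance, FALSE)
  lab <- pk$labels
  k <- length(pk$summit)
  if (k == 0L) return(empty)
  if (!params$separate_touching) {
    # merge touching basins into single foci
    merged <- cc_label_cpp(lab > 0L, d, 26L)
    remap <- integer(k)
    for (i in seq_len(k)) {
      remap[i] <- merged[pk$summit_voxel[i]]
    }
    lab[lab > 0L] <- remap[lab[lab > 0L]]
    keep_ids <- sort(unique(remap))
    # representative summit per merged focus = brightest original summit
    reps <- vapply(keep_ids, function(id) {
      cand <- which(remap == id)
      cand[which.max(pk$summit[cand])]
    }, integer(1))
    summit <- pk$summit[reps]
    summit_voxel <- pk$summit_voxel[reps]
    ids <- keep_ids
  } else {
    summit <- pk$summit
    summit_voxel <- pk$summit_voxel
    ids <- seq_len(k)
  }

  vox <- which(lab > 0L)
  by_focus <- split(vox, lab[vox])
  unit <- prod(vs)
  rows <- list()
  for (j in seq_along(ids)) {
    vv <- by_focus[[as.character(ids[j])]]
    if (is.null(vv)) next
    iv <- arr[vv]
    n_keep <- max(1L, ceiling(params$fraction_f / 100 * length(vv)))
    keep <- vv[order(iv, decreasing = TRUE)[seq_len(n_keep)]]
    if (length(keep) < params$minimum_voxels) next
    smt <- summit[j]
    # plateau-aware centre: voxels of this focus at the summit intensity,
    # centre = the one nearest the plateau centroid (ties: lexicographic
    # z, y, x order)
    plat <- vv[arr[vv] == smt]
    co <- arrayInd(plat, d)
    cm <- colMeans(co)
    dist2 <- (co[, 1] - cm[1])^2 + (co[, 2] - cm[2])^2 + (co[, 3] - cm[3])^2
    ordkey <- order(dist2, co[, 3], co[, 1], co[, 2])
    ctr <- co[ordkey[1L], ]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      focus_id = j,
      z_um = (ctr[3] - 0.5) * vs[["z"]],
      y_um = (ctr[1] - 0.5) * vs[["y"]],
      x_um = (ctr[2] - 0.5) * vs[["x"]],
      voxels = length(keep),
      volume_um3 = length(keep) * unit,
      peak_intensity = smt,
      sum_intensity = sum(arr[keep]))
  }
  if (!length(rows)) return(empty)
  out <- dplyr::bind_rows(rows)
  out$focus_id <- seq_len(nrow(out))
  out
}

#' Count replication nano-foci inside the Xi
#'
#' Counts picked foci whose maximum centre lies inside the Xi region and
#' whose volume is at least `min_volume_um3`; signals below the default
#' 0.0002 um^3 are excluded as unspecific background.
#'
#' @param foci Tibble from [pick_foci_3d()].
#' @param xi Xi [region_mask()].
#' @param min_volume_um3 Volume exclusion threshold.
#' @return Integer count.
#' @export
count_nano_rfi <- function(foci, xi, min_volume_um3 = 0.0002) {
  if (sum(xi$mask) == 0L) stop("empty xi mask", call. = FALSE)
  if (nrow(foci) == 0L) return(0L)
  d <- dim(xi$mask)
  vs <- xi$voxel_size
  iy <- pmin(pmax(round(foci$y_um / vs[["y"]] + 0.5), 1L), d[1])
  ix <- pmin(pmax(round(foci$x_um / vs[["x"]] + 0.5), 1L), d[2])
  iz <- pmin(pmax(round(foci$z_um / vs[["z"]] + 0.5), 1L), d[3])
  inside <- xi$mask[cbind(iy, ix, iz)]
  sum(inside & foci$volume_um3 >= min_volume_um3)
}

#' Count PLA spots by prominence on a maximum-intensity projection
#'
#' Projects the stack, then counts 2D local maxima inside the nucleus
#' whose topographic prominence exceeds the given value (> 40 by
#' default usage in the assays), excluding maxima that touch the frame
#' border ("exclude edge maxima").
#'
#' @param image A [voxel_image()] with a PLA channel.
#' @param nucleus Nucleus [region_mask()] (projected internally).
#' @param prominence Strict prominence threshold.
#' @param channel Spot channel name.
#' @return Integer spot count.
#' @export
pla_spot_count <- function(image, nucleus, prominence = 40,
                           channel = "PLA") {
  if (!channel %in% names(image$channels)) {
    stop("channel '", channel, "' missing from image", call. = FALSE)
  }
  proj <- max_project(image)
  msk <- max_project(nucleus)
  arr <- get_channel(proj, channel)
  d <- dim(arr)
  floorv <- min(arr[msk$mask])
  pk <- find_peaks_cpp(arr, msk$mask, d, floorv - 1, prominence, TRUE)
  k <- length(pk$summit)
  if (k == 0L) return(0L)
  lab <- pk$labels
  n <- 0L
  for (j in seq_len(k)) {
    # an unchallenged summit's prominence is its height above the
    # in-mask minimum
    prom <- pk$prominence[j]
    if (!is.finite(prom)) prom <- pk$summit[j] - floorv
    if (prom <= prominence) next
    # reject maxima whose summit plateau touches the frame border
    plat <- which(lab == j & arr == pk$summit[j])
    co <- arrayInd(plat, d)
    on_edge <- any(co[, 1] == 1L | co[, 1] == d[1] |
                     co[, 2] == 1L | co[, 2] == d[2])
    if (!on_edge) n <- n + 1L
  }
  n
}
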
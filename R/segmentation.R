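#' Triangle auto-threshold
#'
#' Computes the triangle threshold on a 256-bin histogram of the whole
#' stack (or of the voxels under `mask`): a line is drawn from the
#' histogram peak to the far tail, and the threshold is the bin with
#' maximal perpendicular distance to that line. Voxels strictly above the
#' threshold form the mask.
#'
#' @param image A [voxel_image()].
#' @param channel Channel to threshold.
#' @param mask Optional [region_mask()] restricting the histogram and the
#'   output.
#' @param keep_largest Keep only the largest connected component.
#' @return A [region_mask()] with attribute `"threshold"`.
#' @export
triangle_threshold <- function(image, channel, mask = NULL,
                               keep_largest = FALSE) {
  arr <- get_channel(image, channel)
  sel <- if (is.null(mask)) TRUE else {
    check_aligned(image, mask)
    mask$mask
  }
  vals <- arr[sel]
  thr <- triangle_thr(vals)
  m <- arr > thr
  if (!is.null(mask)) m <- m & mask$mask
  if (keep_largest && any(m)) {
    lab <- cc_label_cpp(m, dim(arr), 26L)
    tab <- tabulate(lab[lab > 0L])
    m <- lab == which.max(tab)
  }
  out <- region_mask(m, label = channel, voxel_size = image$voxel_size)
  attr(out, "threshold") <- thr
  out
}

# scalar triangle threshold of a numeric vector (256 equal-width bins)
triangle_thr <- function(vals, bins = 256L) {
  rng <- range(vals)
  if (diff(rng) == 0) {
    stop("degenerate histogram: constant intensities, no threshold exists",
         call. = FALSE)
  }
  brks <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(findInterval(vals, brks, rightmost.closed = TRUE,
                             all.inside = TRUE), bins)
  p <- which.max(h)
  nz <- which(h > 0)
  e <- if ((p - min(nz)) > (max(nz) - p)) min(nz) else max(nz)
  if (e == p) stop("degenerate histogram: single occupied bin",
                   call. = FALSE)
  # perpendicular distance of every bin between peak and tail end to the
  # line through (p, h[p]) and (e, h[e])
  ii <- if (p < e) (p + 1L):(e - 1L) else (e + 1L):(p - 1L)
  if (length(ii) == 0L) ii <- e
  dx <- e - p; dy <- h[e] - h[p]
  d <- abs(dy * ii - dx * h[ii] + dx * h[p] - dy * p) / sqrt(dx^2 + dy^2)
  best <- ii[which.max(d)]
  # threshold at the upper edge of the winning bin
  brks[best + 1L]
}

# fill interior holes of a 3D mask: background components not touching
# the array border become foreground
fill_holes <- function(m) {
  d <- dim(m)
  lab <- cc_label_cpp(!m, d, 6L)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0L]
  m | (lab > 0L & !(lab %in% border))
}

#' Segment nuclei from the DAPI channel
#'
#' Triangle threshold on DAPI over the full stack, hole filling, and
#' connected-component splitting (26-neighbourhood in 3D, 8 in 2D).
#' Components below `min_volume_um3` are dropped; components larger than
#' `review_volume_um3` (e.g. touching nuclei merged into one blob) are
#' kept but flagged `needs_review` and reported with a warning rather
#' than silently merged.
#'
#' @param image A [voxel_image()] with a DAPI channel.
#' @param min_volume_um3 Minimum nucleus volume (um^3; area in 2D).
#' @param review_volume_um3 Volume above which a component is flagged for
#'   manual review.
#' @param channel DNA stain channel name.
#' @return List of nucleus [region_mask()]s (possibly empty), each with
#'   attribute `needs_review`.
#' @export
segment_nucleus <- function(image, min_volume_um3 = 50,
                            review_volume_um3 = 400, channel = "DAPI") {
  thr <- triangle_threshold(image, channel)
  m <- fill_holes(thr$mask)
  lab <- cc_label_cpp(m, dim(m), 26L)
  k <- max(lab)
  if (k == 0L) return(list())
  vs <- image$voxel_size
  unit <- if (dim(m)[3] > 1L) prod(vs) else vs["y"] * vs["x"]
  out <- list()
  for (i in seq_len(k)) {
    sz <- sum(lab == i) * unit
    if (sz < min_volume_um3) next
    rm <- region_mask(lab == i, "nucleus", vs)
    attr(rm, "needs_review") <- sz > review_volume_um3
    out[[length(out) + 1L]] <- rm
  }
  if (any(vapply(out, function(x) isTRUE(attr(x, "needs_review")),
                 logical(1)))) {
    warning("oversized nucleus component(s) flagged for manual review ",
            "(possible touching nuclei)", call. = FALSE)
  }
  out
}

#' Segment Xi territories inside a nucleus
#'
#' Triangle threshold of the H3K27me3 channel restricted to the nucleus;
#' each connected supra-threshold cluster above `min_volume_um3` is one
#' Xi territory, and the number of clusters is the Xi copy number. A
#' nucleus with homogeneous H3K27me3 (constant histogram or no cluster
#' above the minimum volume) yields an empty list.
#'
#' @param image A [voxel_image()] with an H3K27me3 channel.
#' @param nucleus Nucleus [region_mask()].
#' @param min_volume_um3 Minimum Xi cluster volume (um^3).
#' @param channel Xi marker channel.
#' @return List of Xi [region_mask()]s, possibly empty.
#' @export
segment_xi <- function(image, nucleus, min_volume_um3 = 0.5,
                       channel = "H3K27me3") {
  if (sum(nucleus$mask) == 0L) stop("empty nucleus mask", call. = FALSE)
  thr <- tryCatch(triangle_threshold(image, channel, mask = nucleus),
                  error = function(e) NULL)
  if (is.null(thr)) return(list()) # homogeneous H3K27me3
  lab <- cc_label_cpp(thr$mask, dim(thr$mask), 26L)
  k <- max(lab)
  vs <- image$voxel_size
  unit <- if (dim(thr$mask)[3] > 1L) prod(vs) else vs["y"] * vs["x"]
  out <- list()
  for (i in seq_len(k)) {
    if (sum(lab == i) * unit < min_volume_um3) next
    out[[length(out) + 1L]] <- region_mask(lab == i, "xi", vs)
  }
  out
}

#' Place a size-matched control ROI outside the Xi
#'
#' Returns a region with the same voxel count as the Xi mask, fully
#' inside the nucleus and disjoint from the Xi and from chromocenters: a
#' compact blob grown around a seed-randomised centre (the Xi-count
#' nearest admissible voxels). When no chromocenter mask is supplied but
#' `image` is, the top 2% DAPI intensities inside the nucleus stand in
#' for the condensed constitutive heterochromatin to exclude. Placement
#' is seed-reproducible; if the admissible nuclear volume cannot host a
#' region of the required size, an error is raised.
#'
#' @param nucleus,xi [region_mask()]s (xi non-empty).
#' @param chromocenters Optional [region_mask()] to exclude.
#' @param seed Integer seed for the placement.
#' @param image Optional [voxel_image()] with DAPI, used to derive the
#'   chromocenter exclusion when `chromocenters` is `NULL`.
#' @param dapi_quantile Quantile defining the chromocenter proxy.
#' @return A [region_mask()] labelled `"control_roi"`.
#' @export
control_roi <- function(nucleus, xi, chromocenters = NULL, seed = 1,
                        image = NULL, dapi_quantile = 0.98) {
  n_xi <- sum(xi$mask)
  if (n_xi == 0L) stop("empty xi mask", call. = FALSE)
  d <- dim(nucleus$mask)
  excl <- xi$mask
  if (is.null(chromocenters) && !is.null(image) &&
      "DAPI" %in% names(image$channels)) {
    dap <- get_channel(image, "DAPI")
    q <- stats::quantile(dap[nucleus$mask], dapi_quantile)
    excl <- excl | (dap >= q & nucleus$mask)
  } else if (!is.null(chromocenters)) {
    excl <- excl | chromocenters$mask
  }
  allowed <- which(nucleus$mask & !excl)
  if (length(allowed) < n_xi) {
    stop("control-ROI placement failure: nucleus \\ (xi, chromocenters) ",
         "holds ", length(allowed), " voxels but ", n_xi, " are needed",
         call. = FALSE)
  }
  vs <- nucleus$voxel_size
  withr::with_seed(seed, {
    co <- arrayInd(allowed, d)
    ctr <- co[sample.int(nrow(co), 1L), ]
    dist2 <- ((co[, 1] - ctr[1]) * vs[["y"]])^2 +
      ((co[, 2] - ctr[2]) * vs[["x"]])^2 +
      ((co[, 3] - ctr[3]) * vs[["z"]])^2
    pick <- allowed[order(dist2)[seq_len(n_xi)]]
    m <- array(FALSE, d)
    m[pick] <- TRUE
    region_mask(m, "control_roi", vs)
  })
}

#' Gate G1 cells by DNA content
#'
#' Keeps EdU-negative cells whose DAPI sum intensity falls in a window
#' around the lowest mode (2C peak) of the population's DAPI-sum
#' distribution.
#'
#' @param cells Tibble with columns `dapi_sum` and `edu_positive`.
#' @param half_width Half-width of the gate as a fraction of the mode.
#' @return The gated tibble (rows kept in input order).
#' @export
gate_g1 <- function(cells, half_width = 0.15) {
  stopifnot(all(c("dapi_sum", "edu_positive") %in% names(cells)))
  if (nrow(cells) < 10L) {
    stop("fewer than 10 cells: refusing to fit a DNA-content mode",
         call. = FALSE)
  }
  dens <- stats::density(cells$dapi_sum)
  y <- dens$y
  is_mode <- y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf)
  modes <- dens$x[is_mode]
  m <- min(modes)
  keep <- !cells$edu_positive &
    cells$dapi_sum >= m * (1 - half_width) &
    cells$dapi_sum <= m * (1 + half_width)
  cells[keep, , drop = FALSE]
}

#' Classify the S-phase replication pattern of one cell
#'
#' Rule-based stand-in for visual pattern scoring: `non_S` when no
#' supra-background focal replication signal is present; `mid_xi` when at
#' least `xi_fraction` of the focal signal overlaps the Xi territories
#' (the synchronous Xi pattern); `late` when the focal signal concentrates
#' in chromocenters; `early` otherwise.
#'
#' @param image A [voxel_image()] with an EdU or PCNA channel.
#' @param nucleus Nucleus [region_mask()].
#' @param xi_masks List of Xi [region_mask()]s (may be empty).
#' @param chromocenters Optional chromocenter [region_mask()]; defaults to
#'   the top 2% DAPI voxels when DAPI is present.
#' @param xi_fraction Focal-signal fraction in the Xi calling `mid_xi`.
#' @param cc_fraction Focal-signal fraction in chromocenters calling
#'   `late`.
#' @return One of `"non_S"`, `"early"`, `"mid_xi"`, `"late"`.
#' @export
classify_sphase_pattern <- function(image, nucleus, xi_masks,
                                    chromocenters = NULL,
                                    xi_fraction = 0.4, cc_fraction = 0.4) {
  ch <- intersect(c("EdU", "PCNA"), names(image$channels))
  if (length(ch) == 0L) {
    stop("classification needs an EdU or PCNA channel", call. = FALSE)
  }
  arr <- get_channel(image, ch[1])
  vals <- arr[nucleus$mask]
  med <- stats::median(vals)
  mx <- stats::quantile(vals, 0.999)
  if (mx < 2 * (med + 10)) return("non_S")
  focal <- arr > (med + 0.5 * (mx - med)) & nucleus$mask
  nf <- sum(focal)
  if (nf == 0L) return("non_S")
  xi_all <- array(FALSE, dim(arr))
  for (m in xi_masks) xi_all <- xi_all | m$mask
  if (sum(focal & xi_all) / nf >= xi_fraction) return("mid_xi")
  cc <- if (!is.null(chromocenters)) chromocenters$mask
    else if ("DAPI" %in% names(image$channels)) {
      dap <- get_channel(image, "DAPI")
      dap >= stats::quantile(dap[nucleus$mask], 0.98) & nucleus$mask
    } else array(FALSE, dim(arr))
  if (sum(focal & cc) / nf >= cc_fraction) return("late")
  "early"
}
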
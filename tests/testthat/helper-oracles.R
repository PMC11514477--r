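# Independent brute-force oracles and small fixture builders.

# Exhaustive plateau-maxima counter: enumerates every voxel, groups
# contiguous equal-intensity voxels (26-neighbourhood), and accepts a
# plateau as one maximum iff every visible neighbour (in mask, above
# background) has strictly lower intensity.
oracle_plateau_maxima <- function(arr, mask = NULL, background = -Inf) {
  d <- dim(arr)
  if (is.null(mask)) mask <- array(TRUE, d)
  vis <- mask & arr > background
  seen <- array(FALSE, d)
  idx_all <- which(vis)
  nb_of <- function(i) {
    co <- arrayInd(i, d)
    out <- integer(0)
    for (dz in -1:1) for (dx in -1:1) for (dy in -1:1) {
      if (dy == 0 && dx == 0 && dz == 0) next
      y <- co[1] + dy; x <- co[2] + dx; z <- co[3] + dz
      if (y < 1 || y > d[1] || x < 1 || x > d[2] || z < 1 || z > d[3]) next
      out <- c(out, y + d[1] * ((x - 1) + d[2] * (z - 1)))
    }
    out
  }
  n_max <- 0L
  for (i0 in idx_all) {
    if (seen[i0]) next
    # flood the equal-intensity plateau containing i0
    lev <- arr[i0]
    comp <- i0
    stack <- i0
    seen[i0] <- TRUE
    is_max <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (w in nb_of(v)) {
        if (!vis[w]) next
        if (arr[w] == lev && !seen[w]) {
          seen[w] <- TRUE
          comp <- c(comp, w)
          stack <- c(stack, w)
        } else if (arr[w] > lev) {
          is_max <- FALSE
        }
      }
    }
    if (is_max) n_max <- n_max + 1L
  }
  n_max
}

# Direct geometric triangle-threshold oracle: same 256-bin histogram,
# but the winning bin is found by computing the point-to-line distance
# for every bin with the explicit two-point line formula.
oracle_triangle <- function(vals, bins = 256L) {
  rng <- range(vals)
  brks <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(findInterval(vals, brks, rightmost.closed = TRUE,
                             all.inside = TRUE), bins)
  p <- which.max(h)
  nz <- which(h > 0)
  e <- if ((p - min(nz)) > (max(nz) - p)) min(nz) else max(nz)
  x1 <- p; y1 <- h[p]; x2 <- e; y2 <- h[e]
  lo <- min(p, e); hi <- max(p, e)
  cand <- setdiff(seq(lo, hi), c(p, e))
  if (!length(cand)) cand <- e
  dist_pt <- vapply(cand, function(i) {
    num <- abs((y2 - y1) * i - (x2 - x1) * h[i] + x2 * y1 - y2 * x1)
    num / sqrt((y2 - y1)^2 + (x2 - x1)^2)
  }, numeric(1))
  best <- cand[which.max(dist_pt)]
  brks[best + 1L]
}

# O(n^2) interval-intersection oracle on 0-based half-open intervals
oracle_intersect2 <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      s <- max(a$start[i], b$start[j])
      e <- min(a$end[i], b$end[j])
      if (s < e) out[[length(out) + 1L]] <-
          tibble::tibble(chrom = a$chrom[i], start = s, end = e)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  res <- dplyr::distinct(dplyr::bind_rows(out))
  dplyr::arrange(res, chrom, start)
}

oracle_intersect_all <- function(sets, min_overlap = 1) {
  res <- sets[[1]][, c("chrom", "start", "end")]
  for (k in 2:length(sets)) res <- oracle_intersect2(res, sets[[k]])
  res[res$end - res$start >= min_overlap, ]
}

# quick single-channel image builder
mk_img <- function(arr, channel = "X", vs = c(1, 1, 1)) {
  voxel_image(stats::setNames(list(arr), channel), vs)
}

full_mask <- function(arr, vs = c(1, 1, 1)) {
  region_mask(array(TRUE, dim(arr)), "all", vs)
}

# union of segmented Xi masks as one region
xi_union <- function(xis, vs) {
  region_mask(Reduce(`|`, lapply(xis, function(m) m$mask)), "xi", vs)
}
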
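#' Multichannel voxel image
#'
#' The substrate of all image operations: a set of co-registered intensity
#' grids (one per fluorescence channel) with a physical voxel size. Arrays
#' are stored `dim = c(ny, nx, nz)`; 2D images have `nz = 1`. Intensities
#' are arbitrary 16-bit-style counts — every downstream metric is a ratio,
#' so the absolute scale is irrelevant.
#'
#' @param channels Named list of numeric arrays, all with identical
#'   dimensions (`c(ny, nx)` matrices are promoted to `c(ny, nx, 1)`).
#' @param voxel_size Numeric length-3 `(z, y, x)` voxel size in micrometres;
#'   all entries must be strictly positive.
#' @return A `voxel_image` object.
#' @examples
#' img <- voxel_image(list(DAPI = array(100, c(8, 8, 4))),
#'                    voxel_size = c(0.29, 0.05, 0.05))
#' img
#' @export
voxel_image <- function(channels, voxel_size = c(0.29, 0.05, 0.05)) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || anyDuplicated(names(channels)) > 0L) {
    stop("`channels` must be a non-empty uniquely named list of arrays",
         call. = FALSE)
  }
  channels <- lapply(channels, function(a) {
    a <- as.array(a)
    if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
    if (length(dim(a)) != 3L) {
      stop("channel arrays must be 2D or 3D", call. = FALSE)
    }
    a
  })
  d <- dim(channels[[1L]])
  ok <- vapply(channels, function(a) identical(dim(a), d), logical(1))
  if (!all(ok)) stop("all channels must share one dimension", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 strictly positive values (z, y, x) in um",
         call. = FALSE)
  }
  bad <- vapply(channels, function(a) any(!is.finite(a)) || any(a < 0),
                logical(1))
  if (any(bad)) {
    stop("intensities must be finite and >= 0 (channels: ",
         paste(names(channels)[bad], collapse = ", "), ")", call. = FALSE)
  }
  names(voxel_size) <- c("z", "y", "x")
  structure(list(channels = channels, voxel_size = voxel_size),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<voxel_image> %d x %d x %d (y,x,z), voxel %s um\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

img_dim <- function(image) dim(image$channels[[1L]])

#' Extract one channel array from a voxel image
#'
#' @param image A [voxel_image()].
#' @param channel Channel name.
#' @return The 3D intensity array.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "voxel_image"))
  if (!channel %in% names(image$channels)) {
    stop("channel '", channel, "' not present (have: ",
         paste(names(image$channels), collapse = ", "), ")", call. = FALSE)
  }
  image$channels[[channel]]
}

#' Labelled region mask
#'
#' A boolean region (nucleus, Xi, control ROI, scaffold, halo, ...) aligned
#' to a [voxel_image()]. The physical size is always the true-voxel count
#' times the voxel volume (3D) or pixel area (2D), exactly.
#'
#' @param mask Logical array (2D or 3D).
#' @param label Region label, e.g. `"nucleus"`, `"xi"`, `"control_roi"`.
#' @param voxel_size `(z, y, x)` voxel size in micrometres.
#' @return A `region_mask` object.
#' @export
region_mask <- function(mask, label = "region",
                        voxel_size = c(0.29, 0.05, 0.05)) {
  mask <- as.array(mask)
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  names(voxel_size) <- c("z", "y", "x")
  structure(list(mask = mask, label = label, voxel_size = voxel_size),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> '%s': %d voxels, %.4g %s\n", x$label,
              sum(x$mask), mask_size(x),
              if (dim(x$mask)[3] > 1L) "um^3" else "um^2"))
  invisible(x)
}

#' Physical size of a region mask
#'
#' Voxel count times voxel volume (3D) or pixel area (2D).
#'
#' @param mask A [region_mask()].
#' @return Size in um^3 (3D masks) or um^2 (2D masks).
#' @export
mask_size <- function(mask) {
  stopifnot(inherits(mask, "region_mask"))
  vs <- mask$voxel_size
  unit <- if (dim(mask$mask)[3] > 1L) prod(vs) else vs["y"] * vs["x"]
  unname(sum(mask$mask) * unit)
}

check_aligned <- function(image, mask) {
  if (!identical(img_dim(image), dim(mask$mask))) {
    stop("image and mask dimensions differ", call. = FALSE)
  }
  invisible(TRUE)
}

#' Maximum-intensity projection
#'
#' Collapses a Z-stack to a single plane by the per-pixel maximum over Z,
#' the projection used for PLA spot counting, loading coefficients and the
#' Xi relative area. Masks project by `any()` over Z.
#'
#' @param x A [voxel_image()] or [region_mask()].
#' @return A 2D object of the same class.
#' @export
max_project <- function(x) {
  if (inherits(x, "voxel_image")) {
    d <- img_dim(x)
    if (d[3] == 1L) return(x)
    ch <- lapply(x$channels, function(a) {
      array(apply(a, c(1, 2), max), c(d[1], d[2], 1L))
    })
    voxel_image(ch, x$voxel_size)
  } else if (inherits(x, "region_mask")) {
    d <- dim(x$mask)
    if (d[3] == 1L) return(x)
    m <- array(apply(x$mask, c(1, 2), any), c(d[1], d[2], 1L))
    region_mask(m, x$label, x$voxel_size)
  } else {
    stop("`x` must be a voxel_image or region_mask", call. = FALSE)
  }
}

#' Write a voxel image as a multi-page TIFF with a JSON side-car
#'
#' One 32-bit float page per (channel, z-slice), channel-major; voxel size
#' and channel names go to `<stem>.json` so a round trip preserves
#' geometry.
#'
#' @param image A [voxel_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_voxel_tiff <- function(image, path) {
  stopifnot(inherits(image, "voxel_image"))
  d <- img_dim(image)
  scale <- max(1, max(vapply(image$channels, max, numeric(1))))
  pages <- list()
  for (ch in names(image$channels)) {
    a <- image$channels[[ch]]
    for (z in seq_len(d[3])) pages[[length(pages) + 1L]] <- a[, , z] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(channels = names(image$channels), dim = d,
               voxel_size_um = unname(image$voxel_size),
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voxel image written by [write_voxel_tiff()]
#'
#' @param path TIFF path (the `.json` side-car must sit next to it).
#' @return A [voxel_image()].
#' @export
read_voxel_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  chs <- list()
  i <- 0L
  for (ch in meta$channels) {
    a <- array(0, d)
    for (z in seq_len(d[3])) {
      i <- i + 1L
      a[, , z] <- pages[[i]] * meta$intensity_scale
    }
    chs[[ch]] <- a
  }
  voxel_image(chs, meta$voxel_size_um)
}
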
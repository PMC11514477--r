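#' @useDynLib xirep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# intensity levels of the synthetic microscope (arbitrary 16-bit counts;
# every pipeline metric is a ratio, so only contrasts matter)
.levels <- list(
  dapi_bg = 20, dapi_nucleus = 5000, dapi_chromo = 12000,
  h3k_bg = 10, h3k_nucleus = 500, h3k_xi = 3000,
  pcna_diffuse = 800, pcna_non_s = 300, edu_base = 0.8,
  focus_amp = 3000, focus_sigma = 0.1,
  pla_bg = 10, pla_amp = 200, pla_sigma = 0.15,
  mcm_base = 4000, mcm_bg = 10, mcm_mid_s_enrichment = 2,
  fish_xi = 2000, fish_bg = 30
)

# voxel-centre coordinates (um) along each axis for dim d = c(ny,nx,nz)
axis_um <- function(n, step) (seq_len(n) - 0.5) * step

# logical ellipsoid over the (sub)grid given by coordinate vectors
ellipsoid_mask_arr <- function(ys, xs, zs, center, radii) {
  # center/radii are (z, y, x); a zero radius collapses that axis
  ry <- max(radii[2], 1e-9); rx <- max(radii[3], 1e-9)
  rz <- max(radii[1], 1e-9)
  ay <- ((ys - center[2]) / ry)^2
  ax <- ((xs - center[3]) / rx)^2
  az <- ((zs - center[1]) / rz)^2
  d <- c(length(ys), length(xs), length(zs))
  arr <- array(ay, d) + array(rep(ax, each = d[1]), d) +
    array(rep(az, each = d[1] * d[2]), d)
  arr <= 1
}

# add Gaussian spots; centers is a matrix with columns (z,y,x) um.
# sigma_um may be scalar (isotropic) or length 3 (z,y,x): the axial PSF of
# any fluorescence microscope is wider than the lateral one, so spots
# rendered onto coarse z-steps should use sigma_z >= the z-step.
add_spots <- function(arr, voxel_size, centers, sigma_um, amplitude) {
  if (is.null(centers) || nrow(centers) == 0L) return(arr)
  d <- dim(arr)
  vs <- voxel_size # (z,y,x)
  sg <- if (length(sigma_um) == 1L) rep(sigma_um, 3) else sigma_um
  amplitude <- rep_len(amplitude, nrow(centers))
  wy <- ceiling(3.5 * sg[2] / vs[2]); wx <- ceiling(3.5 * sg[3] / vs[3])
  wz <- ceiling(3.5 * sg[1] / vs[1])
  for (i in seq_len(nrow(centers))) {
    cz <- centers[i, 1]; cy <- centers[i, 2]; cx <- centers[i, 3]
    iy <- round(cy / vs[2] + 0.5); ix <- round(cx / vs[3] + 0.5)
    iz <- round(cz / vs[1] + 0.5)
    ys <- max(1, iy - wy):min(d[1], iy + wy)
    xs <- max(1, ix - wx):min(d[2], ix + wx)
    zs <- max(1, iz - wz):min(d[3], iz + wz)
    gy <- exp(-0.5 * ((ys - 0.5) * vs[2] - cy)^2 / sg[2]^2)
    gx <- exp(-0.5 * ((xs - 0.5) * vs[3] - cx)^2 / sg[3]^2)
    gz <- exp(-0.5 * ((zs - 0.5) * vs[1] - cz)^2 / sg[1]^2)
    g <- outer(gy, gx)
    for (k in seq_along(zs)) {
      arr[ys, xs, zs[k]] <- arr[ys, xs, zs[k]] + amplitude[i] * g * gz[k]
    }
  }
  arr
}

# sample n spot centers inside an ellipsoid (radii (z,y,x) um, centred at 0)
# with a guaranteed minimum pairwise separation, via a jittered cubic
# lattice of spacing 1.05*min_sep; `crowded` drops the spacing constraint.
# min_sep may be length 3 (z,y,x): the lattice is built in PSF-normalised
# coordinates, which is the separation that matters for resolvability when
# the axial PSF is wider than the lateral one.
sample_centers <- function(radii, n, min_sep, crowded = FALSE) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  if (length(min_sep) == 3L && !crowded && any(min_sep > 0)) {
    sc <- pmax(min_sep, 1e-9)
    u <- sample_centers(radii / sc, n, 1, crowded = FALSE)
    return(sweep(u, 2, sc, "*"))
  }
  min_sep <- min_sep[1]
  if (crowded || min_sep <= 0) {
    pts <- matrix(numeric(0), 0, 3)
    r <- pmax(radii, 1e-9)
    while (nrow(pts) < n) {
      cand <- cbind(stats::runif(4 * n, -r[1], r[1]),
                    stats::runif(4 * n, -r[2], r[2]),
                    stats::runif(4 * n, -r[3], r[3]))
      if (radii[1] == 0) cand[, 1] <- 0
      keep <- (cand[, 1] / r[1])^2 + (cand[, 2] / r[2])^2 +
        (cand[, 3] / r[3])^2 <= 0.94
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    return(pts[seq_len(n), , drop = FALSE])
  }
  s <- 1.05 * min_sep
  jit <- 0.02 * s
  ax <- function(r) {
    if (r <= 0) return(0)
    k <- floor(2 * r / s)
    if (k < 1) return(0)
    seq(-(k - 1) / 2, (k - 1) / 2) * s
  }
  g <- as.matrix(expand.grid(z = ax(radii[1]), y = ax(radii[2]),
                             x = ax(radii[3])))
  g <- g + matrix(stats::runif(length(g), -jit, jit), nrow(g), 3)
  if (radii[1] == 0) g[, 1] <- 0
  r <- pmax(radii, 1e-9)
  eq <- (g[, 1] / (0.97 * r[1]))^2 + (g[, 2] / (0.97 * r[2]))^2 +
    (g[, 3] / (0.97 * r[3]))^2
  g <- g[eq <= 1, , drop = FALSE]
  if (nrow(g) < n) {
    stop("region too small for ", n, " foci at minimum separation ",
         signif(min_sep, 3), " um (capacity ", nrow(g), ")", call. = FALSE)
  }
  g[sample.int(nrow(g), n), , drop = FALSE]
}

stage_levels <- c("non_S", "early", "mid_xi", "late")

#' Generate a synthetic multichannel nucleus field with ground truth
#'
#' Renders one or more nuclei (ellipsoids of uniform DAPI with bright
#' chromocenters) carrying H3K27me3-marked Xi territories, stage-dependent
#' EdU/PCNA replication signal (diffuse replisome pool plus planted
#' Gaussian foci), optional Mcm2 / Mcm2-phosphoS108 channels with an Xi
#' enrichment factor, PLA spot fields and an X-paint FISH channel. All
#' condition-dependent contrasts come from the [condition_preset()];
#' channel sums respect the preset's factors exactly before noise, and a
#' ground-truth object records every planted focus, region geometry and
#' noise-free region/channel sum.
#'
#' @param preset A [condition_preset()].
#' @param n_cells Number of nuclei, laid out on a square grid; must be >= 1.
#' @param seed Integer seed; identical `(parameters, seed)` give
#'   bit-identical output.
#' @param voxel_size `(z, y, x)` voxel size in um (strictly positive).
#'   The default mirrors confocal sampling (50 nm pixels, 290 nm Z-step).
#' @param channels Subset of `DAPI`, `H3K27me3`, `EdU`, `PCNA`, `Mcm2`,
#'   `Mcm2pS108`, `PLA`, `FISH`.
#' @param stage S-phase stage per cell (recycled): `"non_S"`, `"early"`,
#'   `"mid_xi"`, `"late"`, or `"mix"` to draw from a population mixture.
#' @param n_xi Xi territories per nucleus (C2C12-like cells carry two).
#' @param nucleus_radii_um,xi_radii_um Ellipsoid semi-axes `(z, y, x)` um.
#' @param n_chromocenters Bright constitutive-heterochromatin blobs per
#'   nucleus.
#' @param fixed_counts If set, the exact number of EdU foci planted per Xi;
#'   otherwise counts are drawn Poisson around `preset$foci_per_xi_mean`.
#' @param nuclear_foci Number of non-Xi replication foci for S-phase
#'   stages; defaults depend on stage.
#' @param mcm_xi_enrichment Xi enrichment of the Mcm2 channel before the
#'   preset's reduction; default 2 for mid-S cells.
#' @param dna_content Per-cell DNA content multiplier for DAPI (recycled);
#'   default depends on stage (1 or 2 for non-S, intermediate for S).
#' @param crowded Drop the minimum 4-sigma focus spacing (stress test for
#'   the spot separator).
#' @param twod Render a single-plane (2D) field.
#' @param margin_um Empty margin around each nucleus tile.
#' @param noise Noise model override; default `preset$noise_model`.
#' @return A list with elements `image` ([voxel_image()]) and `truth`
#'   (class `xirep_truth`; see [truth_mask()]).
#' @examples
#' p <- condition_preset("scramble", noise_model = "none")
#' sim <- make_nucleus_image(p, n_cells = 1, seed = 1,
#'                           voxel_size = c(0.6, 0.3, 0.3),
#'                           fixed_counts = 10, nuclear_foci = 5)
#' sim$image
#' @export
make_nucleus_image <- function(preset, n_cells = 1, seed = 1,
                               voxel_size = c(0.29, 0.05, 0.05),
                               channels = c("DAPI", "H3K27me3", "EdU",
                                            "PCNA"),
                               stage = "mid_xi", n_xi = 2,
                               nucleus_radii_um = c(2.5, 5, 5),
                               xi_radii_um = c(1.4, 1.9, 1.6),
                               n_chromocenters = 3, fixed_counts = NULL,
                               nuclear_foci = NULL, mcm_xi_enrichment = NULL,
                               dna_content = NULL, crowded = FALSE,
                               twod = FALSE, margin_um = 1, noise = NULL) {
  validate_preset(preset)
  if (!is.numeric(n_cells) || n_cells < 1) {
    stop("`n_cells` must be >= 1", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 strictly positive um values (z,y,x)",
         call. = FALSE)
  }
  known <- c("DAPI", "H3K27me3", "EdU", "PCNA", "Mcm2", "Mcm2pS108", "PLA",
             "FISH")
  bad <- setdiff(channels, known)
  if (length(bad)) stop("unknown channels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  noise <- noise %||% preset$noise_model
  n_cells <- as.integer(n_cells)
  lv <- .levels

  withr::with_seed(seed, {
    if (twod) nucleus_radii_um[1] <- 0
    if (twod) xi_radii_um[1] <- 0
    tile_yx <- 2 * (max(nucleus_radii_um[2:3]) + margin_um)
    ncol_g <- ceiling(sqrt(n_cells))
    nrow_g <- ceiling(n_cells / ncol_g)
    ny <- ceiling(nrow_g * tile_yx / voxel_size[2])
    nx <- ceiling(ncol_g * tile_yx / voxel_size[3])
    nz <- if (twod) 1L else
      ceiling(2 * (nucleus_radii_um[1] + 0.35) / voxel_size[1])
    d <- c(ny, nx, nz)

    arrs <- stats::setNames(
      lapply(channels, function(ch) array(0, d)), channels)
    # field background
    if ("DAPI" %in% channels) arrs$DAPI[] <- lv$dapi_bg
    if ("H3K27me3" %in% channels) arrs$H3K27me3[] <- lv$h3k_bg
    if ("PLA" %in% channels) arrs$PLA[] <- lv$pla_bg
    if ("FISH" %in% channels) arrs$FISH[] <- lv$fish_bg
    if ("Mcm2" %in% channels) arrs$Mcm2[] <- lv$mcm_bg
    if ("Mcm2pS108" %in% channels) arrs$Mcm2pS108[] <- lv$mcm_bg

    stage <- if (identical(stage, "mix")) {
      sample(stage_levels, n_cells, replace = TRUE,
             prob = c(0.3, 0.3, 0.25, 0.15))
    } else rep_len(stage, n_cells)
    stopifnot(all(stage %in% stage_levels))
    if (!is.null(dna_content)) dna_content <- rep_len(dna_content, n_cells)

    regions <- list(); foci_tbl <- list(); cells <- list()
    zs_all <- axis_um(nz, voxel_size[1])
    for (ci in seq_len(n_cells)) {
      gy <- (ci - 1) %/% ncol_g; gx <- (ci - 1) %% ncol_g
      cen <- c(z = if (twod) zs_all[1] else nz * voxel_size[1] / 2,
               y = (gy + 0.5) * tile_yx, x = (gx + 0.5) * tile_yx)
      content <- if (!is.null(dna_content)) dna_content[ci] else
        switch(stage[ci], non_S = sample(c(1, 2), 1, prob = c(0.7, 0.3)),
               early = 1.3, mid_xi = 1.5, late = 1.8)

      # tile sub-grid
      iy <- which(abs(axis_um(ny, voxel_size[2]) - cen["y"]) <= tile_yx / 2)
      ix <- which(abs(axis_um(nx, voxel_size[3]) - cen["x"]) <= tile_yx / 2)
      ys <- axis_um(ny, voxel_size[2])[iy]
      xs <- axis_um(nx, voxel_size[3])[ix]
      zs <- zs_all
      nuc <- ellipsoid_mask_arr(ys, xs, zs, cen[c("z", "y", "x")],
                                nucleus_radii_um)
      regions[[length(regions) + 1L]] <- tibble(
        cell_id = ci, region = "nucleus", cz = cen[["z"]], cy = cen[["y"]],
        cx = cen[["x"]], rz = nucleus_radii_um[1], ry = nucleus_radii_um[2],
        rx = nucleus_radii_um[3])

      # Xi territories, opposite sides of the nuclear centre
      xi_offset <- 0.52 * nucleus_radii_um[2]
      th0 <- stats::runif(1, 0, 2 * pi)
      xi_cen <- list()
      for (k in seq_len(n_xi)) {
        th <- th0 + (k - 1) * pi + stats::runif(1, -0.2, 0.2)
        xc <- c(cen[["z"]], cen[["y"]] + xi_offset * sin(th),
                cen[["x"]] + xi_offset * cos(th))
        xi_cen[[k]] <- xc
        regions[[length(regions) + 1L]] <- tibble(
          cell_id = ci, region = paste0("xi", k), cz = xc[1], cy = xc[2],
          cx = xc[3], rz = xi_radii_um[1], ry = xi_radii_um[2],
          rx = xi_radii_um[3])
      }
      xi_sub <- array(FALSE, dim(nuc))
      for (k in seq_len(n_xi)) {
        xi_sub <- xi_sub | ellipsoid_mask_arr(ys, xs, zs, xi_cen[[k]],
                                              xi_radii_um)
      }
      xi_sub <- xi_sub & nuc

      # chromocenters: small bright DAPI blobs away from the Xi
      cc_cen <- list()
      if (n_chromocenters > 0) {
        tries <- 0L
        while (length(cc_cen) < n_chromocenters && tries < 400L) {
          tries <- tries + 1L
          u <- stats::runif(3, -0.55, 0.55)
          cand <- c(cen[["z"]] + u[1] * nucleus_radii_um[1],
                    cen[["y"]] + u[2] * nucleus_radii_um[2],
                    cen[["x"]] + u[3] * nucleus_radii_um[3])
          far <- all(vapply(xi_cen, function(xc)
            sqrt(sum((cand - xc)^2)) > max(xi_radii_um) + 0.9, logical(1)))
          if (far) cc_cen[[length(cc_cen) + 1L]] <- cand
        }
        for (k in seq_along(cc_cen)) {
          regions[[length(regions) + 1L]] <- tibble(
            cell_id = ci, region = paste0("chromocenter", k),
            cz = cc_cen[[k]][1], cy = cc_cen[[k]][2], cx = cc_cen[[k]][3],
            rz = if (twod) 0 else 0.5, ry = 0.5, rx = 0.5)
        }
      }
      cc_sub <- array(FALSE, dim(nuc))
      for (k in seq_along(cc_cen)) {
        cc_sub <- cc_sub | ellipsoid_mask_arr(
          ys, xs, zs, cc_cen[[k]], c(if (twod) 0 else 0.5, 0.5, 0.5))
      }
      cc_sub <- cc_sub & nuc

      # structural channels
      if ("DAPI" %in% channels) {
        a <- arrs$DAPI[iy, ix, , drop = FALSE]
        a[nuc] <- lv$dapi_nucleus * content
        a[cc_sub] <- lv$dapi_chromo * content
        arrs$DAPI[iy, ix, ] <- a
      }
      if ("H3K27me3" %in% channels) {
        a <- arrs$H3K27me3[iy, ix, , drop = FALSE]
        a[nuc] <- lv$h3k_nucleus
        a[xi_sub] <- lv$h3k_xi
        arrs$H3K27me3[iy, ix, ] <- a
      }
      if ("FISH" %in% channels) {
        a <- arrs$FISH[iy, ix, , drop = FALSE]
        a[xi_sub] <- lv$fish_xi
        arrs$FISH[iy, ix, ] <- a
      }

      # replication foci geometry; the rendered PSF follows the sampling
      # (lateral sigma = 2 voxels, axial sigma >= one z-step)
      sg_foci <- c(max(voxel_size[1], 2 * voxel_size[2]),
                   2 * voxel_size[2], 2 * voxel_size[3])
      s_phase <- stage[ci] %in% c("early", "mid_xi", "late")
      fz <- list()
      if (s_phase && any(c("EdU", "PCNA") %in% channels)) {
        nf <- nuclear_foci %||%
          switch(stage[ci], early = 300, mid_xi = 100, late = 40)
        if (stage[ci] == "mid_xi") {
          for (k in seq_len(n_xi)) {
            cnt <- if (!is.null(fixed_counts)) fixed_counts else
              stats::rpois(1, preset$foci_per_xi_mean)
            # Xi nano-foci are below confocal resolution (the point of the
            # SIM/hypotonic counting): placed without spacing constraint
            pos <- sample_centers(0.97 * xi_radii_um, cnt, 0,
                                  crowded = TRUE)
            pos <- sweep(pos, 2, xi_cen[[k]], "+")
            fz[[length(fz) + 1L]] <- tibble(
              cell_id = ci, region = paste0("xi", k),
              z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3])
          }
        }
        if (nf > 0 && stage[ci] != "late") {
          # pattern emulation, not a counting substrate: dense placement
          pos <- sample_centers(0.9 * nucleus_radii_um, nf, 0,
                                crowded = TRUE)
          pos <- sweep(pos, 2, cen[c("z", "y", "x")], "+")
          # keep nuclear foci outside the Xi territories
          out_xi <- rep(TRUE, nrow(pos))
          for (k in seq_len(n_xi)) {
            xc <- xi_cen[[k]]
            eq <- ((pos[, 1] - xc[1]) / max(xi_radii_um[1], 1e-9))^2 +
              ((pos[, 2] - xc[2]) / xi_radii_um[2])^2 +
              ((pos[, 3] - xc[3]) / xi_radii_um[3])^2
            out_xi <- out_xi & eq > 1.2
          }
          pos <- pos[out_xi, , drop = FALSE]
          if (nrow(pos)) {
            fz[[length(fz) + 1L]] <- tibble(
              cell_id = ci, region = "nucleus",
              z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3])
          }
        }
        if (stage[ci] == "late" && length(cc_cen)) {
          for (k in seq_along(cc_cen)) {
            cnt <- ceiling(nf / length(cc_cen))
            pos <- sample_centers(c(if (twod) 0 else 0.45, 0.45, 0.45), cnt,
                                  2 * lv$focus_sigma, crowded = TRUE)
            pos <- sweep(pos, 2, cc_cen[[k]], "+")
            fz[[length(fz) + 1L]] <- tibble(
              cell_id = ci, region = paste0("chromocenter", k),
              z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3])
          }
        }
      }
      fz <- if (length(fz)) dplyr::bind_rows(fz) else
        tibble(cell_id = integer(), region = character(), z_um = numeric(),
               y_um = numeric(), x_um = numeric())
      if (nrow(fz)) {
        fz$sigma_um <- sg_foci[2]
        fz$amplitude <- lv$focus_amp
        fz$channel <- "PCNA"
        foci_tbl[[length(foci_tbl) + 1L]] <- fz
      }

      # PCNA / EdU: diffuse replisome pool plus foci; EdU is a fixed
      # fraction of PCNA, boosted by the preset's factor inside the Xi
      if (any(c("EdU", "PCNA") %in% channels)) {
        p <- array(0, dim(nuc))
        if (s_phase) {
          p[nuc] <- lv$pcna_diffuse
          pc <- as.matrix(fz[, c("z_um", "y_um", "x_um")])
          sub <- array(0, dim(nuc))
          sub <- add_spots_sub(sub, voxel_size, pc, sg_foci,
                               lv$focus_amp, ys, xs, zs)
          p <- p + sub
        } else {
          p[nuc] <- lv$pcna_non_s
        }
        if ("PCNA" %in% channels) {
          arrs$PCNA[iy, ix, ] <- arrs$PCNA[iy, ix, , drop = FALSE] + p
        }
        if ("EdU" %in% channels && s_phase) {
          e <- lv$edu_base * p
          e[xi_sub] <- e[xi_sub] * preset$edu_pcna_xi_factor
          arrs$EdU[iy, ix, ] <- arrs$EdU[iy, ix, , drop = FALSE] + e
        }
      }

      # helicase-loading channels: uniform nuclear level with an Xi
      # factor. An explicit `mcm_xi_enrichment` is planted as-is (it IS
      # the ground-truth coefficient, e.g. a G1 loading trajectory); the
      # default mid-S enrichment is attenuated by the preset's Xi
      # reductions.
      if ("Mcm2" %in% channels) {
        enr <- mcm_xi_enrichment %||%
          (lv$mcm_mid_s_enrichment * (1 - preset$mcm2_xi_reduction))
        a <- arrs$Mcm2[iy, ix, , drop = FALSE]
        a[nuc] <- lv$mcm_base
        a[xi_sub] <- lv$mcm_base * enr
        arrs$Mcm2[iy, ix, ] <- a
      }
      if ("Mcm2pS108" %in% channels) {
        enr <- (mcm_xi_enrichment %||% lv$mcm_mid_s_enrichment) *
          (1 - preset$mcm2ps108_xi_reduction)
        a <- arrs$Mcm2pS108[iy, ix, , drop = FALSE]
        a[nuc] <- lv$mcm_base
        a[xi_sub] <- lv$mcm_base * enr
        arrs$Mcm2pS108[iy, ix, ] <- a
      }

      # PLA spots: total count Poisson around the preset mean; each spot
      # falls in the Xi with the probability that plants the preset's
      # Xi density fold in spots-per-DAPI units
      if ("PLA" %in% channels) {
        if (!"DAPI" %in% channels) {
          stop("PLA generation needs the DAPI channel for density truth",
               call. = FALSE)
        }
        n_spots <- stats::rpois(1, preset$pla_nuclear_mean)
        dap <- arrs$DAPI[iy, ix, , drop = FALSE]
        dsum_xi <- sum(apply(dap, c(1, 2), max)[apply(xi_sub, c(1, 2), any)])
        dsum_nuc <- sum(apply(dap, c(1, 2), max)[apply(nuc, c(1, 2), any)])
        p_xi <- min(1, preset$pla_xi_density_fold * dsum_xi / dsum_nuc)
        n_in_xi <- stats::rbinom(1, n_spots, p_xi)
        pos <- matrix(numeric(0), 0, 3)
        if (n_in_xi > 0) {
          per_xi <- tabulate(sample.int(n_xi, n_in_xi, replace = TRUE),
                             n_xi)
          for (k in seq_len(n_xi)) {
            if (per_xi[k] == 0) next
            q <- sample_centers(0.9 * xi_radii_um, per_xi[k], 0.6)
            pos <- rbind(pos, sweep(q, 2, xi_cen[[k]], "+"))
          }
        }
        n_out <- n_spots - n_in_xi
        if (n_out > 0) {
          got <- 0L
          tries <- 0L
          while (got < n_out && tries < 50L) {
            tries <- tries + 1L
            q <- sample_centers(0.9 * nucleus_radii_um,
                                min(2L * (n_out - got) + 4L, 150L), 0.8)
            q <- sweep(q, 2, cen[c("z", "y", "x")], "+")
            keep <- rep(TRUE, nrow(q))
            # keep non-Xi spots a PSF-scale distance clear of the Xi
            # boundary, so their maxima cannot land inside the Xi mask
            marg <- (1 + 0.4 / mean(xi_radii_um[2:3]))^2
            for (k in seq_len(n_xi)) {
              xc <- xi_cen[[k]]
              eq <- ((q[, 1] - xc[1]) / max(xi_radii_um[1], 1e-9))^2 +
                ((q[, 2] - xc[2]) / xi_radii_um[2])^2 +
                ((q[, 3] - xc[3]) / xi_radii_um[3])^2
              keep <- keep & eq > marg
            }
            # spots must also stay separated from all prior spots in the
            # XY projection, where counting happens
            for (j in which(keep)) {
              if (nrow(pos)) {
                dxy <- sqrt((pos[, 2] - q[j, 2])^2 + (pos[, 3] - q[j, 3])^2)
                if (min(dxy) < 0.6) next
              }
              pos <- rbind(pos, q[j, , drop = FALSE])
              got <- got + 1L
              if (got >= n_out) break
            }
          }
          n_in_xi <- min(n_in_xi, nrow(pos))
        }
        if (nrow(pos)) {
          sub <- arrs$PLA[iy, ix, , drop = FALSE]
          sg_pla <- c(max(voxel_size[1], lv$pla_sigma), lv$pla_sigma,
                      lv$pla_sigma)
          sub <- add_spots_sub(sub, voxel_size, pos, sg_pla,
                               lv$pla_amp, ys, xs, zs)
          arrs$PLA[iy, ix, ] <- sub
          foci_tbl[[length(foci_tbl) + 1L]] <- tibble(
            cell_id = ci,
            region = c(rep("xi", n_in_xi),
                       rep("nucleus", nrow(pos) - n_in_xi)),
            z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3],
            sigma_um = lv$pla_sigma, amplitude = lv$pla_amp,
            channel = "PLA")
        }
      }

      cells[[ci]] <- tibble(cell_id = ci, condition = preset$name,
                            stage = stage[ci], dna_content = content)
    }

    regions <- dplyr::bind_rows(regions)
    foci_tbl <- if (length(foci_tbl)) dplyr::bind_rows(foci_tbl) else
      tibble(cell_id = integer(), region = character(), z_um = numeric(),
             y_um = numeric(), x_um = numeric(), sigma_um = numeric(),
             amplitude = numeric(), channel = character())
    cells <- dplyr::bind_rows(cells)

    truth <- structure(
      list(cells = cells, regions = regions, foci = foci_tbl,
           voxel_size = stats::setNames(voxel_size, c("z", "y", "x")),
           dim = d),
      class = "xirep_truth")
    truth$true_sums <- true_region_sums(arrs, truth)

    arrs <- lapply(arrs, apply_noise, noise = noise)
    list(image = voxel_image(arrs, voxel_size), truth = truth)
  })
}

# add_spots on a sub-block whose axis coordinates are ys/xs/zs (um)
add_spots_sub <- function(arr, voxel_size, centers, sigma_um, amplitude,
                          ys, xs, zs) {
  if (is.null(centers) || nrow(centers) == 0L) return(arr)
  off <- c(zs[1] - voxel_size[1] / 2, ys[1] - voxel_size[2] / 2,
           xs[1] - voxel_size[3] / 2)
  centers <- sweep(centers, 2, off, "-")
  add_spots(arr, voxel_size, centers, sigma_um, amplitude)
}

# noise-free bookkeeping: region/channel sums over ground-truth masks
true_region_sums <- function(arrs, truth) {
  out <- list()
  for (ci in unique(truth$regions$cell_id)) {
    nuc <- truth_mask_arr(truth, ci, "nucleus")
    xi <- truth_mask_arr(truth, ci, "xi")
    for (ch in names(arrs)) {
      out[[length(out) + 1L]] <- tibble(
        cell_id = ci, region = c("nucleus", "xi"), channel = ch,
        sum = c(sum(arrs[[ch]][nuc]), sum(arrs[[ch]][xi])))
    }
  }
  dplyr::bind_rows(out)
}

truth_mask_arr <- function(truth, cell_id, region) {
  d <- truth$dim
  vs <- truth$voxel_size
  ys <- axis_um(d[1], vs[2]); xs <- axis_um(d[2], vs[3])
  zs <- axis_um(d[3], vs[1])
  rr <- truth$regions[truth$regions$cell_id == cell_id, ]
  pick <- if (region == "xi") grepl("^xi", rr$region)
    else if (region == "chromocenters") grepl("^chromocenter", rr$region)
    else rr$region == region
  rr <- rr[pick, , drop = FALSE]
  if (nrow(rr) == 0L) {
    stop("no ground-truth region '", region, "' for cell ", cell_id,
         call. = FALSE)
  }
  m <- array(FALSE, d)
  for (i in seq_len(nrow(rr))) {
    m <- m | ellipsoid_mask_arr(ys, xs, zs,
                                c(rr$cz[i], rr$cy[i], rr$cx[i]),
                                c(rr$rz[i], rr$ry[i], rr$rx[i]))
  }
  if (region != "nucleus") {
    m <- m & truth_mask_arr(truth, cell_id, "nucleus")
  }
  m
}

#' Ground-truth region mask
#'
#' Rebuilds the exact mask of a planted region from the generator's
#' geometry record, so noise-free sums over it match
#' `truth$true_sums` voxel for voxel.
#'
#' @param truth The `truth` element returned by [make_nucleus_image()].
#' @param cell_id Cell of interest.
#' @param region `"nucleus"`, `"xi"` (union of Xi territories),
#'   `"chromocenters"`, or an individual name such as `"xi1"`.
#' @return A [region_mask()].
#' @export
truth_mask <- function(truth, cell_id = 1, region = "nucleus") {
  stopifnot(inherits(truth, "xirep_truth"))
  region_mask(truth_mask_arr(truth, cell_id, region), label = region,
              voxel_size = truth$voxel_size)
}

#' @export
print.xirep_truth <- function(x, ...) {
  cat("<xirep_truth>", nrow(x$cells), "cell(s),", nrow(x$foci),
      "planted spot(s)\n")
  invisible(x)
}

#' Generate a single synthetic Xi territory volume
#'
#' A small EdU stack holding one Xi ellipsoid with well-separated planted
#' replication nano-foci — the substrate for foci-picking benchmarks.
#'
#' @inheritParams make_nucleus_image
#' @param fixed_count Exact number of planted foci (otherwise Poisson
#'   around the preset mean).
#' @param margin_um Padding around the Xi ellipsoid.
#' @return List with `image` (EdU channel), `xi` (the ground-truth
#'   [region_mask()]) and `foci` (tibble of planted centers, um).
#' @export
make_xi_volume <- function(preset, seed = 1, fixed_count = NULL,
                           voxel_size = c(0.125, 0.04, 0.04),
                           xi_radii_um = c(1.4, 1.9, 1.6),
                           margin_um = 0.5, crowded = FALSE, noise = NULL) {
  validate_preset(preset)
  noise <- noise %||% preset$noise_model
  lv <- .levels
  withr::with_seed(seed, {
    ext <- xi_radii_um + margin_um
    d <- c(ceiling(2 * ext[2] / voxel_size[2]),
           ceiling(2 * ext[3] / voxel_size[3]),
           ceiling(2 * ext[1] / voxel_size[1]))
    cen <- c(d[3] * voxel_size[1], d[1] * voxel_size[2],
             d[2] * voxel_size[3]) / 2
    ys <- axis_um(d[1], voxel_size[2]); xs <- axis_um(d[2], voxel_size[3])
    zs <- axis_um(d[3], voxel_size[1])
    xi <- ellipsoid_mask_arr(ys, xs, zs, cen, xi_radii_um)
    cnt <- if (!is.null(fixed_count)) fixed_count else
      stats::rpois(1, preset$foci_per_xi_mean)
    # super-resolution-style PSF: lateral sigma = 2 voxels, axial >= z-step
    sg <- c(max(voxel_size[1], 2 * voxel_size[2]), 2 * voxel_size[2],
            2 * voxel_size[3])
    pos <- sample_centers(0.97 * xi_radii_um, cnt, 4 * sg, crowded)
    pos <- sweep(pos, 2, cen, "+")
    a <- array(0, d)
    a[xi] <- 50 # diffuse mid-S nascent-DNA signal inside the territory
    a <- add_spots(a, voxel_size, pos, sg, lv$focus_amp)
    a <- apply_noise(a, noise)
    list(image = voxel_image(list(EdU = a), voxel_size),
         xi = region_mask(xi, "xi", voxel_size),
         foci = tibble(z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3],
                       sigma_um = sg[2], amplitude = lv$focus_amp))
  })
}

#' Generate per-cell time-lapse S-phase label sequences
#'
#' Emulates live imaging of replication patterns at a fixed frame
#' interval: each cell traverses contiguous runs non-S, early S, the
#' synchronous Xi pattern (mid S), late S and back to non-S. The Xi-pattern
#' run length (frames) is drawn from the preset's persistence
#' distribution; the onset of the Xi pattern within S can be shifted by
#' the preset (mH2A1 KD fires the Xi 1-2 frames early).
#'
#' @inheritParams make_nucleus_image
#' @param frame_interval_min Minutes between frames (> 0).
#' @param n_frames Total frames per sequence.
#' @param onset_frames Baseline early-S run length in frames before the Xi
#'   pattern appears.
#' @param fixed_persistence If set, every cell's Xi-pattern run has exactly
#'   this many frames.
#' @param deterministic_mixture Allocate persistence values to cells in
#'   the exact proportions of the distribution (largest-remainder
#'   rounding) instead of sampling, e.g. 10 cells with weights
#'   `c(2 = 0.4, 3 = 0.6)` become exactly 4 two-frame and 6 three-frame
#'   runs.
#' @return Tibble `cell_id, frame, time_min, label` with labels in
#'   `non_S, early, xi_pattern, late`.
#' @examples
#' lab <- make_timelapse_labels(condition_preset("mh2a2_kd"), 4, seed = 2)
#' table(lab$label)
#' @export
make_timelapse_labels <- function(preset, n_cells = 1,
                                  frame_interval_min = 20, seed = 1,
                                  n_frames = 40, onset_frames = 10,
                                  fixed_persistence = NULL,
                                  deterministic_mixture = FALSE) {
  validate_preset(preset)
  if (frame_interval_min <= 0) {
    stop("`frame_interval_min` must be > 0", call. = FALSE)
  }
  dist <- preset$xi_persistence_frames
  frames_avail <- as.numeric(names(dist))
  pers_alloc <- if (deterministic_mixture) {
    w <- dist / sum(dist)
    base <- floor(w * n_cells)
    rem <- n_cells - sum(base)
    if (rem > 0) {
      extra <- order(w * n_cells - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    rep(frames_avail, times = base)
  } else NULL
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_cells), function(ci) {
      s0 <- sample(2:6, 1)
      pers <- if (!is.null(fixed_persistence)) fixed_persistence else
        if (!is.null(pers_alloc)) pers_alloc[ci] else
        if (length(dist) == 1L) frames_avail else
          sample(frames_avail, 1, prob = dist)
      onset <- onset_frames + preset$xi_onset_shift_frames
      early_len <- max(1L, floor(onset) +
                         stats::rbinom(1, 1, onset - floor(onset)))
      lab <- c(rep("non_S", s0), rep("early", early_len),
               rep("xi_pattern", pers), rep("late", 6))
      lab <- c(lab, rep("non_S", max(0, n_frames - length(lab))))
      lab <- lab[seq_len(n_frames)]
      tibble(cell_id = ci, frame = seq_len(n_frames),
             time_min = (seq_len(n_frames) - 1) * frame_interval_min,
             label = lab)
    })
    dplyr::bind_rows(out)
  })
}

#' Generate a synthetic DNA-halo image
#'
#' A 2D DAPI image of a bright insoluble nuclear scaffold disc surrounded
#' by a dimmer halo of extruded chromatin loops. The halo's outer boundary
#' is a radially perturbed circle; the outer radius is chosen so the true
#' halo area equals `pi * (halo_radius_um * halo_radius_factor)^2`, i.e.
#' the measured halo radius `R = sqrt(Ah / pi)` recovers
#' `halo_radius_um * halo_radius_factor` exactly at zero irregularity. An
#' optional FISH channel concentrates signal in a radial band measured
#' from the scaffold border.
#'
#' @param scaffold_radius_um Scaffold disc radius (> 0).
#' @param halo_radius_factor Relative halo radius (>= 1 nominally; > 0).
#' @param irregularity Fractional amplitude of the radial boundary
#'   perturbation; 0 gives a perfect circle. Values that would push the
#'   halo boundary inside the scaffold raise an error.
#' @param seed Integer seed.
#' @param halo_radius_um Baseline (control) halo radius in um.
#' @param fish_band_um Optional `c(lo, hi)` distance band (um from the
#'   scaffold border) holding the FISH signal.
#' @param pixel_um Pixel size in um.
#' @param pad_um Margin beyond the outer boundary.
#' @param noise Noise model (see [condition_preset()]); default none.
#' @return List with `image` (channels DAPI and optionally FISH) and
#'   `truth` (true areas, radius, circularity of the boundary polygon).
#' @export
make_halo_image <- function(scaffold_radius_um = 4, halo_radius_factor = 1,
                            irregularity = 0, seed = 1, halo_radius_um = 5,
                            fish_band_um = NULL, pixel_um = 0.1,
                            pad_um = 2, noise = "none") {
  if (scaffold_radius_um <= 0) {
    stop("`scaffold_radius_um` must be > 0", call. = FALSE)
  }
  if (halo_radius_factor <= 0) {
    stop("`halo_radius_factor` must be > 0", call. = FALSE)
  }
  withr::with_seed(seed, {
    rh <- halo_radius_um * halo_radius_factor
    r_out <- sqrt(scaffold_radius_um^2 + rh^2)
    # smooth random radial perturbation, normalised to unit peak
    modes <- 3:6
    co <- stats::rnorm(length(modes)); si <- stats::rnorm(length(modes))
    g <- function(th) {
      v <- rep(0, length(th))
      for (i in seq_along(modes)) {
        v <- v + co[i] * cos(modes[i] * th) + si[i] * sin(modes[i] * th)
      }
      if (max(abs(v)) > 0) v / max(abs(v)) else v
    }
    rb <- function(th) r_out * (1 + irregularity * g(th))
    th_chk <- seq(0, 2 * pi, length.out = 721)
    if (min(rb(th_chk)) <= scaffold_radius_um) {
      stop("irregularity ", irregularity,
           " pushes the halo boundary inside the scaffold", call. = FALSE)
    }
    half <- max(rb(th_chk)) + pad_um
    n <- ceiling(2 * half / pixel_um)
    xs <- axis_um(n, pixel_um) - half
    ys <- axis_um(n, pixel_um) - half
    r <- sqrt(outer(ys^2, xs^2, "+"))
    th <- atan2(matrix(ys, n, n), matrix(xs, n, n, byrow = TRUE))
    rbm <- matrix(rb(as.vector(th)), n, n)
    dapi <- matrix(30, n, n)
    dapi[r <= rbm] <- 1200
    dapi[r <= scaffold_radius_um] <- 12000
    chs <- list(DAPI = dapi)
    if (!is.null(fish_band_um)) {
      fish <- matrix(30, n, n)
      band <- r > scaffold_radius_um + fish_band_um[1] &
        r <= scaffold_radius_um + fish_band_um[2] & r <= rbm
      fish[band] <- 3000
      fish[r <= scaffold_radius_um] <- 300
      chs$FISH <- fish
    }
    chs <- lapply(chs, apply_noise, noise = noise)
    # true polygon metrics of the outer boundary
    tt <- th_chk[-length(th_chk)]
    px <- rb(tt) * cos(tt); py <- rb(tt) * sin(tt)
    area <- abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
    per <- sum(sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2))
    truth <- list(
      As = pi * scaffold_radius_um^2, At = area,
      Ah = area - pi * scaffold_radius_um^2,
      R = sqrt((area - pi * scaffold_radius_um^2) / pi),
      circularity = 4 * pi * area / per^2)
    list(image = voxel_image(chs, c(1, pixel_um, pixel_um)), truth = truth)
  })
}

#' Generate an exponential growth table
#'
#' Cell counts following `n(t) = n0 * 2^(t / doubling_time_h)`, rounded to
#' whole cells, sampled daily — the substrate for doubling-time
#' estimation.
#'
#' @param n0 Seeding cell count (> 0).
#' @param doubling_time_h Population doubling time in hours (> 0).
#' @param days Number of consecutive days counted.
#' @param interval_h Hours between counts.
#' @return Tibble `t_h, cell_count`.
#' @examples
#' make_growth_table(2e5, 24, 4)
#' @export
make_growth_table <- function(n0, doubling_time_h, days = 4,
                              interval_h = 24) {
  if (n0 <= 0 || doubling_time_h <= 0) {
    stop("`n0` and `doubling_time_h` must be > 0", call. = FALSE)
  }
  t_h <- seq(0, days * 24, by = interval_h)
  tibble(t_h = t_h, cell_count = round(n0 * 2^(t_h / doubling_time_h)))
}
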
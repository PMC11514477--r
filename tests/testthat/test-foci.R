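test_that("well-separated planted spots are each recovered once, at their centers", {
  p <- condition_preset("scramble", noise_model = "none")
  xv <- make_xi_volume(p, seed = 4, fixed_count = 10)
  fo <- pick_foci_3d(xv$image, "EdU", xv$xi)
  expect_equal(nrow(fo), 10)
  vsz <- xv$image$voxel_size
  for (i in seq_len(10)) {
    dz <- abs(fo$z_um - xv$foci$z_um[i])
    dy <- abs(fo$y_um - xv$foci$y_um[i])
    dx <- abs(fo$x_um - xv$foci$x_um[i])
    j <- which.min(dz + dy + dx)
    expect_lte(dz[j], vsz[["z"]])
    expect_lte(dy[j], vsz[["y"]])
    expect_lte(dx[j], vsz[["x"]])
  }
})

test_that("a flat image and an empty mask hold no foci", {
  arr <- array(100, c(10, 10, 4))
  img <- mk_img(arr, "EdU")
  expect_equal(nrow(pick_foci_3d(img, "EdU", full_mask(arr))), 0)
  empty <- region_mask(array(FALSE, dim(arr)), "xi", c(1, 1, 1))
  expect_equal(nrow(pick_foci_3d(img, "EdU", empty)), 0)
})

test_that("picker equals the exhaustive plateau-maxima oracle on random volumes", {
  prm <- foci_params(background = 0, tolerance = 1e-9,
                     minimum_voxels = 1, fraction_f = 100)
  withr::with_seed(77, {
    for (i in 1:8) {
      d <- c(sample(6:14, 1), sample(6:14, 1), sample(3:8, 1))
      # integer-valued field forces plateaus
      arr <- array(sample.int(6, prod(d), replace = TRUE), d)
      img <- mk_img(arr, "EdU")
      got <- nrow(pick_foci_3d(img, "EdU", full_mask(arr), prm))
      expect_equal(got, oracle_plateau_maxima(arr, background = 0),
                   label = paste("volume", i))
    }
    # and under a random mask
    for (i in 1:4) {
      d <- c(10, 10, 4)
      arr <- array(sample.int(5, prod(d), replace = TRUE), d)
      msk <- array(runif(prod(d)) < 0.7, d)
      if (!any(msk)) next
      img <- mk_img(arr, "EdU")
      got <- nrow(pick_foci_3d(img, "EdU",
                               region_mask(msk, "m", c(1, 1, 1)), prm))
      expect_equal(got, oracle_plateau_maxima(arr, msk, background = 0))
    }
  })
})

test_that("detection is invariant under affine intensity maps with rescaled parameters", {
  p <- condition_preset("scramble", noise_model = "none")
  xv <- make_xi_volume(p, seed = 9, fixed_count = 25)
  a <- 3.7; b <- 120
  arr2 <- a * get_channel(xv$image, "EdU") + b
  img2 <- voxel_image(list(EdU = arr2), xv$image$voxel_size)
  prm1 <- foci_params(background = 100, tolerance = 250)
  prm2 <- foci_params(background = a * 100 + b, tolerance = a * 250)
  f1 <- pick_foci_3d(xv$image, "EdU", xv$xi, prm1)
  f2 <- pick_foci_3d(img2, "EdU", xv$xi, prm2)
  expect_equal(nrow(f1), nrow(f2))
  expect_equal(f1[, c("z_um", "y_um", "x_um", "voxels")],
               f2[, c("z_um", "y_um", "x_um", "voxels")])
})

test_that("volume and prominence filters are monotone", {
  p <- condition_preset("scramble")
  xv <- make_xi_volume(p, seed = 5, fixed_count = 40)
  fo <- pick_foci_3d(xv$image, "EdU", xv$xi)
  thr <- c(0, 1e-4, 2e-4, 0.01, 0.05)
  cnt <- vapply(thr, function(v) count_nano_rfi(fo, xv$xi, v), numeric(1))
  expect_true(all(diff(cnt) <= 0))
  # pla prominence monotonicity
  sim <- make_nucleus_image(p, seed = 31, twod = TRUE,
                            voxel_size = c(0.29, 0.1, 0.1),
                            channels = c("DAPI", "H3K27me3", "PLA"),
                            stage = "non_S")
  nuc <- truth_mask(sim$truth, 1, "nucleus")
  cnts <- vapply(c(10, 40, 100, 250), function(pr) {
    pla_spot_count(sim$image, nuc, prominence = pr)
  }, integer(1))
  expect_true(all(diff(cnts) <= 0))
})

test_that("nano-RFi counting applies the volume exclusion and the Xi restriction", {
  foci <- tibble::tibble(
    focus_id = 1:12, z_um = 1, y_um = seq(0.5, 6, length.out = 12),
    x_um = 1, voxels = 10L,
    volume_um3 = c(rep(0.001, 10), 1e-4, 1e-4),
    peak_intensity = 1, sum_intensity = 1)
  xi <- region_mask(array(TRUE, c(70, 20, 10)), "xi",
                    c(0.29, 0.1, 0.1))
  expect_equal(count_nano_rfi(foci, xi), 10)
  outside <- region_mask(array(FALSE, c(70, 20, 10)) |
                           (slice.index(array(0, c(70, 20, 10)), 2) > 18),
                         "xi", c(0.29, 0.1, 0.1))
  expect_equal(count_nano_rfi(foci, outside), 0)
})

test_that("touching foci merge into one object when separation is off", {
  arr <- array(0, c(21, 21, 3))
  img0 <- mk_img(arr, "EdU", c(1, 1, 1))
  arr <- xirep:::add_spots(arr, c(1, 1, 1),
                           rbind(c(1.5, 8.5, 10.5), c(1.5, 13.5, 10.5)),
                           sigma_um = 1.2, amplitude = 100)
  img <- mk_img(arr, "EdU", c(1, 1, 1))
  prm_sep <- foci_params(background = 1, tolerance = 5,
                         minimum_voxels = 1)
  prm_mrg <- foci_params(background = 1, tolerance = 5,
                         minimum_voxels = 1, separate_touching = FALSE)
  expect_equal(nrow(pick_foci_3d(img, "EdU", full_mask(arr), prm_sep)), 2)
  expect_equal(nrow(pick_foci_3d(img, "EdU", full_mask(arr), prm_mrg)), 1)
})

test_that("PLA spots count by strict prominence with edge exclusion", {
  arr <- array(10, c(40, 40, 1))
  pos <- rbind(c(0.5, 8, 8), c(0.5, 8, 30), c(0.5, 20, 20),
               c(0.5, 30, 10), c(0.5, 32, 32))
  arr <- xirep:::add_spots(arr, c(1, 1, 1), pos, sigma_um = 1.2,
                           amplitude = 200)
  img <- mk_img(arr, "PLA", c(1, 1, 1))
  nuc <- full_mask(arr)
  expect_equal(pla_spot_count(img, nuc, prominence = 40), 5)
  expect_equal(pla_spot_count(img, nuc, prominence = 300), 0)
  # a spot on the frame border is excluded
  arr2 <- array(10, c(40, 40, 1))
  arr2 <- xirep:::add_spots(arr2, c(1, 1, 1),
                            rbind(c(0.5, 0.6, 20), c(0.5, 20, 20)),
                            sigma_um = 1.2, amplitude = 200)
  img2 <- mk_img(arr2, "PLA", c(1, 1, 1))
  expect_equal(pla_spot_count(img2, nuc, prominence = 40), 1)
  expect_error(pla_spot_count(img2, nuc, channel = "Nope"), "missing")
})

test_that("fixed planted counts are recovered under Poisson noise", {
  p_ctrl <- condition_preset("scramble")
  p_kd <- condition_preset("mh2a1_kd")
  rec <- function(preset, n, seeds) {
    mean(vapply(seeds, function(s) {
      xv <- make_xi_volume(preset, seed = s, fixed_count = n)
      count_nano_rfi(pick_foci_3d(xv$image, "EdU", xv$xi), xv$xi)
    }, numeric(1)))
  }
  m95 <- rec(p_kd, 95, 1:4)
  m138 <- rec(p_ctrl, 138, 1:4)
  expect_lte(abs(m95 - 95), 0.03 * 95)
  expect_lte(abs(m138 - 138), 0.03 * 138)
  expect_lt(m95, m138)
})

test_that("foci parameter validation rejects bad values", {
  expect_error(foci_params(background = -1), "background")
  expect_error(foci_params(tolerance = 0), "tolerance")
  expect_error(foci_params(fraction_f = 0), "fraction_f")
  expect_error(foci_params(fraction_f = 101), "fraction_f")
  expect_error(foci_params(min_volume_um3 = -1), "min_volume")
})
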
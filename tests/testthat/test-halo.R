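test_that("halo measurement recovers the planted geometry and its identities", {
  h <- make_halo_image(4, 1, irregularity = 0, seed = 1)
  m <- measure_halo(h$image)
  expect_equal(m$R_um, 5, tolerance = 0.02)
  expect_equal(m$Ah_um2, h$truth$Ah, tolerance = 0.02)
  # R = sqrt(Ah/pi) holds exactly on the measured areas
  expect_identical(m$R_um, sqrt(m$Ah_um2 / pi))
  # digitised circle: circularity within 0.02 of 1, clamped to <= 1
  expect_gte(m$circularity, 0.98)
  expect_lte(m$circularity, 1)
  expect_lt(abs(m$circularity_raw - 1), 0.02)
  # no halo: force both thresholds equal
  thr <- 5000
  m0 <- measure_halo(h$image, total_threshold = thr,
                     scaffold_threshold = thr)
  expect_equal(m0$Ah_um2, 0)
  expect_equal(m0$R_um, 0)
  expect_error(measure_halo(h$image, total_threshold = 11000,
                            scaffold_threshold = 100),
               "inconsistent thresholds")
})

test_that("halo radius scales as sqrt(Ah) and circularity is scale-invariant", {
  h1 <- make_halo_image(4, 1, 0, seed = 2)
  h2 <- make_halo_image(4, 2, 0, seed = 2)
  m1 <- measure_halo(h1$image)
  m2 <- measure_halo(h2$image)
  expect_equal(m2$R_um / m1$R_um, 2, tolerance = 0.02)
  # halving R means quartering Ah
  expect_equal(m2$Ah_um2 / m1$Ah_um2, 4, tolerance = 0.04)
  hf <- make_halo_image(4, 1, 0, seed = 2, pixel_um = 0.05)
  mf <- measure_halo(hf$image)
  expect_lt(abs(mf$circularity_raw - m1$circularity_raw), 0.02)
})

test_that("condition comparison reports means, ratios and rank p-values", {
  withr::with_seed(3, {
    halos <- dplyr::bind_rows(
      tibble::tibble(condition = "scramble",
                     R_um = rnorm(8, 5, 0.2), circularity = 0.99),
      tibble::tibble(condition = "mh2a1_kd",
                     R_um = rnorm(8, 11, 0.5), circularity = 0.90))
  })
  cmp <- compare_halo_radii(halos, control = "scramble")
  expect_equal(cmp$radius_ratio[cmp$condition == "scramble"], 1,
               tolerance = 1e-9)
  expect_gte(cmp$radius_ratio[cmp$condition == "mh2a1_kd"], 2)
  expect_lt(cmp$p_value[cmp$condition == "mh2a1_kd"], 0.05)
  expect_error(compare_halo_radii(halos[halos$condition == "scramble", ]),
               "2 conditions")
  # identical populations give ratio 1
  same <- dplyr::mutate(halos, R_um = 5,
                        condition = rep(c("scramble", "x"), each = 8))
  cmp2 <- compare_halo_radii(same, control = "scramble")
  expect_true(all(cmp2$radius_ratio == 1))
})

test_that("irregular halo boundaries lower the measured circularity", {
  hs <- make_halo_image(4, 1.2, irregularity = 0, seed = 5)
  hi <- make_halo_image(4, 1.2, irregularity = 0.25, seed = 5)
  ms <- measure_halo(hs$image)
  mi <- measure_halo(hi$image)
  expect_lt(mi$circularity_raw, ms$circularity_raw - 0.02)
})

test_that("FISH line profiles localise a planted radial band and normalise to 1", {
  h <- make_halo_image(4, 2, 0, seed = 7, fish_band_um = c(5, 7),
                       pad_um = 9)
  scaffold <- region_mask(
    get_channel(h$image, "DAPI") > 5000, "scaffold",
    h$image$voxel_size)
  pr <- fish_line_profile(h$image, scaffold, length_um = 15,
                          report_to_um = 15, seed = 2)
  expect_equal(max(pr$intensity_norm), 1)
  peak_at <- pr$distance_um[which.max(pr$intensity_norm)]
  expect_gte(peak_at, 5)
  expect_lte(peak_at, 7)
  expect_lt(attr(pr, "background"), 0.1)
  # a border-proximal band (control-like) versus signal spread far into
  # the halo (knockdown-like): the profile mass shifts outward
  hnear <- make_halo_image(4, 2, 0, seed = 7, fish_band_um = c(0, 2),
                           pad_um = 9)
  hfar <- make_halo_image(4, 2, 0, seed = 7, fish_band_um = c(1, 10.5),
                          pad_um = 9)
  prn <- fish_line_profile(hnear$image, scaffold, length_um = 15,
                           report_to_um = 15, seed = 2)
  prf <- fish_line_profile(hfar$image, scaffold, length_um = 15,
                           report_to_um = 15, seed = 2)
  com <- function(p) sum(p$distance_um * p$intensity_norm) /
    sum(p$intensity_norm)
  expect_gt(com(prf), com(prn))
})

test_that("rays leaving the image are truncated with a warning", {
  h <- make_halo_image(3, 1, 0, seed = 1, pad_um = 1,
                       fish_band_um = c(1, 3))
  scaffold <- region_mask(get_channel(h$image, "DAPI") > 5000,
                          "scaffold", h$image$voxel_size)
  expect_warning(fish_line_profile(h$image, scaffold, length_um = 30,
                                   seed = 1),
                 "truncated")
})

test_that("hypotonic morphometrics match sphere formulas and flattening contrast", {
  ys <- (seq_len(170) - 0.5) * 0.1
  zs <- (seq_len(48) - 0.5) * 0.25
  vsz <- c(0.25, 0.1, 0.1)
  sph <- xirep:::ellipsoid_mask_arr(ys, ys, zs, c(6, 8.5, 8.5),
                                    c(5, 5, 5))
  ms <- hypotonic_morphometrics(region_mask(sph, "nucleus", vsz))
  expect_equal(ms$diameter_um, 10, tolerance = 0.02)
  expect_equal(ms$surface_um2, 4 * pi * 25, tolerance = 0.05)
  expect_equal(ms$z_extent_um, 10, tolerance = 0.03)
  # flattened ellipsoid of (near) equal volume: wider laterally, thinner
  # axially
  flat <- xirep:::ellipsoid_mask_arr(ys, ys, zs, c(6, 8.5, 8.5),
                                     c(2.5, sqrt(50), sqrt(50)))
  mf <- hypotonic_morphometrics(region_mask(flat, "nucleus", vsz))
  expect_equal(mf$volume_um3, ms$volume_um3, tolerance = 0.02)
  expect_gt(mf$lateral_extent_um, ms$lateral_extent_um)
  expect_lt(mf$z_extent_um, ms$z_extent_um)
  expect_error(hypotonic_morphometrics(
    region_mask(array(FALSE, c(4, 4, 4)), "nucleus", vsz)), "empty")
})

test_that("nuclear roundness: circle 1, 2:1 ellipse 0.5, degenerate errors", {
  ys <- (seq_len(200) - 0.5) * 0.1
  circ <- xirep:::ellipsoid_mask_arr(ys, ys, 0.5, c(0.5, 10, 10),
                                     c(0, 6, 6))
  expect_equal(nuclear_roundness(region_mask(circ, "n", c(1, 0.1, 0.1))),
               1, tolerance = 0.01)
  ell <- xirep:::ellipsoid_mask_arr(ys, ys, 0.5, c(0.5, 10, 10),
                                    c(0, 4, 8))
  expect_equal(nuclear_roundness(region_mask(ell, "n", c(1, 0.1, 0.1))),
               0.5, tolerance = 0.01)
  line <- array(FALSE, c(50, 50, 1))
  line[25, 5:45, 1] <- TRUE
  expect_error(nuclear_roundness(region_mask(line, "n", c(1, 0.1, 0.1))),
               "degenerate")
})
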
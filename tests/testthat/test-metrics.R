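vs_coarse <- c(0.29, 0.1, 0.1)

test_that("region sums are exact and shape-checked", {
  arr <- array(0, c(10, 10, 2))
  arr[1:5, 1:10, 1] <- 5
  img <- mk_img(arr, "DAPI")
  m <- region_mask(arr > 0, "r", c(1, 1, 1))
  expect_identical(region_sum(img, "DAPI", m), 250)
  expect_identical(region_sum(img, "DAPI",
                              region_mask(array(FALSE, dim(arr)), "r",
                                          c(1, 1, 1))), 0)
  bad <- region_mask(array(TRUE, c(4, 4, 1)), "r", c(1, 1, 1))
  expect_error(region_sum(img, "DAPI", bad), "dimensions differ")
})

test_that("EdU/PCNA ratio arithmetic and control normalisation", {
  cells <- tibble::tibble(
    cell_id = rep(1:4, each = 2), condition = rep(c("scramble", "kd"),
                                                  each = 4),
    region = "xi", channel = rep(c("EdU", "PCNA"), 4),
    sum = c(300, 150, 200, 100, 450, 150, 600, 200))
  r <- edu_pcna_ratio(cells, "xi", control = "scramble")
  expect_equal(r$ratio[1], 2)
  expect_equal(mean(r$ratio_norm[r$condition == "scramble"]), 1)
  expect_equal(mean(r$ratio_norm[r$condition == "kd"]), 1.5)
  cells0 <- dplyr::mutate(cells, sum = ifelse(channel == "PCNA", 0, sum))
  expect_error(edu_pcna_ratio(cells0, "xi"), "zero PCNA")
})

test_that("cV curves: degenerate frames, closed-form growth, series contrast", {
  flat <- replicate(3, mk_img(array(100, c(8, 8, 2)), "RPA"),
                    simplify = FALSE)
  m <- full_mask(array(0, c(8, 8, 2)))
  expect_warning(cvf <- rpa_cv_curve(flat, m), "pretreatment cV is zero")
  expect_true(all(cvf$cv_raw == 0))
  expect_true(all(is.na(cvf$cv_norm)))
  # two-level frames: fraction q at level 100 + a(t), rest at 100;
  # closed form cV = a*sqrt(q(1-q)) / (100 + q*a), increasing in a here
  frames <- lapply(1:4, function(t) {
    arr <- array(100, c(10, 10, 1))
    arr[1:5, , 1] <- 100 + 40 * t
    mk_img(arr, "RPA")
  })
  cv <- rpa_cv_curve(frames, full_mask(array(0, c(10, 10, 1))))
  a <- 40 * (1:4); q <- 0.5
  expect_equal(cv$cv_raw, a * sqrt(q * (1 - q)) / (100 + q * a))
  expect_equal(cv$cv_norm[1], 1)
  expect_true(all(diff(cv$cv_norm) > 0))
  # accumulating (stalling-fork) series ends higher than a static one
  static <- rpa_cv_curve(frames[c(1, 1, 1)],
                         full_mask(array(0, c(10, 10, 1))))
  expect_equal(static$cv_norm, rep(1, 3))
  expect_gt(cv$cv_norm[4], static$cv_norm[3])
})

test_that("loading coefficient: uniform-field identity over many seeded ROIs", {
  arr <- array(50, c(40, 40, 4))
  nucm <- array(FALSE, c(40, 40, 4))
  nucm[5:36, 5:36, ] <- TRUE
  xim <- array(FALSE, c(40, 40, 4))
  xim[10:15, 10:15, ] <- TRUE
  img <- voxel_image(list(Mcm2 = arr, DAPI = array(200, dim(arr))),
                     vs_coarse)
  nuc <- region_mask(nucm, "nucleus", vs_coarse)
  xi <- region_mask(xim, "xi", vs_coarse)
  vals <- vapply(1:200, function(s) {
    loading_coefficient(img, "Mcm2", xi, control_roi(nuc, xi, seed = s))
  }, numeric(1))
  expect_equal(vals, rep(1, 200))
  # target doubled inside the Xi, DAPI uniform -> exactly 2
  arr2 <- arr
  arr2[xim] <- 100
  img2 <- voxel_image(list(Mcm2 = arr2, DAPI = array(200, dim(arr))),
                      vs_coarse)
  roi2 <- control_roi(nuc, xi, seed = 1)
  expect_equal(loading_coefficient(img2, "Mcm2", xi, roi2), 2)
  imgz <- voxel_image(list(Mcm2 = array(0, dim(arr)),
                           DAPI = array(200, dim(arr))), vs_coarse)
  expect_error(loading_coefficient(imgz, "Mcm2", xi, roi2), "zero ROI")
})

test_that("loading curves anchor to control t1 and ignore row order", {
  cells <- tidyr::expand_grid(condition = c("scramble", "kd"),
                              time_point = 1:4, rep = 1:5)
  cells$coefficient <- ifelse(cells$condition == "scramble", 2,
                              2 * cells$time_point)
  lc <- loading_curve(cells, control = "scramble")
  expect_true(all(lc$value[lc$condition == "scramble"] == 1))
  expect_equal(lc$value[lc$condition == "kd" & lc$time_point == 4], 4)
  lc2 <- loading_curve(cells[sample.int(nrow(cells)), ],
                       control = "scramble")
  expect_equal(as.data.frame(lc), as.data.frame(lc2))
  expect_error(loading_curve(dplyr::filter(cells, condition == "kd"),
                             control = "scramble"), "anchor")
  expect_error(loading_curve(dplyr::filter(cells, time_point == 1),
                             control = "scramble"), "time points")
})

test_that("PLA density normalises to the control nuclear mean", {
  cells <- tibble::tibble(
    cell_id = c(1, 1, 2, 2), condition = "scramble",
    region = c("nucleus", "xi", "nucleus", "xi"),
    spots = c(10, 5, 10, 5), dapi_sum = c(1e6, 2e5, 1e6, 2e5))
  d <- pla_density(cells)
  expect_equal(d$density[1], 1e-5)
  expect_equal(mean(d$density_norm[d$region == "nucleus"]), 1)
  expect_equal(d$density_norm[d$region == "xi"], c(2.5, 2.5))
  expect_error(pla_density(dplyr::mutate(cells, dapi_sum = 0)),
               "zero DAPI")
})

test_that("Xi relative area is a DAPI share in (0, 1]", {
  cells <- tibble::tibble(
    cell_id = c(1, 1, 2, 2), condition = "c",
    region = c("xi", "nucleus", "xi", "nucleus"),
    channel = "DAPI", sum = c(1e5, 1e6, 5e5, 5e5))
  xa <- xi_relative_area(cells)
  expect_equal(xa$xi_relative_area, c(0.1, 1))
  bad <- dplyr::mutate(cells, sum = ifelse(region == "xi", 2e6, sum))
  expect_error(xi_relative_area(bad), "exceeds")
})

test_that("histone levels are control-normalised", {
  cells <- tibble::tibble(
    cell_id = 1:6, condition = rep(c("scramble", "kd"), each = 3),
    region = "xi", channel = "Mcm2",
    sum = c(100, 110, 90, 60, 80, 70), mean = 1)
  h <- histone_level(cells, "Mcm2", "xi", "scramble")
  expect_equal(mean(h$level[h$condition == "scramble"]), 1)
  expect_equal(mean(h$level[h$condition == "kd"]), 0.7)
  expect_error(histone_level(cells, "H4K20me3", "xi"), "no records")
})

test_that("DAPI SD: uniform zero and two-level closed form", {
  arr <- array(7, c(6, 6, 2))
  img <- mk_img(arr, "DAPI")
  m <- full_mask(arr)
  expect_equal(dapi_sd(img, m), 0)
  arr2 <- arr
  arr2[1:3, , ] <- 19
  expect_equal(dapi_sd(mk_img(arr2, "DAPI"), m), (19 - 7) / 2)
})

test_that("ratio metrics are invariant under joint multiplicative rescaling", {
  p <- condition_preset("scramble", noise_model = "none")
  sim <- make_nucleus_image(p, seed = 2, voxel_size = vs_coarse,
                            fixed_counts = 10, nuclear_foci = 20)
  nuc <- truth_mask(sim$truth, 1, "nucleus")
  xi <- truth_mask(sim$truth, 1, "xi")
  rec1 <- measure_regions(sim$image, list(nucleus = nuc, xi = xi),
                          condition = "scramble")
  img2 <- sim$image
  img2$channels$EdU <- img2$channels$EdU * 13
  img2$channels$PCNA <- img2$channels$PCNA * 13
  rec2 <- measure_regions(img2, list(nucleus = nuc, xi = xi),
                          condition = "scramble")
  expect_equal(edu_pcna_ratio(rec1, "xi")$ratio,
               edu_pcna_ratio(rec2, "xi")$ratio)
})
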
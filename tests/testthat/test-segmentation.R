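vs_coarse <- c(0.29, 0.1, 0.1)

test_that("triangle threshold separates a bright disc exactly and matches the geometric oracle", {
  arr <- array(10, c(40, 40, 1))
  ys <- (seq_len(40) - 0.5)
  disc <- outer((ys - 20)^2, (ys - 20)^2, "+") <= 8^2
  arr[, , 1][disc] <- 1000
  img <- mk_img(arr, "DAPI")
  m <- triangle_threshold(img, "DAPI")
  expect_identical(m$mask[, , 1], disc)
  # random skewed histograms: implementation equals the brute-force
  # perpendicular-distance oracle
  withr::with_seed(42, {
    for (i in 1:25) {
      n <- sample(500:3000, 1)
      vals <- c(rgamma(n, shape = 2, scale = 30),
                runif(sample(5:80, 1), 400, 1000))
      expect_equal(xirep:::triangle_thr(vals), oracle_triangle(vals))
    }
  })
  expect_error(triangle_threshold(mk_img(array(7, c(5, 5, 2)), "DAPI"),
                                  "DAPI"),
               "degenerate histogram")
})

test_that("masks are idempotent under re-thresholding of the binarised channel", {
  arr <- array(10, c(30, 30, 3))
  arr[10:20, 10:20, 2] <- 500
  img <- mk_img(arr, "DAPI")
  m1 <- triangle_threshold(img, "DAPI")
  bin <- mk_img(array(as.numeric(m1$mask), dim(arr)), "DAPI")
  m2 <- triangle_threshold(bin, "DAPI")
  expect_identical(m1$mask, m2$mask)
})

test_that("nucleus segmentation recovers planted nuclei and flags touching ones", {
  p <- condition_preset("scramble")
  sim <- make_nucleus_image(p, n_cells = 3, seed = 6,
                            voxel_size = vs_coarse, stage = "non_S",
                            channels = c("DAPI", "H3K27me3"))
  nuc <- segment_nucleus(sim$image)
  expect_length(nuc, 3)
  # match each mask to its ground-truth nucleus by best Jaccard
  for (ci in 1:3) {
    tm <- truth_mask(sim$truth, ci, "nucleus")$mask
    jac <- vapply(nuc, function(m) {
      sum(m$mask & tm) / sum(m$mask | tm)
    }, numeric(1))
    expect_gt(max(jac), 0.95)
  }
  # empty field: background noise only
  flat <- withr::with_seed(1, array(rpois(30 * 30 * 3, 20), c(30, 30, 3)))
  expect_length(segment_nucleus(mk_img(flat, "DAPI", vs_coarse)), 0)
  # overlapping tiles merge two nuclei into one oversized blob
  simt <- make_nucleus_image(p, n_cells = 2, seed = 7,
                             voxel_size = vs_coarse, stage = "non_S",
                             channels = c("DAPI", "H3K27me3"),
                             margin_um = -1.4, dna_content = 1)
  expect_warning(nt <- segment_nucleus(simt$image), "review")
  expect_true(any(vapply(nt, function(m) attr(m, "needs_review"),
                         logical(1))))
})

test_that("Xi segmentation counts planted copy numbers exactly", {
  p <- condition_preset("scramble")
  for (nx in c(1, 2)) {
    sim <- make_nucleus_image(p, seed = 10 + nx, voxel_size = vs_coarse,
                              stage = "non_S", n_xi = nx,
                              channels = c("DAPI", "H3K27me3"))
    nuc <- segment_nucleus(sim$image)[[1]]
    xis <- segment_xi(sim$image, nuc)
    expect_length(xis, nx)
    for (m in xis) {
      expect_true(all(m$mask[!nuc$mask] == FALSE)) # xi inside nucleus
    }
  }
  # homogeneous H3K27me3 -> empty list
  arr <- array(10, c(30, 30, 3))
  arr[8:22, 8:22, 2] <- 800
  img <- voxel_image(list(DAPI = arr, H3K27me3 = array(300, dim(arr))),
                     vs_coarse)
  nuc <- segment_nucleus(img, min_volume_um3 = 0.1)[[1]]
  expect_length(segment_xi(img, nuc), 0)
})

test_that("control ROI matches the Xi voxel count and stays disjoint", {
  p <- condition_preset("scramble")
  sim <- make_nucleus_image(p, seed = 12, voxel_size = vs_coarse,
                            stage = "non_S",
                            channels = c("DAPI", "H3K27me3"))
  nuc <- segment_nucleus(sim$image)[[1]]
  xis <- segment_xi(sim$image, nuc)
  xi <- xi_union(xis, vs_coarse)
  r1 <- control_roi(nuc, xi, seed = 3, image = sim$image)
  expect_equal(sum(r1$mask), sum(xi$mask))
  expect_false(any(r1$mask & xi$mask))
  expect_true(all(nuc$mask[r1$mask]))
  r1b <- control_roi(nuc, xi, seed = 3, image = sim$image)
  expect_identical(r1$mask, r1b$mask)
  r2 <- control_roi(nuc, xi, seed = 4, image = sim$image)
  expect_false(identical(r1$mask, r2$mask))
  # nucleus barely larger than xi -> placement failure
  small <- region_mask(xi$mask, "nucleus", vs_coarse)
  expect_error(control_roi(small, xi, seed = 1), "placement failure")
  expect_error(control_roi(nuc, region_mask(array(FALSE, dim(xi$mask)),
                                            "xi", vs_coarse)),
               "empty xi")
})

test_that("G1 gating keeps 2C EdU-negative cells from a bimodal population", {
  withr::with_seed(11, {
    cells <- tibble::tibble(
      cell_id = 1:60,
      true_phase = rep(c("g1", "g2", "s"), each = 20),
      dapi_sum = c(rnorm(20, 1e6, 2e4), rnorm(20, 2e6, 4e4),
                   runif(20, 1.3e6, 1.8e6)),
      edu_positive = rep(c(FALSE, FALSE, TRUE), each = 20))
  })
  g <- gate_g1(cells)
  expect_setequal(g$true_phase, "g1")
  expect_equal(nrow(g), 20)
  allpos <- dplyr::mutate(cells, edu_positive = TRUE)
  expect_equal(nrow(gate_g1(allpos)), 0)
  expect_error(gate_g1(cells[1:9, ]), "fewer than 10")
})

test_that("rule-based S-phase pattern calls reach 90% accuracy on a mixed population", {
  p <- condition_preset("scramble")
  stages <- rep(c("non_S", "early", "mid_xi", "late"), 6)
  sim <- make_nucleus_image(p, n_cells = 24, seed = 21,
                            voxel_size = c(0.29, 0.12, 0.12),
                            stage = stages)
  got <- character(24)
  for (i in 1:24) {
    nuc <- truth_mask(sim$truth, i, "nucleus")
    xis <- list(truth_mask(sim$truth, i, "xi"))
    cc <- truth_mask(sim$truth, i, "chromocenters")
    got[i] <- classify_sphase_pattern(sim$image, nuc, xis, cc)
  }
  expect_gte(mean(got == stages), 0.9)
  # constructed unambiguous cases are exact
  expect_identical(got[stages == "non_S"], rep("non_S", 6))
  expect_identical(got[stages == "mid_xi"], rep("mid_xi", 6))
  img <- voxel_image(list(DAPI = array(5, c(4, 4, 1))), c(1, 1, 1))
  expect_error(classify_sphase_pattern(img, full_mask(array(0, c(4, 4, 1))),
                                       list()),
               "EdU or PCNA")
})
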
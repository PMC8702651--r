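test_that("area density is the ROI foreground fraction", {
  roi <- matrix(TRUE, 100, 100)
  mask <- matrix(FALSE, 100, 100)
  mask[seq_len(500)] <- TRUE
  expect_equal(area_density(mask, roi), 0.05)
  expect_equal(area_density(roi, roi), 1)
  expect_equal(area_density(mask & FALSE, roi), 0)
  expect_error(area_density(mask, roi & FALSE), "empty")
})

test_that("perimeter index follows the boundary-count definition", {
  sq <- matrix(FALSE, 100, 100)
  sq[45:54, 45:54] <- TRUE
  expect_equal(vessel_perimeter_index(perimeter_map(sq)), 36 / 10000)
  expect_equal(vessel_perimeter_index(perimeter_map(sq & FALSE)), 0)
  # full-field mask: background is in-image only, so no boundary at all
  expect_equal(vessel_perimeter_index(perimeter_map(matrix(TRUE, 100, 100))),
               0)
})

test_that("diameter index recovers stamped calibers", {
  bar5 <- matrix(FALSE, 30, 120)
  bar5[11:15, 11:110] <- TRUE
  sk5 <- matrix(FALSE, 30, 120)
  sk5[13, 11:110] <- TRUE
  expect_equal(vessel_diameter_index(bar5, sk5), 5)

  line <- sk5
  expect_equal(vessel_diameter_index(line, line), 1)

  # pooled mean over two calibers: (300 + 700) / (100 + 100)
  two <- matrix(FALSE, 40, 120)
  two[5:7, 11:110] <- TRUE
  two[21:27, 11:110] <- TRUE
  sk2 <- matrix(FALSE, 40, 120)
  sk2[6, 11:110] <- TRUE
  sk2[24, 11:110] <- TRUE
  expect_equal(vessel_diameter_index(two, sk2), 5)

  expect_true(is.nan(vessel_diameter_index(bar5, sk5 & FALSE)))
})

test_that("complexity index matches the digital-square closed form", {
  sq <- matrix(FALSE, 100, 100)
  sq[45:54, 45:54] <- TRUE
  expect_equal(vessel_complexity_index(sq, perimeter_map(sq)),
               36^2 / (4 * pi * 100), tolerance = 1e-12)
  expect_true(is.nan(vessel_complexity_index(sq & FALSE, sq & FALSE)))
})

test_that("box-counting dimension hits the closed-form limits", {
  line <- matrix(FALSE, 320, 320)
  line[160, ] <- TRUE
  expect_equal(box_counting_dimension(line), 1, tolerance = 0.1)
  expect_equal(box_counting_dimension(matrix(TRUE, 320, 320)), 2,
               tolerance = 0.05)
  expect_true(is.nan(box_counting_dimension(matrix(FALSE, 64, 64))))
})

test_that("circular ROIs have the right physical size and position", {
  g <- angiogram(matrix(0, 320, 320))
  ctr <- c(160.5, 160.5)
  roi1 <- circle_roi(g, ctr, 1.0)
  expect_lt(abs(sum(roi1) / (pi * (160 / 3)^2) - 1), 0.01)
  # the inscribed 3-mm circle touches all four borders
  roi3 <- circle_roi(g, ctr, 3.0)
  expect_true(any(roi3[1, ]) && any(roi3[320, ]) &&
                any(roi3[, 1]) && any(roi3[, 320]))
  expect_error(circle_roi(g, ctr, 3.5), "exceeds the field")
  expect_equal(area_density(matrix(TRUE, 320, 320), roi1), 1)
})

test_that("mm-denominated morphometry is resolution-stable", {
  for (n in c(160L, 320L)) {
    g <- angiogram(matrix(0, n, n))
    vessel <- !disk_mask(n, 0.5 / g$mm_per_px)
    faz <- detect_faz(vessel, g, 3L)
    expect_equal(faz$area_mm2, pi * 0.25, tolerance = 0.02)
    expect_equal(faz$perimeter_mm, pi, tolerance = 0.02)
  }
})

test_that("the full metric record is complete and internally consistent", {
  b <- reference_bundle()
  rec <- quantify_all(b$image)
  expect_identical(ncol(rec), 24L)
  expect_identical(names(rec), mrvs:::metric_names)

  expect_lt(abs(rec$vessel_density - mean(b$gt_vessel)), 0.05)
  # disjoint branch masks make the densities exactly additive
  expect_equal(rec$big_vessel_density + rec$small_vessel_density,
               rec$vessel_density, tolerance = 1e-12)
  expect_lte(rec$vessel_skeleton_density, rec$vessel_density)
  expect_gte(rec$vessel_skeleton_fractal_dimension, 1)
  expect_lte(rec$vessel_skeleton_fractal_dimension, 2)
  expect_gte(rec$faz_circularity, 0)
  expect_lt(abs(rec$faz_area_mm2 / (pi * prod(b$spec$faz_semi_axes_mm)) - 1),
            0.10)
})

test_that("a capillary-free phantom pins the small-vessel residue", {
  b0 <- generate_phantom(phantom_spec(seed = 42L, speckle_shape = 50,
                                      branching_prob = 0))
  rec <- quantify_all(b0$image)
  # regression fixture (see the capillary-branch residue note in
  # test-segmentation.R)
  expect_equal(rec$small_vessel_density, 0.1267383, tolerance = 1e-4)
  expect_equal(rec$big_vessel_density + rec$small_vessel_density,
               rec$vessel_density, tolerance = 1e-12)
})
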
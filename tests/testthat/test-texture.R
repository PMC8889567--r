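test_that("discretization follows the fixed-bin rules", {
  roi <- roi_mask(array(TRUE, c(2, 2, 2)), c(1, 1, 1))
  dspec <- discretization_spec("dose")
  d <- image_volume(array(c(0.4, 1.0, 2.7, 99.9, 250, 0, 5, 100.0), c(2, 2, 2)),
                    modality = "DOSE_GY")
  lv <- discretize(d, roi, dspec)$levels
  expect_equal(as.vector(lv), c(1, 2, 3, 100, 100, 1, 6, 100))

  cspec <- discretization_spec("ct")
  ct <- image_volume(array(c(-1500, -1000, -999, 0, 49.9, 50, 100, 2000),
                           c(2, 2, 2)), modality = "CT_HU")
  lc <- discretize(ct, roi, cspec)$levels
  # clamp to [-1000, 100], shift +1000, bin width 50
  expect_equal(as.vector(lc), c(1, 1, 1, 21, 21, 22, 23, 23))
})

test_that("texture matrices match hand-enumerated examples", {
  # 1x1x4 strip [1,1,2,2]: two axial runs of length 2, two zones of size 2
  strip <- array(c(1L, 1L, 2L, 2L), c(1, 1, 4))
  R <- glrlm_matrix(strip)
  expect_equal(R[, 2], c(1, 1))            # the two length-2 runs
  expect_equal(R[, 1], c(24, 24))          # singleton runs in the other 12 dirs
  Z <- glszm_matrix(strip)
  expect_equal(Z, matrix(c(0, 0, 1, 1), 2, 2))

  # GLCM: symmetric, and total mass twice the enumerated unordered pairs
  set.seed(41)
  for (rep in 1:5) {
    lev <- random_level_grid(sample(3:5, 3, replace = TRUE), 4, runif(1, 0, 0.4))
    C <- glcm_matrix(lev)
    oc <- oracle_glcm(lev)
    expect_equal(C, oc)
    expect_equal(C, t(C))
    expect_equal(sum(C), 2 * (sum(oc) / 2))
  }
})

test_that("constant input collapses to the degenerate feature values", {
  lev <- array(3L, c(4, 4, 4))
  f <- texture_features_from_levels(lev)
  expect_equal(unname(f["glcm__contrast"]), 0)
  expect_equal(unname(f["glcm__correlation"]), 1)
  expect_equal(unname(f["glcm__mcc"]), 1)
  expect_equal(unname(f["ngtdm__coarseness"]), 0)  # no gray tone differences
  v <- uniform_dose(7, c(4, 4, 4))
  roi <- roi_mask(array(TRUE, c(4, 4, 4)), c(3, 3, 3))
  fo <- first_order_features(v$values[roi$values], rep(8L, 64))
  expect_equal(unname(fo["variance"]), 0)
  expect_equal(unname(fo["uniformity"]), 1)
  expect_equal(unname(fo["skewness"]), 0)
})

test_that("every texture feature matches the brute-force oracle", {
  set.seed(42)
  for (rep in 1:25) {
    dims <- sample(2:5, 3, replace = TRUE)
    lev <- random_level_grid(dims, sample(2:5, 1), runif(1, 0, 0.3))
    got <- texture_features_from_levels(lev)
    want <- oracle_texture_features(lev)
    expect_lt(max(abs(unname(got) - unname(want))), 1e-9)
  }
})

test_that("direction-aggregated features are invariant to axis permutation", {
  set.seed(43)
  lev <- random_level_grid(c(4, 5, 3), 4, 0.2)
  f0 <- texture_features_from_levels(lev)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    fp <- texture_features_from_levels(aperm(lev, perm))
    expect_equal(fp, f0, tolerance = 1e-12)
  }
})

test_that("histogram-shape features are invariant to a whole-bin CT shift", {
  set.seed(44)
  roi <- roi_mask(array(TRUE, c(5, 5, 5)), c(1, 1, 1))
  base <- array(runif(125, -800, -300), c(5, 5, 5))
  cspec <- discretization_spec("ct")
  f1 <- compute_features(image_volume(base, modality = "CT_HU"), roi, cspec)
  f2 <- compute_features(image_volume(base + 100, modality = "CT_HU"), roi, cspec)
  for (nm in c("firstorder__entropy", "firstorder__uniformity")) {
    expect_equal(unname(f2[nm]), unname(f1[nm]), tolerance = 1e-12)
  }
})

test_that("the catalog has exactly 78 features per context", {
  cat78 <- feature_catalog()
  expect_length(cat78, 78)
  expect_equal(sum(startsWith(cat78, "firstorder__")), 17)
  expect_equal(sum(startsWith(cat78, "glcm__")), 24)
  expect_equal(sum(startsWith(cat78, "glrlm__")), 16)
  expect_equal(sum(startsWith(cat78, "glszm__")), 16)
  expect_equal(sum(startsWith(cat78, "ngtdm__")), 5)
  expect_false(any(grepl("firstorder__mean$", cat78)))

  set.seed(45)
  v <- image_volume(array(runif(512, 0, 60), c(8, 8, 8)), c(3, 3, 3),
                    modality = "DOSE_GY")
  f <- compute_features(v, box_mask(), discretization_spec("dose"))
  expect_identical(names(f), cat78)
  expect_true(all(is.finite(f)))
})

test_that("degenerate ROIs are rejected", {
  v <- uniform_dose(5, c(4, 4, 4))
  single <- roi_mask(array(c(TRUE, rep(FALSE, 63)), c(4, 4, 4)), c(3, 3, 3))
  expect_error(compute_features(v, single, discretization_spec("dose")),
               "at least 2")
  empty <- roi_mask(array(FALSE, c(4, 4, 4)), c(3, 3, 3))
  expect_error(compute_features(v, empty, discretization_spec("dose")))
})
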
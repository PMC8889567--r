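test_that("resampling preserves constants and the identity case", {
  v <- uniform_dose(50, c(10, 10, 10), spacing = c(3, 3, 3))
  out <- resample_volume(v, 1.5)
  expect_equal(out$spacing_mm, c(1.5, 1.5, 1.5))
  expect_lt(max(abs(out$values - 50)), 1e-9)

  same <- resample_volume(v, c(3, 3, 3))
  expect_equal(same$values, v$values)
})

test_that("cubic resampling reproduces a linear ramp exactly", {
  shape <- c(12, 6, 6)
  ramp <- array(rep(seq(0, 33, by = 3), times = 36), shape)  # 3 Gy per voxel in x
  v <- image_volume(ramp, c(2, 2, 2), modality = "DOSE_GY")
  out <- resample_volume(v, 1)
  # analytic ramp at the new sample positions: 1.5 Gy per 1 mm step
  expected <- (seq_len(dim(out$values)[1]) - 1) * 1.5
  err <- max(abs(sweep(out$values, 1, expected)))
  expect_lt(err, 1e-6)
  expect_equal(out$values[1, 1, 1], 0, tolerance = 1e-9)
  expect_equal(out$values[dim(out$values)[1], 1, 1], 33, tolerance = 1e-9)
})

test_that("nearest resampling keeps masks boolean and extent within a voxel", {
  m <- box_mask(c(10, 10, 10), c(3, 3, 3), c(8, 8, 8), spacing = c(3, 3, 3))
  out <- resample_volume(m, 1.5, "nearest")
  expect_type(out$values, "logical")
  expect_s3_class(out, "roi_mask")
  # physical extent within one (source) voxel of the original
  ext_in <- dim(m$values) * m$spacing_mm
  ext_out <- dim(out$values) * out$spacing_mm
  expect_true(all(abs(ext_in - ext_out) <= m$spacing_mm))
  # bspline on masks is refused
  expect_error(resample_volume(m, 1.5, "bspline"), "nearest")
  expect_error(resample_volume(m, -1, "nearest"), "positive")
})

test_that("resampling preserves the ROI mean of a constant volume", {
  v <- uniform_dose(17.5, c(9, 9, 9), spacing = c(2, 2, 2))
  m <- box_mask(c(9, 9, 9), c(2, 2, 2), c(8, 8, 8), spacing = c(2, 2, 2))
  rv <- resample_volume(v, 1.5)
  rm_ <- resample_volume(m, 1.5, "nearest")
  expect_equal(mean(rv$values[rm_$values]), mean(v$values[m$values]),
               tolerance = 1e-9)
})

test_that("derived ROIs follow strict thresholds and nest", {
  shape <- c(10, 10, 10)
  lung <- box_mask(shape, c(2, 2, 2), c(9, 9, 9))
  # uniform 15 Gy: gt10 is the whole lung, gt20 empty
  r <- suppressWarnings(derive_rois(lung, NULL, uniform_dose(15, shape), "esophageal"))
  expect_equal(r$lung_gt10$values, r$lung_eval$values)
  expect_equal(sum(r$lung_gt20$values), 0)

  # zero dose: both sub-ROIs empty
  r0 <- suppressWarnings(derive_rois(lung, NULL, uniform_dose(0, shape), "esophageal"))
  expect_equal(sum(r0$lung_gt10$values), 0)
  expect_equal(sum(r0$lung_gt20$values), 0)

  # random dose: nesting holds
  set.seed(31)
  d <- image_volume(array(runif(1000, 0, 40), shape), c(3, 3, 3),
                    modality = "DOSE_GY")
  rr <- suppressWarnings(derive_rois(lung, NULL, d, "esophageal"))
  expect_true(all(rr$lung_gt20$values <= rr$lung_gt10$values))
  expect_true(all(rr$lung_gt10$values <= rr$lung_eval$values))
})

test_that("GTV subtraction defines the lung-cancer evaluation ROI", {
  shape <- c(10, 10, 10)
  lung <- box_mask(shape, c(2, 2, 2), c(9, 9, 9))
  gtv <- box_mask(shape, c(2, 2, 2), c(9, 5, 9))  # covers half the lungs
  r <- suppressWarnings(derive_rois(lung, gtv, uniform_dose(15, shape), "lung"))
  expect_equal(sum(r$lung_eval$values),
               sum(lung$values) - sum(gtv$values & lung$values))
  expect_error(derive_rois(lung, NULL, uniform_dose(15, shape), "lung"), "GTV")
  # GTV covering everything: empty evaluation ROI is an error
  all_gtv <- roi_mask(array(TRUE, shape), c(3, 3, 3))
  expect_error(derive_rois(lung, all_gtv, uniform_dose(15, shape), "lung"),
               "empty")
})

test_that("volumes round-trip through NIfTI", {
  dir <- withr::local_tempdir()
  v <- image_volume(array(rnorm(210), c(5, 6, 7)), c(1.5, 2, 2.5),
                    c(-10, 0, 4), "CT_HU")
  p <- file.path(dir, "v.nii.gz")
  write_volume(v, p)
  v2 <- read_volume(p, "CT_HU")
  expect_equal(v2$values, v$values, tolerance = 1e-6)
  expect_equal(v2$spacing_mm, v$spacing_mm)
  expect_equal(v2$origin_mm, v$origin_mm)
  m <- box_mask(c(5, 6, 7), c(1, 2, 3), c(4, 5, 6), spacing = c(1.5, 2, 2.5))
  pm <- file.path(dir, "m.nii.gz")
  write_volume(m, pm)
  expect_equal(read_mask(pm)$values, m$values)
  expect_error(read_volume(file.path(dir, "missing.nii.gz")), "not found")
})

test_that("ROI maps serialize with a JSON index", {
  dir <- withr::local_tempdir()
  lung <- box_mask(c(10, 10, 10), c(2, 2, 2), c(9, 9, 9))
  r <- suppressWarnings(derive_rois(lung, NULL, uniform_dose(15, c(10, 10, 10)),
                                    "esophageal"))
  idx_path <- write_rois(r, dir)
  idx <- jsonlite::read_json(idx_path, simplifyVector = TRUE)
  expect_setequal(idx$name, c("lung_eval", "lung_gt10", "lung_gt20"))
  expect_equal(idx$n_voxels[idx$name == "lung_gt20"], 0)
  back <- read_mask(idx$path[idx$name == "lung_eval"])
  expect_equal(back$values, r$lung_eval$values)
})
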
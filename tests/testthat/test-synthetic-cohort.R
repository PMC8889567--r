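test_that("a cohort is bit-reproducible from its spec", {
  a <- generate_cohort(tiny_cohort_spec(seed = 5))
  b <- generate_cohort(tiny_cohort_spec(seed = 5))
  expect_identical(a, b)
  c_ <- generate_cohort(tiny_cohort_spec(seed = 6))
  expect_false(identical(a, c_))
})

test_that("phantoms satisfy the anatomical and dosimetric contract", {
  coh <- generate_cohort(tiny_cohort_spec(n = 6, type = "lung", seed = 2))
  expect_length(coh, 6)
  for (p in coh) {
    expect_true(sum(p$lung_mask$values) >= 1)
    expect_false(is.null(p$gtv_mask))
    expect_true(p$rp_grade %in% 0:4)
    # lungs are low-HU, background soft tissue
    expect_lt(mean(p$ct$values[p$lung_mask$values]), -400)
    expect_gt(mean(p$ct$values[!p$lung_mask$values]), -100)
    # per-voxel doses genuinely differ between fractions (alternating beams)
    f1 <- p$fraction_doses$fractions[[1]]$values
    f2 <- p$fraction_doses$fractions[[2]]$values
    expect_gt(max(abs(f1 - f2)), 0.01)
    expect_true(all(f1 >= 0))
  }
})

test_that("empirical prevalence is calibrated to the target", {
  prev_e <- vapply(1:10, function(s) {
    mean(rp_labels(generate_cohort(tiny_cohort_spec(n = 40, seed = s))))
  }, numeric(1))
  expect_lt(abs(mean(prev_e) - 0.62), 0.05)

  prev_l <- vapply(1:10, function(s) {
    mean(rp_labels(generate_cohort(tiny_cohort_spec(n = 40, type = "lung", seed = s))))
  }, numeric(1))
  expect_lt(abs(mean(prev_l) - 0.17), 0.05)
})

test_that("grade labeling follows each cohort's positivity rule", {
  eso <- generate_cohort(tiny_cohort_spec(n = 30, seed = 9))
  g_e <- vapply(eso, `[[`, integer(1), "rp_grade")
  expect_true(all(g_e %in% c(0L, 1L, 2L)))
  expect_equal(rp_labels(eso), as.integer(g_e >= 1))

  lun <- generate_cohort(tiny_cohort_spec(n = 30, type = "lung", seed = 9))
  g_l <- vapply(lun, `[[`, integer(1), "rp_grade")
  expect_true(all(g_l %in% c(0L, 2L, 3L)))
  expect_equal(rp_labels(lun), as.integer(g_l >= 2))
})

test_that("increasing the planted MLD effect strengthens the MLD-label link", {
  cors <- vapply(c(0, 0.4, 1.2), function(eff) {
    rs <- vapply(1:6, function(s) {
      coh <- generate_cohort(tiny_cohort_spec(
        n = 50, seed = s, effect_mld = eff, effect_texture = 0, noise_sd = 0.2))
      stats::cor(vapply(coh, `[[`, numeric(1), "mld"), rp_labels(coh))
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("a cohort survives the disk round trip", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(tiny_cohort_spec(n = 3, type = "lung", seed = 4))
  manifest <- cohort_to_disk(coh, dir)
  man <- utils::read.csv(manifest)
  expect_equal(nrow(man), 3)
  back <- read_cohort(manifest)
  for (i in 1:3) {
    expect_equal(back[[i]]$ct$values, coh[[i]]$ct$values, tolerance = 1e-6)
    expect_equal(back[[i]]$lung_mask$values, coh[[i]]$lung_mask$values)
    expect_equal(back[[i]]$gtv_mask$values, coh[[i]]$gtv_mask$values)
    expect_equal(back[[i]]$rp_grade, coh[[i]]$rp_grade)
    expect_equal(length(back[[i]]$fraction_doses),
                 length(coh[[i]]$fraction_doses))
    expect_equal(back[[i]]$fraction_doses$fractions[[1]]$values,
                 coh[[i]]$fraction_doses$fractions[[1]]$values,
                 tolerance = 1e-6)
  }
  expect_error(read_cohort(file.path(dir, "nope.csv")), "nope.csv")
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(10, "esophageal", target_prevalence = 1.2))
  expect_error(cohort_spec(10, "esophageal", grid_shape = c(4, 32, 32)))
  expect_error(cohort_spec(10, "esophageal", n_fractions_range = c(0, 5)))
})
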
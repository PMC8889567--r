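# Small deterministic fixtures built in code.

uniform_dose <- function(gy, shape = c(8, 8, 8), spacing = c(3, 3, 3)) {
  image_volume(array(gy, shape), spacing, modality = "DOSE_GY")
}

box_mask <- function(shape = c(8, 8, 8), from = c(2, 2, 2), to = c(7, 7, 7),
                     spacing = c(3, 3, 3)) {
  m <- array(FALSE, shape)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  roi_mask(m, spacing)
}

uniform_series <- function(gy_per_fraction, n_fractions, shape = c(6, 6, 6)) {
  dose_series(replicate(n_fractions, uniform_dose(gy_per_fraction, shape),
                        simplify = FALSE))
}

tiny_cohort_spec <- function(n = 12, type = "esophageal", seed = 1, ...) {
  cohort_spec(n, type, grid_shape = c(16L, 16L, 12L),
              voxel_spacing_mm = c(4, 4, 4), seed = seed, ...)
}

# Feature table of pure-noise + one planted feature, for selection tests.
noise_table <- function(n = 80, p = 6, planted_effect = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, 0.5)
  X[, 1] <- X[, 1] + planted_effect * y
  colnames(X) <- c("MLD", paste0("V", seq_len(p - 1) * 5))
  list(table = as.data.frame(X), labels = y)
}
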
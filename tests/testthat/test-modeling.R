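test_that("SMOTE equalizes classes with convex synthetic points", {
  set.seed(51)
  X <- matrix(rnorm(200), 100, 2)
  y <- c(rep(1, 20), rep(0, 80))
  bal <- smote_balance(X, y, k = 5)
  expect_equal(sum(bal$labels == 1), 80)
  expect_equal(sum(bal$labels == 0), 80)
  expect_equal(sum(bal$synthetic), 60)
  # synthetic points lie inside the minority convex hull (here: coord ranges)
  synth <- bal$features[bal$synthetic, ]
  rng <- apply(X[y == 1, ], 2, range)
  expect_true(all(synth[, 1] >= rng[1, 1] & synth[, 1] <= rng[2, 1]))
  expect_true(all(synth[, 2] >= rng[1, 2] & synth[, 2] <= rng[2, 2]))
})

test_that("SMOTE with two minority points stays on their segment", {
  set.seed(52)
  X <- rbind(c(0, 0), c(1, 2), matrix(rnorm(20, 5), 10, 2))
  y <- c(1, 1, rep(0, 10))
  bal <- suppressWarnings(smote_balance(X, y, k = 5))
  synth <- bal$features[bal$synthetic, , drop = FALSE]
  # every synthetic point is t * (1,2) for t in [0,1]
  t <- synth[, 1]
  expect_true(all(t >= 0 & t <= 1))
  expect_equal(synth[, 2], 2 * t, tolerance = 1e-12)
})

test_that("SMOTE handles balanced input and degenerate minorities", {
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(0, 1), 10)
  bal <- smote_balance(X, y)
  expect_identical(bal$features, X)
  expect_false(any(bal$synthetic))
  expect_error(smote_balance(X, rep(0, 20)), "both classes")
  expect_error(smote_balance(X[1:10, ], c(1, rep(0, 9))), "at least 2")
})

test_that("ridge logistic matches an independent convex optimizer", {
  set.seed(53)
  X <- matrix(rnorm(100), 20, 5)
  y <- rbinom(20, 1, 0.5)
  for (lambda in c(0.1, 2, 50)) {
    fit <- fit_l2_logistic(X, y, lambda)
    obj <- function(b) {
      eta <- b[1] + drop(X %*% b[-1])
      -sum(y * eta - log1p(exp(eta))) + lambda / 2 * sum(b[-1]^2)
    }
    o <- stats::optim(rep(0, 6), obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))
    expect_lt(max(abs(c(fit$intercept, fit$coef) - o$par)), 1e-6)
  }
})

test_that("ridge limit and separable sign behave as expected", {
  set.seed(54)
  X <- matrix(rnorm(60), 30, 2)
  y <- rbinom(30, 1, 0.4)
  fit <- fit_l2_logistic(X, y, lambda = 1e8)
  expect_lt(max(abs(fit$coef)), 1e-4)
  expect_equal(predict_logistic(fit, X)[1], mean(y), tolerance = 1e-3)

  toy <- matrix(c(-1, 1), 2, 1)
  fit2 <- fit_l2_logistic(toy, c(0, 1), lambda = 1)
  expect_gt(fit2$coef[1], 0)
})

test_that("ROC AUC is the Mann-Whitney pairwise statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0)), 1)
  expect_equal(pr_auc(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0)), 1)
  set.seed(55)
  for (rep in 1:10) {
    s <- rnorm(40); y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    # brute force over all positive-negative pairs, ties at 1/2
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(s, y), mean(cmp), tolerance = 1e-12)
  }
  # ties in scores are shared between classes
  expect_equal(roc_auc(c(1, 1, 0), c(1, 0, 0)), 0.75)
  expect_error(roc_auc(rnorm(5), rep(1, 5)), "both classes")
})

test_that("PR AUC of random scores approximates the prevalence", {
  set.seed(56)
  pis <- replicate(400, {
    y <- c(rep(1, 17), rep(0, 83))
    pr_auc(rnorm(100), y)
  })
  expect_lt(abs(mean(pis) - 0.17), 0.05)
})

test_that("the Z comparison matches hand evaluation and is antisymmetric", {
  # Table-like values: means 0.75 vs 0.67, SDs 0.10/0.11, n = 500
  set.seed(57)
  a <- rnorm(500); a <- (a - mean(a)) / sd(a) * 0.10 + 0.75
  b <- rnorm(500); b <- (b - mean(b)) / sd(b) * 0.11 + 0.67
  cm <- compare_auc(a, b)
  expect_equal(cm$z, 0.08 / sqrt((0.01 + 0.0121) / 500), tolerance = 1e-9)
  expect_lt(cm$p_value, 0.05)
  cm_rev <- compare_auc(b, a)
  expect_equal(cm_rev$z, -cm$z)
  expect_equal(cm_rev$p_value, cm$p_value)
  same <- compare_auc(a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_auc(a, a[1:10]), "equal length")
})

test_that("ROC AUC agrees with an independent implementation", {
  set.seed(58)
  for (rep in 1:5) {
    s <- rnorm(70); y <- rbinom(70, 1, 0.4)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
    expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
  }
})
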
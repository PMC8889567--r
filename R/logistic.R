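#' L2-regularized logistic regression
#'
#' Fits a multivariate logistic model by Newton iteration (IRLS) on the
#' penalized negative log-likelihood
#' \deqn{-\sum_i [y_i \eta_i - \log(1 + e^{\eta_i})] + \frac{\lambda}{2}\|\beta\|^2}
#' with the intercept unpenalized. The objective is strictly convex for
#' `lambda > 0`, so the fit is deterministic given the data and strength.
#' `lambda = 0` gives the unregularized maximum-likelihood fit (used for
#' univariate screening).
#'
#' @param x numeric matrix of predictors (standardized by the caller for
#'   penalized fits).
#' @param y 0/1 response.
#' @param lambda non-negative L2 penalty on the coefficients.
#' @param max_iter,tol Newton iteration controls.
#' @param beta_init optional warm-start coefficient vector
#'   `c(intercept, coef)`; the converged optimum does not depend on it.
#' @return List with `intercept`, `coef`, `converged`, `n_iter`.
#' @export
fit_l2_logistic <- function(x, y, lambda = 0, max_iter = 100L, tol = 1e-8,
                            beta_init = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("x and y dimensions disagree")
  X <- cbind(1, x)
  pen <- c(0, rep(lambda, p))
  if (is.null(beta_init)) {
    beta <- numeric(p + 1)
    beta[1] <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  } else {
    beta <- beta_init
  }
  objective <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(pmin(eta, 700)))) + sum(pen * b^2) / 2
  }
  converged <- FALSE
  it <- 0L
  obj <- objective(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) {
      # near-singular Hessian (e.g. separation at lambda = 0): ridge the solve
      step <- solve(H + diag(1e-8, p + 1), grad)
    }
    # backtracking line search keeps the Newton iteration globally stable
    # (matters under separation, where full steps can overshoot)
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      cobj <- objective(cand)
      if (cobj <= obj + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    beta <- beta + alpha * step
    obj <- objective(beta)
    if (max(abs(alpha * step)) < tol) { converged <- TRUE; break }
  }
  if (!converged && lambda > 0) {
    stop("L2 logistic fit did not converge at lambda = ", lambda)
  }
  list(intercept = beta[1], coef = stats::setNames(beta[-1], colnames(x)),
       converged = converged, n_iter = it)
}

#' @rdname fit_l2_logistic
#' @param fit a fit returned by `fit_l2_logistic()`.
#' @param newx matrix of predictors.
#' @return `predict_logistic()` returns predicted probabilities.
#' @export
predict_logistic <- function(fit, newx) {
  stats::plogis(drop(as.matrix(newx) %*% fit$coef) + fit$intercept)
}

# Fast univariate logistic fit returning the Wald p-value of the slope.
# Mirrors glm(binomial) but avoids its per-call overhead; used thousands of
# times during screening and repeated-CV ranking.
univariate_logistic_p <- function(x, y) {
  sx <- stats::sd(x)
  if (!is.finite(sx) || sx == 0) return(list(p = NA_real_, slope = NA_real_))
  xs <- (x - mean(x)) / sx
  X <- cbind(1, xs)
  beta <- c(stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6)), 0)
  for (it in 1:50) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X)
    step <- solve(H, drop(crossprod(X, y - mu)))
    msz <- max(abs(step))
    if (msz > 15) step <- step * (15 / msz)
    beta <- beta + step
    if (msz < 1e-9) break
  }
  # complete separation: slope diverges, Wald p -> treat as 0 (kept)
  if (abs(beta[2]) > 25) return(list(p = 0, slope = beta[2] / sx))
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  se <- sqrt(diag(solve(crossprod(X * w, X))))[2]
  z <- beta[2] / se
  list(p = 2 * stats::pnorm(-abs(z)), slope = beta[2] / sx)
}
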
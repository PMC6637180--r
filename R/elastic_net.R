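#' Fit a Gaussian elastic net at fixed penalties
#'
#' Minimizes
#' \deqn{\frac{1}{2n}\sum_i (y_i - b_0 - x_i b)^2 +
#'       \lambda\left(\alpha \|b\|_1 + \frac{1-\alpha}{2}\|b\|_2^2\right)}
#' by cyclic coordinate descent.  With `standardize = TRUE` (the default, and
#' the convention used throughout training) the penalty is applied to
#' coefficients of unit-population-variance predictors, and the returned
#' coefficients are rescaled to the input scale; the intercept is never
#' penalized.  Zero-variance predictor columns get coefficient 0.
#'
#' @param X Numeric matrix, samples x predictors (the rank-transformed
#'   feature matrix in the training pipeline).
#' @param y Numeric response vector (the arcsine-sqrt-transformed metabolite).
#' @param alpha Elastic net mixing parameter in `[0, 1]` (1 = lasso,
#'   0 = ridge).
#' @param lambda Non-negative sparsity penalty; may be a decreasing vector,
#'   in which case the whole path is fit with warm starts.
#' @param standardize Standardize predictors internally for the penalty.
#' @param tol Relative convergence threshold: a coordinate sweep converges
#'   when no update satisfies `v_j * (delta b_j)^2 > tol * mean((y - mean(y))^2)`
#'   (the usual coordinate-descent criterion, scaled by the null deviance).
#'   Tighten (e.g. `1e-10`) for high-precision solutions.
#' @param max_iter Maximum coordinate-descent sweeps per lambda.
#' @return For scalar `lambda`, a list with `coefficients` (named vector on
#'   the input scale), `intercept`, `alpha`, `lambda`; for a vector, the
#'   coefficient path as a matrix `coefficients` (p x n_lambda) plus
#'   `intercepts`.
#' @export
fit_elastic_net <- function(X, y, alpha, lambda, standardize = TRUE,
                            tol = 1e-7, max_iter = 100000L) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in predictors or response")
  stopifnot(length(y) == nrow(X), alpha >= 0, alpha <= 1, all(lambda >= 0))
  n <- nrow(X)
  if (n < 3) stop("elastic net fitting requires at least 3 samples")
  single <- length(lambda) == 1L
  lambda_sorted <- sort(lambda, decreasing = TRUE)
  if (!isTRUE(all.equal(lambda, lambda_sorted)) && !single)
    stop("lambda path must be decreasing")

  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  sds <- sqrt(colMeans(Xc^2))
  scale_back <- rep(1, ncol(X))
  if (standardize) {
    ok <- sds > 0
    Xc[, ok] <- sweep(Xc[, ok, drop = FALSE], 2, sds[ok], "/")
    scale_back[ok] <- sds[ok]
  }
  ym <- mean(y)
  ydev <- mean((y - ym)^2)
  eps <- tol * if (ydev > 0) ydev else 1
  fit <- enet_path_cd(Xc, y - ym, alpha, lambda, eps, as.integer(max_iter))
  beta <- fit$beta / scale_back
  rownames(beta) <- colnames(X)
  intercepts <- ym - as.numeric(crossprod(xm, beta))
  if (single)
    list(coefficients = stats::setNames(beta[, 1], colnames(X)),
         intercept = intercepts[1], alpha = alpha, lambda = lambda)
  else
    list(coefficients = beta, intercepts = intercepts, alpha = alpha,
         lambda = lambda)
}

#' Elastic net penalized objective
#'
#' Evaluates the objective [fit_elastic_net()] minimizes at an arbitrary
#' `(b0, b)`, including the internal-standardization weights on the penalty,
#' so that solver output can be compared against independent minimizers.
#'
#' @inheritParams fit_elastic_net
#' @param b0 Intercept.
#' @param b Coefficient vector on the input scale.
#' @return The scalar objective value.
#' @export
enet_objective <- function(X, y, b0, b, alpha, lambda, standardize = TRUE) {
  X <- as.matrix(X)
  s <- if (standardize) {
    sds <- sqrt(colMeans(sweep(X, 2, colMeans(X))^2))
    ifelse(sds > 0, sds, 1)
  } else rep(1, ncol(X))
  r <- y - b0 - as.numeric(X %*% b)
  mean(r^2) / 2 +
    lambda * (alpha * sum(s * abs(b)) + (1 - alpha) / 2 * sum((s * b)^2))
}

#' Lambda path for an elastic net fit
#'
#' Geometric sequence of `n_lambda` values from `lambda_max` (the smallest
#' penalty at which all coefficients are zero, computed on the standardized
#' scale) down to `lambda_min_ratio * lambda_max`.  The default ratio follows
#' the usual convention: 1e-3 when `n > p`, 1e-2 otherwise.  For `alpha`
#' close to 0 the ridge limit has no finite `lambda_max`; the path is then
#' anchored at `alpha = 0.001` as is customary.
#'
#' @inheritParams fit_elastic_net
#' @param n_lambda Number of penalties along the path.
#' @param lambda_min_ratio Ratio of the smallest to the largest penalty;
#'   `NULL` selects the dimension-dependent default.
#' @return Decreasing numeric vector of length `n_lambda`.
#' @export
enet_lambda_path <- function(X, y, alpha, n_lambda = 100L,
                             lambda_min_ratio = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(lambda_min_ratio))
    lambda_min_ratio <- if (n > ncol(X)) 1e-3 else 1e-2
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  sds <- sqrt(colMeans(Xc^2))
  ok <- sds > 0
  Xs <- sweep(Xc[, ok, drop = FALSE], 2, sds[ok], "/")
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / n / max(alpha, 1e-3)
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}
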
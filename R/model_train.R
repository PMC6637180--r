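#' Training configuration
#'
#' Collects the hyperparameter search and cross-validation settings for
#' [train_all()].  Defaults: the mixing parameter is searched over
#' `seq(0.05, 1, by = 0.05)`; each alpha gets a geometric path of
#' `n_lambda = 100` sparsity penalties (see [enet_lambda_path()]); ten-fold
#' cross-validation selects the `(alpha, lambda)` pair with the smallest
#' cross-validated mean squared error (the Gaussian deviance, i.e. the
#' cross-validated likelihood criterion); metabolites whose pooled
#' out-of-fold Spearman correlation reaches `well_predicted_threshold`
#' (default 0.3) are flagged well predicted.
#'
#' @param alpha_grid Numeric vector of mixing parameters in `[0, 1]`.
#' @param n_lambda Length of each lambda path.
#' @param cv_scheme `"kfold"` or `"loocv"` (leave-one-out, i.e. `k = n`).
#' @param k Number of folds for `"kfold"`.
#' @param well_predicted_threshold Spearman threshold for the well-predicted
#'   flag (inclusive).
#' @param seed Integer seed controlling fold assignment; one shuffle is drawn
#'   per run and shared by every metabolite so scores are comparable.
#' @param lambda_min_ratio Passed to [enet_lambda_path()]; `NULL` for the
#'   dimension-dependent default.
#' @return A `train_config` object.
#' @export
train_config <- function(alpha_grid = seq(0.05, 1, by = 0.05),
                         n_lambda = 100L,
                         cv_scheme = c("kfold", "loocv"),
                         k = 10L,
                         well_predicted_threshold = 0.3,
                         seed = 1L,
                         lambda_min_ratio = NULL) {
  cv_scheme <- match.arg(cv_scheme)
  stopifnot(length(alpha_grid) >= 1, all(alpha_grid >= 0 & alpha_grid <= 1),
            k >= 2, n_lambda >= 2)
  structure(list(alpha_grid = alpha_grid, n_lambda = as.integer(n_lambda),
                 cv_scheme = cv_scheme, k = as.integer(k),
                 well_predicted_threshold = well_predicted_threshold,
                 seed = as.integer(seed), lambda_min_ratio = lambda_min_ratio),
            class = "train_config")
}

# Seeded fold assignment shared across metabolites: a shuffled 1..k label per
# sample, balanced to within one sample per fold.
assign_folds <- function(n, config) {
  k <- if (config$cv_scheme == "loocv") n else min(config$k, n)
  if (k < 2) stop("cross-validation requires at least 2 folds")
  sample(rep_len(seq_len(k), n))
}

spearman_or_zero <- function(pred, obs) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(0)
  stats::cor(pred, obs, method = "spearman")
}

# Pre-standardized design matrices for cross-validation: the predictor matrix
# and fold assignment are shared by every metabolite (and every alpha), so
# centering/scaling is done once per run instead of once per fit.
make_cv_context <- function(X_t, folds) {
  standardize_block <- function(M) {
    xm <- colMeans(M)
    Mc <- sweep(M, 2, xm)
    s <- sqrt(colMeans(Mc^2))
    ok <- s > 0
    Mc[, ok] <- sweep(Mc[, ok, drop = FALSE], 2, s[ok], "/")
    list(Xs = Mc, xm = xm, s = ifelse(ok, s, 1))
  }
  fold_ids <- sort(unique(folds))
  list(
    folds = folds, fold_ids = fold_ids,
    full = standardize_block(X_t),
    per_fold = lapply(fold_ids, function(f)
      standardize_block(X_t[folds != f, , drop = FALSE]))
  )
}

# Path fit on a pre-standardized block; returns coefficients on the input
# scale plus per-lambda intercepts.
path_fit_block <- function(block, y, alpha, lambda, tol = 1e-7,
                           max_iter = 100000L) {
  ym <- mean(y)
  yc <- y - ym
  ydev <- mean(yc^2)
  eps <- tol * if (ydev > 0) ydev else 1
  fit <- enet_path_cd(block$Xs, yc, alpha, lambda, eps, as.integer(max_iter))
  beta <- fit$beta / block$s
  list(beta = beta, intercepts = ym - as.numeric(crossprod(block$xm, beta)))
}

#' Cross-validated elastic net for one metabolite
#'
#' For each alpha in the grid, builds a lambda path on the full data, fits
#' the path on each training fold, and accumulates held-out squared error
#' per `(alpha, lambda)`.  The pair minimizing the cross-validated MSE is
#' selected (ties broken toward the larger lambda, then the earlier alpha),
#' the model is refit on all samples at that pair, and the metabolite is
#' scored by the Spearman correlation between the pooled out-of-fold
#' predictions and the observed response.
#'
#' @param X_t Rank-inverse-normal-transformed predictor matrix
#'   (samples x features).
#' @param y_t Arcsine-sqrt-transformed response vector.
#' @param config A [train_config()].
#' @param folds Optional integer fold labels (one per sample); when omitted
#'   a seeded assignment is drawn from `config$seed`.
#' @param context Optional precomputed standardization context (internal;
#'   [train_all()] builds one per run since the design matrix and folds are
#'   shared by every metabolite).
#' @return A `metabolite_fit` list: `coefficients`, `intercept`, `alpha`,
#'   `lambda`, `cv_spearman`, `n_nonzero`, `n_positive`, `n_negative`,
#'   `cv_mse`, and the pooled out-of-fold predictions `oof_pred`.
#' @export
cross_validate_metabolite <- function(X_t, y_t, config = train_config(),
                                      folds = NULL, context = NULL) {
  X_t <- as.matrix(X_t)
  n <- nrow(X_t)
  if (is.null(folds)) {
    set.seed(config$seed)
    folds <- assign_folds(n, config)
  }
  stopifnot(length(folds) == n)
  if (is.null(context)) context <- make_cv_context(X_t, folds)

  best <- NULL
  for (a in config$alpha_grid) {
    lam <- enet_lambda_path(X_t, y_t, a, config$n_lambda,
                            config$lambda_min_ratio)
    oof <- matrix(NA_real_, n, length(lam))
    for (fi in seq_along(context$fold_ids)) {
      hold <- folds == context$fold_ids[fi]
      fit <- path_fit_block(context$per_fold[[fi]], y_t[!hold], a, lam)
      oof[hold, ] <- sweep(X_t[hold, , drop = FALSE] %*% fit$beta,
                           2, fit$intercepts, "+")
    }
    mse <- colMeans((oof - y_t)^2)
    # prefer the sparser (larger-lambda) end of ties within this alpha
    li <- which(mse <= min(mse))[1]
    if (is.null(best) || mse[li] < best$mse) {
      best <- list(alpha = a, lambda = lam[li], mse = mse[li],
                   oof = oof[, li], lambda_path = lam, lambda_index = li)
    }
  }

  refit_path <- path_fit_block(context$full, y_t, best$alpha,
                               best$lambda_path)
  coef <- refit_path$beta[, best$lambda_index]
  b0 <- refit_path$intercepts[best$lambda_index]
  structure(list(
    coefficients = stats::setNames(coef, colnames(X_t)),
    intercept = b0,
    alpha = best$alpha,
    lambda = best$lambda,
    cv_mse = best$mse,
    cv_spearman = spearman_or_zero(best$oof, y_t),
    n_nonzero = sum(coef != 0),
    n_positive = sum(coef > 0),
    n_negative = sum(coef < 0),
    oof_pred = best$oof
  ), class = "metabolite_fit")
}

#' Train per-metabolite prediction models on paired tables
#'
#' The full training pipeline: align the two tables on shared samples,
#' total-sum scale both, apply the prevalence/abundance (and optional
#' variance) filter independently to each, rank-inverse-normal transform the
#' predictors, arcsine-sqrt transform the metabolites, and run
#' [cross_validate_metabolite()] for every metabolite with one shared fold
#' assignment.  Constant metabolite columns are dropped with a warning (their
#' predictability is undefined).
#'
#' The returned weight matrix spans the union of features receiving a nonzero
#' coefficient in any model; poorly predicted metabolites are retained but
#' flagged.  A metabolite is flagged well predicted when its cross-validated
#' Spearman correlation is at least `config$well_predicted_threshold` and its
#' model uses at least one predictor.
#'
#' @param X Sequence-feature [abundance_table()] (taxa/OTUs/gene families).
#' @param Y Metabolite [abundance_table()] over overlapping samples.
#' @param config A [train_config()].
#' @param policy A [filter_policy()] applied to both tables.
#' @return A [weight_matrix()] whose `"fits"` attribute keeps the full
#'   per-metabolite fit objects and whose `"summary"` attribute is the
#'   [summary.weight_matrix()] data frame.
#' @export
train_all <- function(X, Y, config = train_config(), policy = filter_policy()) {
  aligned <- align_samples(X, Y)
  Xn <- prepare_features(aligned$x, policy)
  Yn <- if (aligned$y$normalized) aligned$y else tss_normalize(aligned$y)
  Yn <- prevalence_abundance_filter(Yn, policy)
  const_y <- apply(Yn$values, 2, function(v) max(v) == min(v))
  if (any(const_y)) {
    warning("dropping constant metabolite(s): ",
            paste(feature_ids(Yn)[const_y], collapse = ", "))
    Yn$values <- Yn$values[, !const_y, drop = FALSE]
  }
  if (ncol(Yn$values) == 0) stop("no metabolites survive filtering")

  X_t <- rank_inverse_normal_matrix(Xn$values)
  Y_t <- arcsine_sqrt(Yn$values)

  set.seed(config$seed)
  folds <- assign_folds(nrow(X_t), config)
  ctx <- make_cv_context(X_t, folds)

  fits <- lapply(seq_len(ncol(Y_t)), function(j) {
    cross_validate_metabolite(X_t, Y_t[, j], config, folds = folds,
                              context = ctx)
  })
  names(fits) <- colnames(Y_t)

  coef_all <- vapply(fits, `[[`, numeric(ncol(X_t)), "coefficients")
  if (is.null(dim(coef_all)))
    coef_all <- matrix(coef_all, ncol = length(fits),
                       dimnames = list(colnames(X_t), names(fits)))
  used <- rowSums(coef_all != 0) > 0
  coef_used <- coef_all[used, , drop = FALSE]

  cv_r <- vapply(fits, `[[`, numeric(1), "cv_spearman")
  nnz <- vapply(fits, `[[`, numeric(1), "n_nonzero")
  wp <- cv_r >= config$well_predicted_threshold & nnz > 0

  wm <- weight_matrix(
    coef_used,
    intercepts = vapply(fits, `[[`, numeric(1), "intercept"),
    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
    lambda = vapply(fits, `[[`, numeric(1), "lambda"),
    cv_spearman = cv_r,
    well_predicted = wp,
    threshold = config$well_predicted_threshold
  )
  attr(wm, "fits") <- fits
  attr(wm, "summary") <- summary(wm)
  attr(wm, "folds") <- folds
  wm
}
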
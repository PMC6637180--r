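#' Generate paired feature/metabolite tables with known ground truth
#'
#' Emulates the statistical structure of paired metagenome/metabolome
#' training data.  Sequence features follow a sparse, heavy-tailed
#' compositional model: per-feature log-normal abundances whose log-means are
#' shifted by a small number of latent community gradients (sparse random
#' factor loadings, the analogue of the population structure real cohorts
#' show), per-feature prevalence introducing zeros, and row renormalization
#' to sum 1.  Each planted metabolite is constructed on the arcsine-sqrt
#' scale as `intercept + (rank-INT features) . (sparse signed weights) +
#' noise`, mapped back through the inverse transform; noise metabolites are
#' independent of the features.  The metabolite table is renormalized
#' row-wise, so like real compositional metabolomes it carries a mild
#' per-sample coupling on top of the planted linear signal.
#'
#' The signal is planted exactly on the transformed scales where the models
#' fit, making parameter recovery a well-posed oracle; `misspecified = TRUE`
#' instead plants the linear signal on the raw relative-abundance scale, to
#' probe robustness to transform misspecification.
#'
#' @param n_samples Number of samples (>= 10).
#' @param n_features Number of sequence features.
#' @param n_metabolites Number of metabolites.
#' @param frac_planted Fraction of metabolites carrying planted signal.
#' @param support_size Nonzero weights per planted metabolite
#'   (< `n_features`); the default 8 gives model sizes of the order seen in
#'   real gut training data (median around 10).
#' @param noise_sd Gaussian noise s.d. on the transformed scale.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param zero_fraction Target fraction of zero cells in the feature table.
#' @param signal_sd Standard deviation of the planted linear predictor on
#'   the transformed scale (weight vectors are scaled to this norm).
#' @param n_factors Number of latent community gradients shaping the
#'   feature covariance.
#' @param misspecified Plant signal on the raw instead of transformed scale.
#' @return A `synthetic_dataset` list: `X`, `Y` (normalized
#'   [abundance_table()]s), `true_weights` (features x metabolites),
#'   `true_intercepts`, `planted_metabolite_ids`, `noise_metabolite_ids`,
#'   `noise_sd`, `seed`, plus the generative parameters needed by
#'   [make_validation_cohort()].
#' @export
generate_synthetic_dataset <- function(n_samples = 50L, n_features = 200L,
                                       n_metabolites = 30L,
                                       frac_planted = 0.67,
                                       support_size = 8L, noise_sd = 0.05,
                                       seed = 1L, zero_fraction = 0.35,
                                       signal_sd = 0.25, n_factors = 4L,
                                       misspecified = FALSE) {
  stopifnot(n_samples >= 10, support_size < n_features,
            frac_planted >= 0, frac_planted <= 1, noise_sd >= 0,
            zero_fraction >= 0, zero_fraction < 0.9)
  set.seed(seed)
  feat_ids <- sprintf("F%03d", seq_len(n_features))
  samp_ids <- sprintf("S%03d", seq_len(n_samples))
  met_ids <- sprintf("M%02d", seq_len(n_metabolites))

  mu <- stats::rnorm(n_features, 0, 1.5)
  lo <- max(0.02, 1 - zero_fraction - 0.3)
  hi <- min(1, 1 - zero_fraction + 0.3)
  prev <- stats::runif(n_features, lo, hi)
  # sparse loadings: each gradient shifts the log-abundance of ~30% of
  # features, giving the feature table a low-rank covariance component
  draw_loadings <- function()
    matrix(stats::rnorm(n_features * n_factors, 0, 1.5) *
             (stats::runif(n_features * n_factors) < 0.3),
           n_features, n_factors)
  loadings <- draw_loadings()

  draw_X <- function(sids, mu_d, prev_d, load_d) {
    n <- length(sids)
    fscores <- matrix(stats::rnorm(n * n_factors), n, n_factors)
    logmean <- matrix(mu_d, n, n_features, byrow = TRUE) +
      fscores %*% t(load_d)
    raw <- matrix(stats::rlnorm(n * n_features, logmean, 1), n, n_features) *
      (matrix(stats::runif(n * n_features), n, n_features) <
         matrix(prev_d, n, n_features, byrow = TRUE))
    # an all-zero sample cannot be normalized; give it its most prevalent
    # feature at the median abundance (vanishingly rare at realistic sizes)
    zero_rows <- rowSums(raw) == 0
    if (any(zero_rows)) {
      j <- which.max(prev_d)
      raw[zero_rows, j] <- exp(mu_d[j])
    }
    dimnames(raw) <- list(sids, feat_ids)
    raw
  }
  X_raw <- draw_X(samp_ids, mu, prev, loadings)
  X <- abundance_table(X_raw / rowSums(X_raw), normalized = TRUE)

  n_planted <- round(frac_planted * n_metabolites)
  planted <- met_ids[seq_len(n_planted)]
  noise_m <- setdiff(met_ids, planted)
  eligible <- which(prev >= stats::median(prev))

  W <- matrix(0, n_features, n_metabolites,
              dimnames = list(feat_ids, met_ids))
  b0 <- stats::setNames(stats::runif(n_metabolites, 0.5, 0.8), met_ids)
  for (m in planted) {
    supp <- sample(eligible, support_size)
    w <- stats::runif(support_size, 0.5, 1) *
      sample(c(-1, 1), support_size, replace = TRUE)
    W[supp, m] <- w / sqrt(sum(w^2)) * signal_sd
  }
  mu_met <- stats::rnorm(length(noise_m), log(0.3), 0.3)

  build_Y <- function(Z, X_values) {
    n <- nrow(Z)
    raw <- matrix(0, n, n_metabolites, dimnames = list(rownames(Z), met_ids))
    for (m in planted) {
      lin <- if (misspecified)
        b0[m] + as.numeric(X_values %*% W[, m]) * 25
      else b0[m] + as.numeric(Z %*% W[, m])
      raw[, m] <- inverse_arcsine_sqrt(lin + stats::rnorm(n, 0, noise_sd))
    }
    for (i in seq_along(noise_m))
      raw[, noise_m[i]] <- stats::rlnorm(n, mu_met[i], 0.4)
    abundance_table(raw / rowSums(raw), normalized = TRUE)
  }
  Z <- rank_inverse_normal_matrix(X$values, constant_action = "zero")
  Y <- build_Y(Z, X$values)

  structure(list(X = X, Y = Y, true_weights = W, true_intercepts = b0,
                 planted_metabolite_ids = planted,
                 noise_metabolite_ids = noise_m,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 params = list(mu = mu, prev = prev, mu_met = mu_met,
                               lo = lo, hi = hi, loadings = loadings,
                               n_factors = n_factors,
                               draw_loadings = draw_loadings,
                               draw_X = draw_X,
                               misspecified = misspecified)),
            class = "synthetic_dataset")
}

# Theoretical rank-INT value of raw abundance x under its own generative
# marginal (zero mass 1 - prev, log-normal above): the transformed value a
# within-distribution cohort of typical size would assign.  Zeros sit at the
# center of the zero mass, mirroring average-rank tie handling.
quantile_transform_truth <- function(x, mu_d, prev_d, clamp = 0.01) {
  f <- ifelse(x > 0,
              (1 - prev_d) + prev_d * stats::plnorm(x, mu_d, 1),
              (1 - prev_d) / 2)
  stats::qnorm(pmin(pmax(f, clamp), 1 - clamp))
}

#' Draw a validation cohort from a (possibly drifted) generative model
#'
#' New samples come from the training dataset's generative model with a
#' drift-controlled perturbation of the feature distribution: per-feature
#' log-means, prevalences and gradient loadings are interpolated between the
#' training values (`drift = 0`) and a freshly drawn, unrelated set
#' (`drift = 1`).  `drift` may be a vector (one value per new sample) to
#' build a graded cohort for RTSI-versus-accuracy experiments.
#'
#' True metabolite profiles are generated from each sample's transformed
#' feature values *under its own generative distribution* (theoretical
#' quantile positions), with the feature-metabolite linkage itself drifting:
#' at drift `d` the effective weights are `(1 - d) * W + d * W_alt`, where
#' `W_alt` is an unrelated sparse weight matrix.  A fully drifted community
#' is thus unrelated both in its feature distribution and in which features
#' drive which metabolites — the out-of-domain situation the RTSI score is
#' designed to flag — and prediction accuracy genuinely degrades with
#' drift.
#'
#' @param dataset A `synthetic_dataset` from [generate_synthetic_dataset()].
#' @param n_new_samples Number of new samples (>= 2).
#' @param drift Scalar or per-sample vector in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list: `X` (new-cohort feature [abundance_table()]), `Y_true`
#'   (the matching true metabolite table), `drift` (per-sample).
#' @export
make_validation_cohort <- function(dataset, n_new_samples, drift = 0,
                                   seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"), n_new_samples >= 2,
            all(drift >= 0 & drift <= 1))
  drift <- rep_len(drift, n_new_samples)
  p <- dataset$params
  n_features <- length(p$mu)
  set.seed(seed)
  mu_alt <- stats::rnorm(n_features, 0, 1.5)
  prev_alt <- stats::runif(n_features, p$lo, p$hi)
  load_alt <- p$draw_loadings()
  samp_ids <- sprintf("V%03d", seq_len(n_new_samples))

  # unrelated linkage: fresh sparse weights of the same scale and sparsity
  W <- dataset$true_weights
  W_alt <- W * 0
  supp_sizes <- colSums(W != 0)
  for (m in dataset$planted_metabolite_ids) {
    k <- supp_sizes[[m]]
    supp <- sample(which(prev_alt >= stats::median(prev_alt)), k)
    w <- stats::runif(k, 0.5, 1) * sample(c(-1, 1), k, replace = TRUE)
    W_alt[supp, m] <- w / sqrt(sum(w^2)) * sqrt(sum(W[, m]^2))
  }

  raw <- matrix(0, n_new_samples, n_features,
                dimnames = list(samp_ids, rownames(dataset$true_weights)))
  Z_true <- raw
  for (i in seq_len(n_new_samples)) {
    d <- drift[i]
    mu_d <- (1 - d) * p$mu + d * mu_alt
    prev_d <- (1 - d) * p$prev + d * prev_alt
    load_d <- (1 - d) * p$loadings + d * load_alt
    raw[i, ] <- p$draw_X(samp_ids[i], mu_d, prev_d, load_d)
    Z_true[i, ] <- quantile_transform_truth(raw[i, ], mu_d, prev_d)
  }
  X_new <- abundance_table(raw / rowSums(raw), normalized = TRUE)

  met_ids <- colnames(dataset$true_weights)
  y_raw <- matrix(0, n_new_samples, length(met_ids),
                  dimnames = list(samp_ids, met_ids))
  for (m in dataset$planted_metabolite_ids) {
    lin <- (1 - drift) * as.numeric(Z_true %*% W[, m]) +
      drift * as.numeric(Z_true %*% W_alt[, m])
    t_m <- dataset$true_intercepts[m] + lin +
      stats::rnorm(n_new_samples, 0, dataset$noise_sd)
    y_raw[, m] <- inverse_arcsine_sqrt(t_m)
  }
  for (i in seq_along(dataset$noise_metabolite_ids))
    y_raw[, dataset$noise_metabolite_ids[i]] <-
      stats::rlnorm(n_new_samples, p$mu_met[i], 0.4)
  Y_true <- abundance_table(y_raw / rowSums(y_raw), normalized = TRUE)

  list(X = X_new, Y_true = Y_true,
       drift = stats::setNames(drift, samp_ids))
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d samples, %d features, %d metabolites (%d planted, %d noise), noise_sd = %g, seed = %d\n",
              nrow(x$X$values), ncol(x$X$values), ncol(x$Y$values),
              length(x$planted_metabolite_ids),
              length(x$noise_metabolite_ids), x$noise_sd, x$seed))
  invisible(x)
}
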
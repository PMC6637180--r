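# Shared fixtures and independent oracles for the test suite.  Oracles are
# deliberately written without reference to the package's own algorithms.

tiny_table <- function(values = rbind(c(1, 1), c(2, 2), c(4, 0)),
                       normalized = FALSE) {
  abundance_table(values,
                  sample_ids = paste0("s", seq_len(nrow(values))),
                  feature_ids = paste0("f", seq_len(ncol(values))),
                  normalized = normalized)
}

write_table_tsv <- function(tab, id_col = "sample_id") {
  path <- tempfile(fileext = ".tsv")
  v <- tab$values
  lines <- c(paste(c(id_col, colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], v[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  path
}

random_weight_matrix <- function(seed, p = 6, m = 4) {
  set.seed(seed)
  coef <- matrix(rnorm(p * m) * (runif(p * m) < 0.6), p, m,
                 dimnames = list(sprintf("feat%02d", seq_len(p)),
                                 sprintf("met%02d", seq_len(m))))
  cv <- runif(m, -0.2, 0.9)
  wp <- cv >= 0.3 & colSums(coef != 0) > 0
  weight_matrix(coef, intercepts = rnorm(m), alpha = runif(m),
                lambda = rexp(m, 10), cv_spearman = cv, well_predicted = wp)
}

# Small paired dataset + fast training configuration for pipeline-level unit
# tests (full-scale runs live in the acceptance tests).
small_dataset <- function(seed = 3) {
  generate_synthetic_dataset(n_samples = 30, n_features = 40,
                             n_metabolites = 6, frac_planted = 0.5,
                             support_size = 4, noise_sd = 0.05, seed = seed)
}

# Larger feature space so the latent gradients are Tracy-Widom-detectable
# (cached: PCA-scale fixture used by several RTSI tests).
rtsi_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_synthetic_dataset(n_samples = 40, n_features = 120,
                                           n_metabolites = 6,
                                           frac_planted = 0.5,
                                           support_size = 4,
                                           noise_sd = 0.05, seed = 7)
    cache
  }
})

fast_config <- function(seed = 1) {
  train_config(alpha_grid = c(0.2, 0.5, 1), n_lambda = 40L, k = 5L,
               seed = seed)
}

# Brute-force elastic net minimizer: enumerates every sign pattern of the
# coefficients; within a pattern the penalized objective is a smooth
# quadratic solved in closed form.  The true objective is evaluated at every
# candidate, so the minimum over candidates equals the global minimum
# (the optimal pattern's candidate attains it).
oracle_enet_objective <- function(X, y, alpha, lambda) {
  n <- nrow(X)
  p <- ncol(X)
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  s <- sqrt(colMeans(Xc^2))
  s[s == 0] <- 1
  Xs <- sweep(Xc, 2, s, "/")
  yc <- y - mean(y)
  obj <- function(b)
    mean((yc - Xs %*% b)^2) / 2 +
      lambda * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
  G <- crossprod(Xs) / n + diag(lambda * (1 - alpha), p)
  cvec <- crossprod(Xs, yc) / n
  best <- obj(rep(0, p))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (k in seq_len(nrow(signs))) {
    sg <- signs[k, ]
    supp <- which(sg != 0)
    if (!length(supp)) next
    b <- rep(0, p)
    sol <- tryCatch(solve(G[supp, supp, drop = FALSE],
                          cvec[supp] - lambda * alpha * sg[supp]),
                    error = function(e) NULL)
    if (is.null(sol)) next
    b[supp] <- sol
    best <- min(best, obj(b))
  }
  best
}

# Independent running-sum enrichment score (straightforward loop).
oracle_ks_score <- function(is_member) {
  n <- length(is_member)
  nh <- sum(is_member)
  run <- 0
  extreme <- 0
  for (i in seq_len(n)) {
    run <- run + if (is_member[i]) 1 / nh else -1 / (n - nh)
    if (abs(run) > abs(extreme)) extreme <- run
  }
  extreme
}

# Exhaustive permutation p-value over all placements of nh members in a list
# of length n, one-sided in the direction of the observed score.
oracle_ks_exhaustive_p <- function(n, member_positions) {
  nh <- length(member_positions)
  obs <- oracle_ks_score(seq_len(n) %in% member_positions)
  placements <- utils::combn(n, nh)
  scores <- apply(placements, 2, function(pos)
    oracle_ks_score(seq_len(n) %in% pos))
  p <- if (obs >= 0) mean(scores >= obs) else mean(scores <= obs)
  list(es = obs, p = p)
}

# Per-sample prediction accuracy on a validation cohort: correlation across
# well-predicted metabolites between cohort-standardized predicted and true
# transformed abundances (standardization removes per-metabolite baselines).
per_sample_accuracy <- function(pred, truth, metabolites) {
  zs <- function(m) apply(m, 2, function(v)
    if (stats::sd(v) == 0) v * 0 else (v - mean(v)) / stats::sd(v))
  P <- zs(arcsine_sqrt(pred[, metabolites, drop = FALSE]))
  Tr <- zs(arcsine_sqrt(truth[, metabolites, drop = FALSE]))
  vapply(seq_len(nrow(P)), function(i) stats::cor(P[i, ], Tr[i, ]),
         numeric(1))
}
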
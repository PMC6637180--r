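# Critical values of the Tracy-Widom TW1 distribution (upper tail), the
# published table values for the significance levels commonly used to select
# significant principal components.
TW1_CRITICAL <- c("0.05" = 0.9793, "0.01" = 2.0234,
                  "0.005" = 2.4224, "0.001" = 3.2724)

tw1_critical_value <- function(significance) {
  if (significance >= 1) return(-Inf)
  key <- format(significance, scientific = FALSE, trim = TRUE)
  if (!key %in% names(TW1_CRITICAL))
    stop("unsupported Tracy-Widom significance level ", significance,
         "; available: ", paste(names(TW1_CRITICAL), collapse = ", "),
         " (or >= 1 to accept every component)")
  unname(TW1_CRITICAL[key])
}

# Patterson-style Tracy-Widom statistics for a decreasing eigenvalue vector:
# the i-th statistic tests the leading eigenvalue of the trailing block
# lam[i:m], using the moment-based effective dimension and the TW1
# centering/scaling.
tracy_widom_stats <- function(lam) {
  m <- length(lam)
  stats <- rep(-Inf, m)
  for (i in seq_len(m)) {
    tail_ <- lam[i:m]
    mm <- length(tail_)
    if (mm < 2) break
    s1 <- sum(tail_)
    if (s1 <= 0) break
    s2 <- mm^2 * sum(tail_^2) / s1^2
    denom <- s2 - mm
    if (denom <= 0) break # eigenvalues (near-)equal: no excess top eigenvalue
    v <- mm * (mm + 2) / denom # effective dimension
    if (v <= 1) break
    l_norm <- mm * tail_[1] / s1
    mu <- (sqrt(v - 1) + sqrt(mm))^2 / v
    sig <- (sqrt(v - 1) + sqrt(mm)) / v *
      (1 / sqrt(v - 1) + 1 / sqrt(mm))^(1 / 3)
    stats[i] <- (l_norm - mu) / sig
  }
  stats
}

#' Select significant principal components by Tracy-Widom testing
#'
#' Computes the eigenvalues of the sample covariance of the (transformed,
#' filtered) training feature matrix and tests the leading eigenvalues
#' sequentially against the Tracy-Widom TW1 null: at each step the remaining
#' eigenvalue block is summarized by its moment-based effective dimension
#' (Patterson-style normalization), the top eigenvalue is centered and
#' scaled, and the statistic is compared to the TW1 critical value at
#' `significance`.  K is the number of consecutive leading eigenvalues whose
#' statistic exceeds the critical value.
#'
#' @param training_X_t Numeric matrix of transformed training features
#'   (samples x features), at least 3 samples.
#' @param significance Upper-tail significance level; one of 0.05 (default),
#'   0.01, 0.005, 0.001, or any value >= 1 to accept all components.
#' @return A list: `K`, `loadings` (features x K matrix of unit-norm loading
#'   vectors), `eigenvalues`, `tw_stats`, `critical_value`.
#' @export
select_top_pcs_tracy_widom <- function(training_X_t, significance = 0.05) {
  training_X_t <- as.matrix(training_X_t)
  n <- nrow(training_X_t)
  if (n < 3) stop("Tracy-Widom PC selection requires at least 3 samples")
  crit <- tw1_critical_value(significance)
  pc <- stats::prcomp(training_X_t, center = TRUE, scale. = FALSE)
  lam <- pc$sdev^2
  pos <- lam > max(lam) * 1e-12
  if (!any(pos)) {
    warning("degenerate (rank-0) training matrix; no significant components")
    return(list(K = 0L, loadings = pc$rotation[, 0, drop = FALSE],
                eigenvalues = lam, tw_stats = numeric(0),
                critical_value = crit))
  }
  lam <- lam[pos]
  tw <- tracy_widom_stats(lam)
  exceeds <- tw > crit
  K <- if (!length(exceeds) || !exceeds[1]) 0L
       else which.min(c(exceeds, FALSE)) - 1L
  list(K = as.integer(K),
       loadings = pc$rotation[, seq_len(K), drop = FALSE],
       eigenvalues = lam, tw_stats = tw, critical_value = crit)
}

#' Representative Training Sample Index (RTSI)
#'
#' Scores how well each new sample is represented by the training feature
#' space.  Both tables are restricted to their shared features (new-cohort
#' features never seen in training are flagged and excluded from the score);
#' each cohort is rank-inverse-normal transformed within itself; the training
#' matrix's significant principal components are selected by Tracy-Widom
#' testing; and each new sample is scored by the correlation between its
#' transformed feature vector and the K top loading vectors, aggregated by
#' `aggregate` (default: the highest absolute correlation; loading sign is
#' arbitrary, so the absolute value is used).
#'
#' @param new_X,training_X [abundance_table()]s (normalized or raw; raw
#'   tables are total-sum scaled).  The training table is filtered by
#'   `policy` before the PCA.
#' @param policy A [filter_policy()] for the training features.
#' @param significance Tracy-Widom significance level for
#'   [select_top_pcs_tracy_widom()].
#' @param aggregate `"max"` (highest absolute correlation over the K
#'   components, the default) or `"mean"` (their average).
#' @return An `rtsi_result`: `rtsi` (named per-sample scores, `NA` when
#'   `K = 0`), `n_top_pcs`, `feature_overlap` (per-sample fraction of the
#'   sample's nonzero features that are shared with training),
#'   `flagged_unseen_features`.
#' @export
compute_rtsi <- function(new_X, training_X, policy = filter_policy(),
                         significance = 0.05,
                         aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!new_X$normalized) new_X <- tss_normalize(new_X)
  training_X <- prepare_features(training_X, policy)
  shared <- intersect(feature_ids(training_X), feature_ids(new_X))
  if (length(shared) == 0)
    stop("no features shared between the new cohort and the training set")
  unseen <- setdiff(feature_ids(new_X), feature_ids(training_X))
  nz <- new_X$values > 0
  overlap <- vapply(seq_len(nrow(nz)), function(i) {
    present <- feature_ids(new_X)[nz[i, ]]
    if (!length(present)) return(0)
    mean(present %in% feature_ids(training_X))
  }, numeric(1))
  names(overlap) <- sample_ids(new_X)

  train_t <- rank_inverse_normal_matrix(
    training_X$values[, shared, drop = FALSE])
  new_t <- rank_inverse_normal_matrix(
    new_X$values[, shared, drop = FALSE], constant_action = "zero")

  sel <- select_top_pcs_tracy_widom(train_t, significance)
  if (sel$K == 0) {
    warning("no significant principal components at significance ",
            significance, "; RTSI is undefined")
    scores <- stats::setNames(rep(NA_real_, nrow(new_t)), rownames(new_t))
  } else {
    cors <- abs(stats::cor(t(new_t), sel$loadings))
    cors[is.na(cors)] <- 0 # constant transformed sample vector
    scores <- if (aggregate == "max") apply(cors, 1, max)
              else rowMeans(cors)
    names(scores) <- rownames(new_t)
  }
  structure(list(rtsi = scores, n_top_pcs = sel$K,
                 feature_overlap = overlap,
                 flagged_unseen_features = unseen,
                 significance = significance, aggregate = aggregate),
            class = "rtsi_result")
}

#' @export
print.rtsi_result <- function(x, ...) {
  cat(sprintf("rtsi_result: %d samples scored against %d significant PC(s); %d unseen feature(s) flagged\n",
              length(x$rtsi), x$n_top_pcs, length(x$flagged_unseen_features)))
  invisible(x)
}
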
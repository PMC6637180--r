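#' Filtering policy for compositional feature tables
#'
#' Encodes the prevalence/abundance filter used on both predictor and
#' metabolite tables: a feature is kept when its relative abundance exceeds
#' `min_abundance` in at least `ceiling(min_prevalence * n_samples)` samples.
#' The defaults (0.01% abundance in at least 10% of samples) are the settings
#' used for human gut metagenomes; [filter_policy_nongut()] gives the more
#' permissive low-abundance threshold (0.0001%) plus a variance filter, the
#' configuration appropriate for sparser 16S profiles from non-gut
#' environments.
#'
#' @param min_abundance Relative-abundance threshold (fraction; 1e-4 = 0.01%).
#' @param min_prevalence Minimum fraction of samples (in `[0,1]`) in which the
#'   abundance threshold must be exceeded.
#' @param min_variance Across-sample variance threshold for
#'   [variance_filter()]; `NA` (default) disables the variance filter, `0`
#'   removes exactly the features that do not vary over the samples.
#' @return A `filter_policy` object.
#' @export
filter_policy <- function(min_abundance = 1e-4, min_prevalence = 0.10,
                          min_variance = NA_real_) {
  stopifnot(min_abundance >= 0, min_prevalence >= 0, min_prevalence <= 1,
            is.na(min_variance) || min_variance >= 0)
  structure(list(min_abundance = min_abundance,
                 min_prevalence = min_prevalence,
                 min_variance = min_variance),
            class = "filter_policy")
}

#' @rdname filter_policy
#' @export
filter_policy_nongut <- function() {
  filter_policy(min_abundance = 1e-6, min_prevalence = 0.10, min_variance = 0)
}

#' Total-sum scaling
#'
#' Divides every sample row by its sum so that each sample becomes a vector
#' of relative abundances summing to 1.  Idempotent and invariant to
#' per-sample rescaling.
#'
#' @param table An [abundance_table()] of non-negative values with no
#'   all-zero sample.
#' @return The normalized table with `normalized = TRUE`.
#' @export
tss_normalize <- function(table) {
  validate_abundance_table(table)
  rs <- rowSums(table$values)
  if (any(rs == 0))
    stop("cannot normalize all-zero sample(s): ",
         paste(sample_ids(table)[rs == 0], collapse = ", "))
  abundance_table(table$values / rs, normalized = TRUE)
}

#' Prevalence/abundance filter
#'
#' Retains exactly the features whose relative abundance exceeds
#' `policy$min_abundance` in at least `ceiling(policy$min_prevalence * n)`
#' of the `n` samples.  Sample rows are left untouched (no renormalization
#' after filtering), so downstream values stay on the original
#' relative-abundance scale.
#'
#' @param table A normalized [abundance_table()].
#' @param policy A [filter_policy()].
#' @return The table restricted to the retained features, in original order.
#' @export
prevalence_abundance_filter <- function(table, policy = filter_policy()) {
  validate_abundance_table(table)
  if (!table$normalized)
    stop("prevalence/abundance filtering expects a normalized table; call tss_normalize() first")
  n <- nrow(table$values)
  need <- ceiling(policy$min_prevalence * n)
  hits <- colSums(table$values > policy$min_abundance)
  keep <- hits >= need
  if (!any(keep))
    stop(sprintf(paste0("no features exceed abundance %g in at least %d of %d samples; ",
                        "consider relaxing the filter thresholds"),
                 policy$min_abundance, need, n))
  out <- table
  out$values <- table$values[, keep, drop = FALSE]
  out
}

#' Variance filter
#'
#' Drops features whose across-sample variance (denominator `n - 1`) is less
#' than or equal to `min_variance`; at the default 0 exactly the constant
#' features are removed.
#'
#' @param table An [abundance_table()].
#' @param min_variance Non-negative variance threshold.
#' @return The table restricted to features with variance above the
#'   threshold.
#' @export
variance_filter <- function(table, min_variance = 0) {
  validate_abundance_table(table)
  stopifnot(min_variance >= 0)
  v <- apply(table$values, 2, stats::var)
  keep <- v > min_variance
  if (!any(keep))
    stop("no features vary more than the variance threshold; consider relaxing it")
  out <- table
  out$values <- table$values[, keep, drop = FALSE]
  out
}

#' Rank-based inverse normal transformation
#'
#' Maps values to standard-normal quantiles through their ranks:
#' `qnorm((rank - 0.5) / n)`, with ties receiving average ranks.  This is the
#' quantile transformation used to variance-stabilize skewed, zero-inflated
#' microbial feature abundances before regression; it is strictly
#' rank-preserving on untied values.
#'
#' @param values Numeric vector of length at least 2, not all identical.
#' @return Numeric vector of transformed values.
#' @export
rank_inverse_normal <- function(values) {
  if (length(values) < 2)
    stop("rank-based inverse normal transform requires at least 2 values")
  if (any(!is.finite(values))) stop("non-finite values in input")
  if (max(values) == min(values))
    stop("constant vector cannot be rank-transformed (remove constant features first)")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.5) / length(values))
}

# Column-wise rank-INT for a samples x features matrix.  constant_action
# governs the degenerate columns the prediction pipeline may see (zero-filled
# missing model features): "error" for training, "zero" to map them to the
# transform's center.
rank_inverse_normal_matrix <- function(m, constant_action = c("error", "zero")) {
  constant_action <- match.arg(constant_action)
  out <- m
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (max(col) == min(col)) {
      if (constant_action == "error")
        stop("constant feature column '", colnames(m)[j],
             "' cannot be rank-transformed")
      out[, j] <- 0
    } else out[, j] <- rank_inverse_normal(col)
  }
  out
}

#' Arcsine square root transform and its inverse
#'
#' The variance-stabilizing transform applied to metabolite relative
#' abundances before model fitting: `asin(sqrt(y))`, mapping `[0, 1]` onto
#' `[0, pi/2]`.  The inverse clamps its argument to `[0, pi/2]` before
#' applying `sin(.)^2`, so back-transformed predictions always land in
#' `[0, 1]` whatever the linear model produced.
#'
#' @param y Numeric values in `[0, 1]` (a tolerance of 1e-12 outside the
#'   interval is clamped; larger excursions are an error).
#' @param t Any finite numeric values on the transformed scale.
#' @return `arcsine_sqrt`: values in `[0, pi/2]`; `inverse_arcsine_sqrt`:
#'   values in `[0, 1]`.
#' @export
arcsine_sqrt <- function(y) {
  if (any(!is.finite(y))) stop("non-finite values in input")
  if (any(y < -1e-12 | y > 1 + 1e-12))
    stop("arcsine square root transform requires values in [0, 1]; got ",
         signif(y[which(y < -1e-12 | y > 1 + 1e-12)[1]], 6))
  asin(sqrt(pmin(pmax(y, 0), 1)))
}

#' @rdname arcsine_sqrt
#' @export
inverse_arcsine_sqrt <- function(t) {
  if (any(!is.finite(t))) stop("non-finite values in input")
  sin(pmin(pmax(t, 0), pi / 2))^2
}

# Shared preprocessing for a predictor table: normalize if needed, apply the
# prevalence/abundance filter, optionally the variance filter, and always drop
# constant columns (the rank transform is undefined on them).
prepare_features <- function(x, policy) {
  if (!x$normalized) x <- tss_normalize(x)
  x <- prevalence_abundance_filter(x, policy)
  if (!is.na(policy$min_variance)) x <- variance_filter(x, policy$min_variance)
  const <- apply(x$values, 2, function(v) max(v) == min(v))
  if (any(const)) x$values <- x$values[, !const, drop = FALSE]
  if (ncol(x$values) == 0) stop("no non-constant features survive filtering")
  x
}
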
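#' Align a new feature table to a trained model
#'
#' Columns are reordered to the model's predictor features.  Model features
#' absent from the new table are zero-filled and reported (never silently
#' dropped); new-cohort features unknown to the model are ignored and
#' counted.
#'
#' @param new_X A normalized [abundance_table()] for the new cohort.
#' @param model A [weight_matrix()].
#' @return A list: `matrix` (samples x model features),
#'   `missing_feature_ids` (model features not observed in the new cohort),
#'   `n_ignored` (new features not in the model), `coverage_fraction`
#'   (per-sample fraction of model features with nonzero abundance).
#' @export
align_features <- function(new_X, model) {
  validate_abundance_table(new_X)
  feats <- rownames(model$coefficients)
  present <- intersect(feats, feature_ids(new_X))
  if (length(feats) > 0 && length(present) == 0)
    stop("no overlap between model features and the new table's features; ",
         "check cohort representativeness (RTSI) and feature naming")
  m <- matrix(0, nrow(new_X$values), length(feats),
              dimnames = list(sample_ids(new_X), feats))
  m[, present] <- new_X$values[, present, drop = FALSE]
  missing <- setdiff(feats, present)
  list(matrix = m,
       missing_feature_ids = missing,
       n_ignored = length(setdiff(feature_ids(new_X), feats)),
       coverage_fraction = if (length(feats)) rowMeans(m > 0)
                           else stats::setNames(rep(0, nrow(m)), rownames(m)))
}

#' Predict metabolite relative abundances for new communities
#'
#' Applies a trained weight matrix: align features to the model, total-sum
#' scale, rank-inverse-normal transform each feature within the new cohort
#' (constant columns, including zero-filled missing model features, map to
#' the transform's center 0), take the per-metabolite linear combination
#' `b0 + x_t . b`, and back-transform through the clamped inverse
#' arcsine-sqrt, so every prediction is a relative abundance in `[0, 1]`.
#'
#' Because the rank transform is cohort-relative, at least 2 samples are
#' required; single-sample prediction is refused.  Predictions are not
#' renormalized across metabolites: each metabolite's relative abundance is
#' predicted independently.
#'
#' @param new_X An [abundance_table()] of sequence features for the new
#'   cohort (auto-normalized with a warning if needed).
#' @param model A [weight_matrix()] from [train_all()] or
#'   [read_weight_matrix()].
#' @return A `prediction_result`: `predicted` (samples x metabolites matrix
#'   in `[0, 1]`), `missing_feature_ids`, `coverage_fraction`, `n_ignored`.
#' @export
predict_metabolome <- function(new_X, model) {
  validate_weight_matrix(model)
  if (nrow(new_X$values) < 2)
    stop("prediction requires at least 2 samples: the rank-based inverse ",
         "normal transform is computed within the new cohort and is ",
         "undefined for a single sample")
  if (!new_X$normalized) {
    warning("input table is not normalized; applying total-sum scaling")
    new_X <- tss_normalize(new_X)
  }
  al <- align_features(new_X, model)
  Z <- if (ncol(al$matrix) > 0)
    rank_inverse_normal_matrix(al$matrix, constant_action = "zero")
  else al$matrix
  t_hat <- sweep(Z %*% model$coefficients, 2, model$intercepts, "+")
  pred <- inverse_arcsine_sqrt(t_hat)
  dimnames(pred) <- list(sample_ids(new_X), colnames(model$coefficients))
  structure(list(predicted = pred,
                 missing_feature_ids = al$missing_feature_ids,
                 coverage_fraction = al$coverage_fraction,
                 n_ignored = al$n_ignored),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: %d samples x %d metabolites; %d model feature(s) missing from input\n",
              nrow(x$predicted), ncol(x$predicted),
              length(x$missing_feature_ids)))
  invisible(x)
}

#' @param object A `weight_matrix`.
#' @param newdata An [abundance_table()] of new-cohort sequence features.
#' @param ... Unused.
#' @rdname predict_metabolome
#' @export
predict.weight_matrix <- function(object, newdata, ...) {
  predict_metabolome(newdata, object)
}
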
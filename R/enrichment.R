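#' Rank predictor features by model usage
#'
#' A feature's usage score is the number of well-predicted metabolite models
#' in which its coefficient is nonzero.  Features are ordered by decreasing
#' score with lexicographic tie-breaking, giving the ranked list consumed by
#' the enrichment analyses.  All of the model's predictor features are
#' ranked; features used only by poorly predicted models get score 0.
#'
#' @param model A [weight_matrix()] with at least one well-predicted
#'   metabolite.
#' @return A data frame (`feature_id`, `usage_score`) ordered by rank.
#' @export
rank_features_by_usage <- function(model) {
  validate_weight_matrix(model)
  if (!any(model$well_predicted))
    stop("no well-predicted metabolites: feature usage ranking is undefined")
  b <- model$coefficients[, model$well_predicted, drop = FALSE]
  score <- rowSums(b != 0)
  ord <- order(-score, rownames(model$coefficients), method = "radix")
  data.frame(feature_id = rownames(model$coefficients)[ord],
             usage_score = as.integer(score[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Enrichment score of a membership indicator along a ranked list: running sum
# +1/Nh at members, -1/(N-Nh) elsewhere; the score is the deviation of
# largest magnitude (signed; positive = concentration at the top).
ks_running_score <- function(is_member) {
  n <- length(is_member)
  nh <- sum(is_member)
  if (nh == 0 || nh == n) return(0)
  steps <- ifelse(is_member, 1 / nh, -1 / (n - nh))
  run <- cumsum(steps)
  i <- which.max(abs(run))
  run[i]
}

#' Permutation KS enrichment of a feature set in a ranked list
#'
#' Computes the classic (unweighted) Kolmogorov-Smirnov-style enrichment
#' score: walking down the ranked list, the running sum rises by `1/Nh` at
#' set members and falls by `1/(N-Nh)` at non-members; the score is the
#' largest-magnitude deviation, positive when the set concentrates at the
#' top of the list.  Significance comes from a permutation null that places
#' `Nh` members uniformly at random within the fixed ranking; the p-value is
#' one-sided in the direction of the observed score, with `+1/(n+1)`
#' smoothing so it is never exactly 0.
#'
#' @param ranked A ranked feature list from [rank_features_by_usage()] (or
#'   any data frame with a `feature_id` column in rank order).
#' @param gene_set Character vector of member feature ids; must intersect
#'   the ranked list.
#' @param n_permutations Number of random placements (default 1e5, the
#'   published protocol's count).
#' @param seed Integer seed for the permutation draws.
#' @return A list: `es`, `p`, `direction` (`"over"`/`"under"`), `set_size`
#'   (members found in the list), `n_permutations`.
#' @export
ks_enrichment <- function(ranked, gene_set, n_permutations = 100000L,
                          seed = 1L) {
  ids <- ranked$feature_id
  n <- length(ids)
  is_member <- ids %in% gene_set
  nh <- sum(is_member)
  if (nh == 0)
    stop("gene set has no members in the ranked list: ",
         paste(utils::head(gene_set, 3), collapse = ", "), "...")
  es <- ks_running_score(is_member)
  if (nh == n) # degenerate: the set is the whole list
    return(list(es = 0, p = 1, direction = "over", set_size = nh,
                n_permutations = 0L))
  set.seed(seed)
  null_es <- vapply(seq_len(n_permutations), function(i) {
    m <- logical(n)
    m[sample.int(n, nh)] <- TRUE
    ks_running_score(m)
  }, numeric(1))
  hits <- if (es >= 0) sum(null_es >= es) else sum(null_es <= es)
  p <- (hits + 1) / (n_permutations + 1)
  list(es = es, p = p, direction = if (es >= 0) "over" else "under",
       set_size = nh, n_permutations = as.integer(n_permutations))
}

#' One-tailed Fisher over-representation test
#'
#' Upper-tail (greater) hypergeometric probability of observing at least the
#' given number of candidate features inside the set, from the 2x2 table
#' `[[in_set_candidate, in_set_rest], [out_set_candidate, out_set_rest]]`.
#'
#' @param in_set_candidate,in_set_rest,out_set_candidate,out_set_rest
#'   Non-negative cell counts with positive margins.
#' @return The one-tailed p-value.
#' @export
fisher_overrepresentation <- function(in_set_candidate, in_set_rest,
                                      out_set_candidate, out_set_rest) {
  tab <- matrix(c(in_set_candidate, out_set_candidate,
                  in_set_rest, out_set_rest), 2, 2)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (sum(tab) == 0) stop("all-zero contingency table")
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return The BH-adjusted q-values, in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set enrichment over a trained model
#'
#' Runs [ks_enrichment()] for every set in a collection against the model's
#' usage ranking, plus a one-tailed Fisher over-representation test of each
#' set among the candidate features (those used by at least one
#' well-predicted model), and controls both p-value families by
#' Benjamini-Hochberg FDR.  Sets with no member in the ranked list are
#' skipped with a warning.
#'
#' @param model A [weight_matrix()].
#' @param gene_sets A `gene_set_collection` from [read_gene_sets()] or a
#'   named list of character vectors.
#' @param n_permutations Permutations per set for the KS null.
#' @param seed Integer seed.
#' @param q_threshold Reporting threshold stored with the result (default
#'   0.25, the conventional GSEA cutoff).
#' @return A data frame with one row per testable set: `set_name`, `es`,
#'   `p`, `q`, `direction`, `set_size`, `fisher_p`, `fisher_q`,
#'   `significant` (`q < q_threshold`).
#' @export
enrich_all <- function(model, gene_sets, n_permutations = 100000L, seed = 1L,
                       q_threshold = 0.25) {
  ranked <- rank_features_by_usage(model)
  candidate <- ranked$usage_score > 0
  set.seed(seed)
  set_seeds <- sample.int(.Machine$integer.max - 1L, length(gene_sets))
  rows <- lapply(seq_along(gene_sets), function(i) {
    nm <- names(gene_sets)[i]
    members <- ranked$feature_id %in% gene_sets[[i]]
    if (!any(members)) {
      warning("gene set '", nm, "' has no members in the ranked list; skipped")
      return(NULL)
    }
    ks <- ks_enrichment(ranked, gene_sets[[i]], n_permutations, set_seeds[i])
    fp <- fisher_overrepresentation(sum(members & candidate),
                                    sum(members & !candidate),
                                    sum(!members & candidate),
                                    sum(!members & !candidate))
    data.frame(set_name = nm, es = ks$es, p = ks$p, direction = ks$direction,
               set_size = ks$set_size, fisher_p = fp,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0)
    stop("no gene set overlaps the ranked feature list")
  rows$q <- bh_fdr(rows$p)
  rows$fisher_q <- bh_fdr(rows$fisher_p)
  rows$significant <- rows$q < q_threshold
  rows[, c("set_name", "es", "p", "q", "direction", "set_size",
           "fisher_p", "fisher_q", "significant")]
}
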
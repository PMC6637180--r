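# Apply explicit per-feature permutations (a list of index vectors, one per
# column) and renormalize each sample row to sum 1.  Split out from
# permute_and_renormalize so the arithmetic is testable with fixed
# permutations.
apply_feature_permutations <- function(table, perms) {
  v <- table$values
  stopifnot(length(perms) == ncol(v))
  for (j in seq_len(ncol(v))) v[, j] <- v[perms[[j]], j]
  rs <- rowSums(v)
  if (any(rs == 0)) return(NULL) # caller redraws
  abundance_table(v / rs, normalized = TRUE)
}

#' Within-feature permutation with per-sample renormalization
#'
#' The null model used for significance testing: every feature column is
#' independently permuted across samples (breaking all feature-feature and
#' feature-metabolite linkage while preserving each feature's marginal value
#' multiset), then each sample row is renormalized to sum 1 so the permuted
#' table keeps the compositional structure of the original.  The alternative
#' `"sample_label"` mode shuffles whole sample rows instead, preserving
#' inter-feature structure.
#'
#' In the rare event that a permutation produces an all-zero sample row, that
#' draw is discarded and redrawn (logged as a message), up to `max_retries`.
#'
#' @param table A normalized [abundance_table()].
#' @param seed Integer seed for the permutation draw.
#' @param mode `"per_feature"` (default) or `"sample_label"`.
#' @param max_retries Redraw cap for degenerate permutations.
#' @return A permuted, renormalized `abundance_table`.
#' @export
permute_and_renormalize <- function(table, seed,
                                    mode = c("per_feature", "sample_label"),
                                    max_retries = 100L) {
  mode <- match.arg(mode)
  validate_abundance_table(table)
  if (!table$normalized)
    stop("permutation null expects a normalized table")
  n <- nrow(table$values)
  set.seed(seed)
  for (attempt in seq_len(max_retries)) {
    perms <- if (mode == "per_feature")
      replicate(ncol(table$values), sample.int(n), simplify = FALSE)
    else rep(list(sample.int(n)), ncol(table$values))
    out <- apply_feature_permutations(table, perms)
    if (!is.null(out)) {
      rownames(out$values) <- sample_ids(table)
      return(out)
    }
    message("permutation produced an all-zero sample; redrawing (attempt ",
            attempt, ")")
  }
  stop("failed to draw a non-degenerate permutation after ", max_retries,
       " attempts")
}

#' Permutation null for the number of well-predicted metabolites
#'
#' Quantifies whether training identifies more well-predicted metabolites
#' than expected when all shared signal between features and metabolites is
#' broken: each iteration independently permutes-and-renormalizes both the
#' feature and the metabolite table (fresh seeds derived from the master
#' seed), retrains the full model, and records the fraction of metabolites
#' flagged well predicted.  The observed (unshuffled) fraction is reported
#' alongside, and the per-metabolite well-predicted indicators of the first
#' permuted run are compared with the observed ones by the exact McNemar
#' test.
#'
#' @param X,Y Paired [abundance_table()]s as in [train_all()].
#' @param config A [train_config()].
#' @param policy A [filter_policy()].
#' @param n_iterations Number of permutation iterations (>= 1).  Small counts
#'   (tens) already separate signal from null; the full published protocol
#'   used 1000.
#' @param seed Master seed for the permutation stream.
#' @return A `null_run_summary`: `observed_fraction`, `null_fractions`
#'   (length `n_iterations`), `mcnemar_p` (observed vs first permuted run),
#'   `n_iterations`, `seed`.
#' @export
run_null <- function(X, Y, config = train_config(), policy = filter_policy(),
                     n_iterations = 20L, seed = 1L) {
  stopifnot(n_iterations >= 1)
  observed <- train_all(X, Y, config, policy)
  obs_wp <- observed$well_predicted
  observed_fraction <- mean(obs_wp)

  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_iterations)
  Xn <- if (X$normalized) X else tss_normalize(X)
  Yn <- if (Y$normalized) Y else tss_normalize(Y)

  null_fractions <- numeric(n_iterations)
  mcnemar_p <- NA_real_
  for (it in seq_len(n_iterations)) {
    Xp <- permute_and_renormalize(Xn, iter_seeds[2L * it - 1L])
    Yp <- permute_and_renormalize(Yn, iter_seeds[2L * it])
    fit <- tryCatch(train_all(Xp, Yp, config, policy),
                    error = function(e) NULL)
    wp <- if (is.null(fit)) logical(0) else fit$well_predicted
    null_fractions[it] <- if (length(wp)) mean(wp) else 0
    if (it == 1L) {
      shared <- intersect(names(obs_wp), names(wp))
      b <- sum(obs_wp[shared] & !wp[shared])
      c_ <- sum(!obs_wp[shared] & wp[shared])
      mcnemar_p <- if (b + c_ == 0) 1 else mcnemar_exact(b, c_)
    }
  }
  structure(list(observed_fraction = observed_fraction,
                 null_fractions = null_fractions,
                 mcnemar_p = mcnemar_p,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 observed_model = observed),
            class = "null_run_summary")
}

#' @export
print.null_run_summary <- function(x, ...) {
  cat(sprintf("null_run_summary: observed well-predicted fraction %.3f vs null mean %.3f over %d iteration(s); McNemar exact p = %.3g\n",
              x$observed_fraction, mean(x$null_fractions), x$n_iterations,
              x$mcnemar_p))
  invisible(x)
}

#' Exact McNemar test on discordant pairs
#'
#' Two-sided exact test for paired binary outcomes based only on the
#' discordant counts: `p = min(1, 2 * P(B <= min(b, c)))` with
#' `B ~ Binomial(b + c, 1/2)`.  Used to compare per-metabolite well-predicted
#' status between the observed and a permuted training run.
#'
#' @param b,c Non-negative discordant counts (1/0 and 0/1 pairs).
#' @return The exact p-value in `(0, 1]`.
#' @export
mcnemar_exact <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0) {
    warning("no discordant pairs; p = 1")
    return(1)
  }
  min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
}
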
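make_usage_model <- function() {
  # 5 metabolites, 4 well predicted; feature usage counts are known
  coef <- rbind(
    fA = c(1, 1, 1, 0, 1),   # used in 3 well-predicted models (+ 1 poor)
    fB = c(1, 1, 0, 0, 0),   # 2
    fC = c(0, 0, 1, 1, 0),   # 2
    fD = c(0, 0, 0, 0, 1),   # 0 well-predicted uses, only the poor model
    fE = c(0, 1, 0, 0, 0))   # 1
  colnames(coef) <- paste0("m", 1:5)
  wp <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  weight_matrix(coef, intercepts = rep(0, 5), alpha = rep(0.5, 5),
                lambda = rep(0.1, 5), cv_spearman = c(.5, .6, .4, .35, .1),
                well_predicted = wp)
}

test_that("feature usage counts well-predicted models only, with lexicographic ties", {
  ranked <- rank_features_by_usage(make_usage_model())
  expect_equal(ranked$feature_id, c("fA", "fB", "fC", "fE", "fD"))
  expect_equal(ranked$usage_score, c(3L, 2L, 2L, 1L, 0L))

  none <- random_weight_matrix(1)
  none$well_predicted[] <- FALSE
  expect_error(rank_features_by_usage(none), "no well-predicted")
})

test_that("the enrichment score reproduces the hand-worked running sum", {
  ranked <- data.frame(feature_id = c("a", "b", "c", "d"))
  ks <- ks_enrichment(ranked, c("a", "b"), n_permutations = 5000, seed = 1)
  expect_equal(ks$es, 1.0)
  expect_equal(ks$direction, "over")
  # exhaustive: only 1 of the C(4,2) = 6 placements reaches es >= 1
  exact <- oracle_ks_exhaustive_p(4, c(1, 2))
  expect_equal(exact$es, 1.0)
  expect_equal(exact$p, 1 / 6)
  se <- sqrt(exact$p * (1 - exact$p) / 5000)
  expect_lt(abs(ks$p - exact$p), 3 * se + 1 / 5001)

  # a set covering the whole list is degenerate
  all_ks <- ks_enrichment(ranked, letters[1:4])
  expect_equal(all_ks$es, 0)
  expect_equal(all_ks$p, 1)

  expect_error(ks_enrichment(ranked, c("zz")), "no members")
})

test_that("Monte-Carlo enrichment p-values agree with exhaustive enumeration", {
  set.seed(41)
  for (i in 1:5) {
    n <- sample(5:8, 1)
    nh <- sample(2:(n - 2), 1)
    pos <- sort(sample(n, nh))
    ranked <- data.frame(feature_id = paste0("g", seq_len(n)))
    ks <- ks_enrichment(ranked, paste0("g", pos),
                        n_permutations = 20000, seed = i)
    exact <- oracle_ks_exhaustive_p(n, pos)
    expect_equal(ks$es, exact$es, tolerance = 1e-12)
    se <- sqrt(exact$p * (1 - exact$p) / 20000)
    expect_lt(abs(ks$p - exact$p), 3 * se + 1 / 20001)
  }
})

test_that("one-tailed Fisher over-representation equals the hypergeometric tail", {
  expect_equal(fisher_overrepresentation(1, 0, 0, 1), 0.5)
  expect_equal(fisher_overrepresentation(5, 0, 0, 5), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(fisher_overrepresentation(0, 3, 4, 5), 1)
  # independent closed form: sum of hypergeometric mass at or above observed
  oracle <- sum(dhyper(2:3, 3, 5, 4))
  expect_equal(fisher_overrepresentation(2, 1, 2, 3), oracle,
               tolerance = 1e-12)
  expect_error(fisher_overrepresentation(0, 0, 0, 0), "all-zero")
})

test_that("BH q-values follow the step-up rule and preserve p-value ordering", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(42)
  p <- runif(50)
  q <- bh_fdr(p)
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
  expect_true(all(q >= p - 1e-15))
})

test_that("collection-level enrichment assembles scores, p, q and Fisher columns", {
  model <- make_usage_model()
  sets <- list(top = c("fA", "fB"), spread = c("fB", "fD"),
               absent = c("zz"))
  expect_warning(res <- enrich_all(model, sets, n_permutations = 2000,
                                   seed = 3), "absent")
  expect_equal(sort(res$set_name), c("spread", "top"))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$q >= res$p - 1e-15))
  expect_true(all(res$fisher_q >= res$fisher_p - 1e-15))
  top <- res[res$set_name == "top", ]
  expect_gt(top$es, 0)
})
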
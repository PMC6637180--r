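test_that("total-sum scaling normalizes rows, is idempotent and scale-invariant", {
  tab <- tiny_table(rbind(c(2, 2, 4)))
  got <- tss_normalize(tab)
  expect_equal(unname(got$values[1, ]), c(0.25, 0.25, 0.5))
  expect_true(got$normalized)

  # idempotence and invariance to per-sample rescaling
  expect_equal(tss_normalize(got)$values, got$values)
  for (seed in 1:5) {
    set.seed(seed)
    v <- matrix(rexp(12), 3, 4)
    scaled <- v * runif(3, 0.1, 50)
    expect_equal(tss_normalize(tiny_table(v))$values,
                 tss_normalize(tiny_table(scaled))$values,
                 tolerance = 1e-12)
  }

  expect_error(tss_normalize(tiny_table(rbind(c(1, 1), c(0, 0)))), "s2")
})

test_that("prevalence/abundance filter keeps features above threshold in enough samples", {
  # one sample out of ten is exactly 10% prevalence: ceil(0.1 * 10) = 1, kept
  v <- matrix(0, 10, 2, dimnames = list(paste0("s", 1:10), c("rare", "fill")))
  v[1, "rare"] <- 0.02
  v[, "fill"] <- 1 - v[, "rare"]
  tab <- abundance_table(v, normalized = TRUE)
  kept <- prevalence_abundance_filter(tab, filter_policy(1e-4, 0.10))
  expect_true("rare" %in% feature_ids(kept))

  # an identically-zero feature never survives a positive threshold
  v2 <- cbind(v, zero = 0)
  v2[, "fill"] <- 1 - v2[, "rare"]
  kept2 <- prevalence_abundance_filter(abundance_table(v2, normalized = TRUE),
                                       filter_policy(1e-4, 0.10))
  expect_false("zero" %in% feature_ids(kept2))

  # thresholds (0, 0) keep everything
  kept3 <- prevalence_abundance_filter(abundance_table(v2, normalized = TRUE),
                                       filter_policy(0, 0))
  expect_equal(feature_ids(kept3), colnames(v2))

  expect_error(prevalence_abundance_filter(tab, filter_policy(0.99, 1)),
               "relaxing")
  expect_error(prevalence_abundance_filter(tiny_table(), filter_policy()),
               "normalized")
})

test_that("variance filter drops exactly the non-varying features at threshold zero", {
  v <- cbind(const = rep(0.1, 3), vary = c(0.1, 0.2, 0.3))
  tab <- abundance_table(v, sample_ids = paste0("s", 1:3),
                         feature_ids = colnames(v))
  got <- variance_filter(tab, 0)
  expect_equal(feature_ids(got), "vary")
  expect_error(variance_filter(tab, 1e6), "relaxing")
})

test_that("feature filters commute (both are per-feature predicates)", {
  set.seed(9)
  v <- matrix(rexp(20 * 15) * (runif(20 * 15) < 0.6), 20, 15)
  v[, 3] <- 0.01 # constant column
  tab <- tss_normalize(tiny_table(v + 1e-9))
  pol <- filter_policy(1e-3, 0.2)
  a <- variance_filter(prevalence_abundance_filter(tab, pol), 0)
  b <- prevalence_abundance_filter(variance_filter(tab, 0), pol)
  expect_equal(a$values, b$values)
})

test_that("rank-based inverse normal transform matches its quantile definition", {
  got <- rank_inverse_normal(c(5, 1, 3))
  expect_equal(got, qnorm(c(5 / 6, 1 / 6, 0.5)), tolerance = 1e-12)
  expect_equal(got[3], 0)

  # ties get average ranks
  expect_equal(rank_inverse_normal(c(1, 1, 2)),
               qnorm(c(1 / 3, 1 / 3, 5 / 6)), tolerance = 1e-12)

  # the median element of an odd-length tie-free vector maps to 0
  set.seed(4)
  v <- sample(100, 21)
  expect_equal(rank_inverse_normal(v)[which(v == sort(v)[11])], 0)

  expect_error(rank_inverse_normal(c(1, 1)), "constant")
  expect_error(rank_inverse_normal(7), "at least 2")
})

test_that("rank transform is centered and rank-preserving on tie-free input", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- rnorm(40) # even n, ties have probability zero
    z <- rank_inverse_normal(v)
    expect_lt(abs(mean(z)), 1e-9)
    expect_equal(cor(v, z, method = "spearman"), 1)
  }
})

test_that("arcsine-sqrt transform and inverse are exact and clamped", {
  expect_equal(arcsine_sqrt(c(0, 1)), c(0, pi / 2))
  expect_equal(arcsine_sqrt(0.25), pi / 6, tolerance = 1e-12)
  expect_error(arcsine_sqrt(1.01), "\\[0, 1\\]")
  expect_equal(inverse_arcsine_sqrt(-0.2), 0)
  expect_equal(inverse_arcsine_sqrt(5), 1)

  grid <- seq(0, 1, length.out = 1e5)
  expect_lt(max(abs(inverse_arcsine_sqrt(arcsine_sqrt(grid)) - grid)), 1e-12)
  # back-transform always lands in [0, 1]
  t_vals <- seq(-3, 5, length.out = 1000)
  expect_true(all(inverse_arcsine_sqrt(t_vals) >= 0 &
                    inverse_arcsine_sqrt(t_vals) <= 1))
})
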
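test_that("feature alignment reorders, zero-fills and reports, and refuses disjoint sets", {
  wm <- random_weight_matrix(1, p = 3)
  rownames(wm$coefficients) <- c("a", "b", "c")

  shuffled <- abundance_table(
    matrix(c(0.2, 0.5, 0.3, 0.1, 0.3, 0.6), 2, 3, byrow = TRUE,
           dimnames = list(c("s1", "s2"), c("c", "a", "b"))),
    normalized = TRUE)
  al <- align_features(shuffled, wm)
  expect_equal(colnames(al$matrix), c("a", "b", "c"))
  expect_equal(al$matrix[, "a"], shuffled$values[, "a"])
  expect_length(al$missing_feature_ids, 0)

  partial <- abundance_table(
    matrix(0.25, 2, 3, dimnames = list(c("s1", "s2"), c("a", "c", "d"))))
  al2 <- align_features(partial, wm)
  expect_equal(al2$missing_feature_ids, "b")
  expect_true(all(al2$matrix[, "b"] == 0))
  expect_equal(al2$n_ignored, 1)

  disjoint <- abundance_table(
    matrix(0.5, 2, 2, dimnames = list(c("s1", "s2"), c("x", "y"))))
  expect_error(align_features(disjoint, wm), "no overlap")
})

test_that("an intercept-only model predicts the back-transformed intercept everywhere", {
  coef <- matrix(0, 2, 3, dimnames = list(c("a", "b"),
                                          c("m1", "m2", "m3")))
  t0 <- c(m1 = 0.4, m2 = -0.3, m3 = 2.0) # in-range, clamped-low, clamped-high
  wm <- weight_matrix(coef, intercepts = t0, alpha = rep(0.5, 3),
                      lambda = rep(0.1, 3), cv_spearman = rep(0, 3),
                      well_predicted = rep(FALSE, 3))
  newX <- abundance_table(
    matrix(c(0.3, 0.7, 0.6, 0.4), 2, 2, byrow = TRUE,
           dimnames = list(c("s1", "s2"), c("a", "b"))), normalized = TRUE)
  pred <- predict_metabolome(newX, wm)
  expect_equal(unname(pred$predicted[, "m1"]), rep(sin(0.4)^2, 2))
  expect_equal(unname(pred$predicted[, "m2"]), c(0, 0))   # clamped at 0
  expect_equal(unname(pred$predicted[, "m3"]), c(1, 1))   # clamped at pi/2
})

test_that("prediction enforces its cohort and normalization contracts", {
  wm <- random_weight_matrix(2, p = 3)
  rownames(wm$coefficients) <- c("a", "b", "c")
  one <- abundance_table(matrix(c(0.5, 0.3, 0.2), 1, 3,
                                dimnames = list("s1", c("a", "b", "c"))),
                         normalized = TRUE)
  expect_error(predict_metabolome(one, wm), "at least 2 samples")

  raw <- abundance_table(matrix(c(5, 3, 2, 1, 1, 2), 2, 3, byrow = TRUE,
                                dimnames = list(c("s1", "s2"),
                                                c("a", "b", "c"))))
  expect_warning(pred <- predict_metabolome(raw, wm), "not normalized")
  expect_true(all(pred$predicted >= 0 & pred$predicted <= 1))
})

test_that("predictions are bounded, sample-order equivariant, and ignore unknown features", {
  for (seed in 1:4) {
    wm <- random_weight_matrix(seed, p = 5, m = 3)
    set.seed(seed + 100)
    n <- 8
    v <- matrix(rexp(n * 5), n, 5,
                dimnames = list(paste0("s", 1:n),
                                rownames(wm$coefficients)))
    tab <- tss_normalize(abundance_table(v))
    pred <- predict_metabolome(tab, wm)
    expect_true(all(pred$predicted >= 0 & pred$predicted <= 1))

    # permuting input samples permutes output rows identically
    perm <- sample(n)
    tab_p <- abundance_table(tab$values[perm, ], normalized = TRUE)
    pred_p <- predict_metabolome(tab_p, wm)
    expect_equal(pred_p$predicted, pred$predicted[perm, ])

    # an extra feature unknown to the model changes nothing
    v2 <- cbind(tab$values, novel = 0.1)
    tab2 <- tss_normalize(abundance_table(v2))
    # renormalization changes shared-feature proportions, so compare with
    # the same values instead: append a zero-abundance unknown feature
    v3 <- cbind(tab$values, novel = 0)
    tab3 <- abundance_table(v3, normalized = TRUE)
    pred3 <- predict_metabolome(tab3, wm)
    expect_equal(pred3$predicted, pred$predicted)
    expect_equal(pred3$n_ignored, 1)
  }
})

test_that("in-sample predictions track cross-validated performance on synthetic data", {
  ds <- small_dataset(seed = 6)
  cfg <- fast_config(seed = 4)
  wm <- train_all(ds$X, ds$Y, cfg)
  pred <- predict_metabolome(ds$X, wm)
  Yn <- tss_normalize(ds$Y)
  for (m in names(which(wm$well_predicted))) {
    r_in <- cor(pred$predicted[, m], Yn$values[sample_ids(ds$X), m],
                method = "spearman")
    expect_gt(r_in, wm$cv_spearman[[m]] - 0.15)
  }
})
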
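test_that("abundance tables read back exactly what was written, in either orientation", {
  tab <- tiny_table()
  path <- write_table_tsv(tab)
  got <- read_abundance_table(path)
  expect_equal(got$values, tab$values)
  expect_false(got$normalized)

  tpath <- tempfile(fileext = ".tsv")
  write_abundance_table(tab, tpath, orientation = "features_in_rows")
  got_t <- read_abundance_table(tpath, orientation = "features_in_rows")
  expect_equal(got_t$values, tab$values)
  # auto-detection keys on the header's first cell
  expect_equal(read_abundance_table(tpath, orientation = "auto")$values,
               tab$values)
})

test_that("round trips are lossless for randomly generated tables", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- matrix(rexp(6 * 4), 6, 4,
                dimnames = list(paste0("s", 1:6), paste0("f", 1:4)))
    tab <- abundance_table(v / rowSums(v), normalized = TRUE)
    path <- tempfile(fileext = ".tsv")
    write_abundance_table(tab, path)
    got <- read_abundance_table(path, normalized = TRUE)
    expect_equal(got$values, tab$values, tolerance = 1e-14)
  }
})

test_that("malformed abundance tables are rejected with located errors", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2", "s1\t1\t1", "s2\t-0.1\t2"), path)
  expect_error(read_abundance_table(path), "s2.*f1|negative")

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2", "s1\toops\t1", "s2\t2\t2"), bad)
  expect_error(read_abundance_table(bad), "non-numeric.*oops|oops")

  expect_error(abundance_table(rbind(c(1, 2), c(1, 2)),
                               sample_ids = c("a", "a"),
                               feature_ids = c("f", "g")),
               "duplicate sample")
  expect_error(abundance_table(rbind(c(0.5, 0.5), c(0.9, 0.2)),
                               sample_ids = c("a", "b"),
                               feature_ids = c("f", "g"),
                               normalized = TRUE),
               "row sums")
})

test_that("weight matrices round-trip through their TSV serialization", {
  for (seed in 1:5) {
    wm <- random_weight_matrix(seed)
    path <- tempfile(fileext = ".tsv")
    write_weight_matrix(wm, path)
    got <- read_weight_matrix(path)
    expect_equal(got$coefficients, wm$coefficients, tolerance = 1e-13)
    expect_equal(got$intercepts, wm$intercepts, tolerance = 1e-13)
    expect_equal(got$alpha, wm$alpha, tolerance = 1e-13)
    expect_equal(got$lambda, wm$lambda, tolerance = 1e-13)
    expect_equal(got$cv_spearman, wm$cv_spearman, tolerance = 1e-13)
    expect_equal(got$well_predicted, wm$well_predicted)
  }
})

test_that("weight matrix invariants are enforced at construction and on read", {
  wm <- random_weight_matrix(1)
  # a well-predicted metabolite must use at least one predictor
  bad_wp <- wm$well_predicted
  zero_col <- which(colSums(wm$coefficients != 0) > 0)[1]
  coef2 <- wm$coefficients
  coef2[, zero_col] <- 0
  expect_error(weight_matrix(coef2, wm$intercepts, wm$alpha, wm$lambda,
                             wm$cv_spearman,
                             replace(bad_wp, zero_col, TRUE)),
               "all-zero coefficient")

  # empty metabolite set cannot be serialized
  expect_error(weight_matrix(matrix(0, 2, 0,
                                    dimnames = list(c("a", "b"), NULL)),
                             numeric(0), numeric(0), numeric(0), numeric(0),
                             logical(0)),
               "no models")

  # a file without the intercept record is a format error
  path <- tempfile(fileext = ".tsv")
  write_weight_matrix(wm, path)
  txt <- readLines(path)
  writeLines(txt[!startsWith(txt, "intercept\t")], path)
  expect_error(read_weight_matrix(path), "intercept")
})

test_that("gene sets parse from GMT and long format, deduplicate, and round-trip", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("genusA\tdesc\tg1\tg2", "genusB\t\tg2\tg3\tg4"), gmt)
  sets <- read_gene_sets(gmt)
  expect_equal(sets$genusA, c("g1", "g2"))
  expect_equal(sets$genusB, c("g2", "g3", "g4"))

  dup <- tempfile(fileext = ".gmt")
  writeLines("genusA\tdesc\tg1\tg1", dup)
  expect_warning(dsets <- read_gene_sets(dup), "duplicate")
  expect_equal(dsets$genusA, "g1")

  empty <- tempfile(fileext = ".gmt")
  writeLines("genusA\tdesc", empty)
  expect_error(read_gene_sets(empty), "no members")

  long <- tempfile(fileext = ".tsv")
  writeLines(c("genusA\tg1", "genusA\tg1"), long)
  expect_warning(lsets <- read_gene_sets(long), "duplicate")
  expect_equal(lsets$genusA, "g1")

  for (fmt in c("gmt", "long")) {
    path <- tempfile()
    write_gene_sets(sets, path, format = fmt)
    got <- read_gene_sets(path, format = fmt)
    expect_equal(got[order(names(got))], sets[order(names(sets))],
                 ignore_attr = TRUE)
  }
})

test_that("sample alignment intersects by identifier and refuses tiny overlaps", {
  x <- tiny_table()
  y <- abundance_table(matrix(1:6, 3, 2,
                              dimnames = list(c("s3", "s1", "s2"),
                                              c("m1", "m2"))))
  al <- align_samples(x, y)
  expect_equal(sample_ids(al$x), sample_ids(al$y))
  expect_equal(sample_ids(al$x), c("s1", "s2", "s3")) # x's ordering
  expect_equal(al$y$values["s3", "m1"], 1)

  y2 <- abundance_table(matrix(1:4, 2, 2,
                               dimnames = list(c("s1", "zz"),
                                               c("m1", "m2"))))
  expect_error(align_samples(x, y2), "at least 3")
})
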
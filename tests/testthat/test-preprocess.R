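test_that("probe filter drops >20% missing and keeps exactly 20%", {
  v <- matrix(rnorm(30), 3, 10)
  v[1, 1:3] <- NA      # 30% missing -> dropped
  v[2, 1:2] <- NA      # exactly 20% -> kept
  m <- make_probes(v)
  f <- filter_probes(m, 0.20)
  expect_equal(rownames(f$values), c("p02", "p03"))

  complete <- make_probes(matrix(rnorm(20), 2, 10))
  expect_identical(filter_probes(complete)$values, complete$values)
})

test_that("knn imputation averages nearest neighbours and preserves observed cells", {
  v <- rbind(c(1, NA, 3), c(1, 2, 3), c(1, 2, 3), c(100, 50, 100))
  m <- make_probes(v)
  out <- knn_impute(m, k = 2)
  expect_equal(out$values[1, 2], 2)           # mean of the two identical rows
  obs <- !is.na(v)
  expect_identical(out$values[obs], v[obs])   # observed cells untouched

  complete <- make_probes(matrix(rnorm(12), 3))
  expect_identical(knn_impute(complete, 10)$values, complete$values)
})

test_that("knn imputation clamps k to the available neighbours", {
  set.seed(42)
  v <- matrix(rnorm(25), 5, 5)
  v[3, 2] <- NA
  m <- make_probes(v)
  expect_warning(out <- knn_impute(m, k = 10), "clamped")
  # oracle: with k larger than the pool, the imputed value is the plain
  # mean of every other row's entry in that column
  expect_equal(out$values[3, 2], mean(v[-3, 2]))
})

test_that("knn imputation refuses an all-missing row", {
  v <- matrix(rnorm(9), 3)
  v[2, ] <- NA
  expect_error(knn_impute(make_probes(v)), "every value missing")
})

test_that("probe collapse averages multi-probe genes and drops unmapped", {
  v <- rbind(c(2, 4), c(4, 8), c(1, 1), c(9, 9))
  m <- make_probes(v, groups = stats::setNames(rep("tumor", 2),
                                               c("s01", "s02")),
                   probe_to_gene = c(p01 = "G", p02 = "G", p03 = "H"))
  expect_message(g <- collapse_probes(m), "1 unmapped")
  expect_equal(g$values["G", ], c(s01 = 3, s02 = 6))
  expect_equal(g$values["H", ], c(s01 = 1, s02 = 1))  # single probe copied
  expect_false("p04" %in% rownames(g$values))
  expect_equal(nrow(g$values), 2L)
})

test_that("quantile normalization matches the hand-worked example", {
  m <- make_expr(cbind(c(1, 2, 3), c(4, 5, 6)), n_tumor = 1, n_normal = 1)
  q <- quantile_normalize(m)
  expect_equal(unname(q$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q$values[, 2]), c(2.5, 3.5, 4.5))

  ident <- make_expr(cbind(c(1, 5, 2), c(1, 5, 2)), n_tumor = 2)
  expect_equal(quantile_normalize(ident)$values, ident$values)

  single <- make_expr(matrix(c(3, 1, 2), 3, 1), n_tumor = 1)
  expect_identical(quantile_normalize(single)$values, single$values)
})

test_that("quantile normalization equalizes column distributions exactly", {
  set.seed(7)
  m <- make_expr(matrix(rnorm(200, 8, 2), 40, 5), n_tumor = 3, n_normal = 2)
  q <- quantile_normalize(m)
  sorted <- apply(q$values, 2, sort)
  for (j in 2:5)
    expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
  expect_equal(diff(range(colMeans(q$values))), 0, tolerance = 1e-12)
  # rank order within each column is preserved
  expect_equal(apply(q$values, 2, rank), apply(m$values, 2, rank))
})

test_that("log2 transform handles offsets and domain errors", {
  m <- make_expr(cbind(c(3, 0), c(1, 7)), n_tumor = 2)
  out <- log2_transform(m, offset = 1)
  expect_equal(out$values[1, 1], 2)
  expect_equal(out$values[2, 1], 0)
  bad <- make_expr(cbind(c(-2, 1)), n_tumor = 1)
  expect_error(log2_transform(bad, 1), "g01")
})

test_that("essentiality aggregates sgRNAs then cell lines", {
  t1 <- data.frame(sgrna = c("a", "b", "c"), gene = "G", cellline = "CL1",
                   fold_change = c(-1, -2, -3))
  e1 <- essentiality_from_sgrna(t1)
  expect_equal(unname(e1$essentiality["G"]), -2)
  expect_equal(e1$per_cellline$fold_change, -2)

  # mean of per-cellline means, not pooled: CL1 has 3 sgRNAs at -1, CL2
  # one sgRNA at -3 -> gene value (-1 + -3)/2, not the pooled -1.5
  t2 <- data.frame(sgrna = c("a", "b", "c", "d"), gene = "G",
                   cellline = c("CL1", "CL1", "CL1", "CL2"),
                   fold_change = c(-1, -1, -1, -3))
  expect_equal(unname(essentiality_from_sgrna(t2)$essentiality["G"]), -2)

  # single sgRNA, single cell line: the fold change passes through
  t3 <- data.frame(sgrna = "s", gene = "PGK1", cellline = "CL1",
                   fold_change = -1.84)
  expect_equal(unname(essentiality_from_sgrna(t3)$essentiality["PGK1"]),
               -1.84)
})

test_that("essentiality is invariant to record order", {
  set.seed(3)
  t <- data.frame(sgrna = sprintf("sg%d", 1:12),
                  gene = rep(c("A", "B"), each = 6),
                  cellline = rep(c("CL1", "CL2"), 6),
                  fold_change = rnorm(12))
  shuffled <- t[sample(nrow(t)), ]
  expect_equal(essentiality_from_sgrna(t)$essentiality,
               essentiality_from_sgrna(shuffled)$essentiality)
})
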
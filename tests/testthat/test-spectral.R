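test_that("spectral matrices match the 2-node hand computation", {
  net <- make_network(data.frame(gene_a = "a", gene_b = "b", weight = 1),
                      c(a = 2, b = 2), context = "tissue")
  mats <- build_matrices(net)
  expect_equal(unname(mats$S_prime), rbind(c(1, 1), c(1, 1)))
  expect_equal(unname(mats$S_dprime), rbind(c(1, 1), c(1, 1)))
  expect_equal(unname(mats$L_raw), rbind(c(1, -1), c(-1, 1)))
  expect_equal(unname(mats$L_norm), rbind(c(0.5, -0.5), c(-0.5, 0.5)))
  expect_equal(mats$asymmetry, 0)

  e <- eigendecompose(mats, 2)
  expect_equal(e$values, c(0, 1))   # characteristic polynomial by hand
})

test_that("degree-weighted binary limit reproduces the standard Laplacian", {
  cu <- clique_union_network(c(4, 5))
  mats <- build_matrices(cu$net)
  # S'' collapses to the affinity matrix itself
  expect_equal(mats$S_dprime, mats$S_prime, tolerance = 1e-12)
  # and L_raw to D - A of the plain graph
  A <- mats$S_prime - diag(nrow(mats$S_prime))
  L_std <- diag(rowSums(A)) - A
  expect_equal(unname(mats$L_raw), unname(L_std), tolerance = 1e-10)
})

test_that("degree-weighted limit agrees with an independent graph library", {
  skip_if_not_installed("igraph")
  cu <- clique_union_network(c(3, 4))
  mats <- build_matrices(cu$net)
  g <- igraph::graph_from_data_frame(
    cu$net$edges[c("gene_a", "gene_b")], directed = FALSE,
    vertices = cu$net$nodes)
  L_ref <- as.matrix(igraph::laplacian_matrix(g))
  L_ref <- L_ref[mats$genes, mats$genes]
  expect_equal(unname(mats$L_raw), unname(L_ref), tolerance = 1e-10)
})

test_that("single-node network degenerates cleanly", {
  net <- make_network(data.frame(gene_a = character(0),
                                 gene_b = character(0),
                                 weight = numeric(0)),
                      c(a = 1.5), context = "tissue")
  mats <- build_matrices(net)
  expect_equal(dim(mats$L_norm), c(1L, 1L))
  cl <- spectral_cluster(net, k = 1)
  expect_equal(unname(cl$assignment), 1L)
})

test_that("non-positive node weights are rejected for the tissue Laplacian", {
  net <- worked_cluster()  # cell-line context, negative weights
  expect_error(build_matrices(net), "positive")
})

test_that("eigendecomposition is complete, orthonormal and sign-fixed", {
  set.seed(12)
  edges <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                      weight = c(0.9, 0.4, 0.7))
  net <- make_network(edges, c(a = 1, b = 2, c = 1.5), context = "tissue")
  mats <- build_matrices(net)
  e <- eigendecompose(mats, 3)
  expect_equal(crossprod(e$vectors), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  sym <- (mats$L_norm + t(mats$L_norm)) / 2
  recon <- e$vectors %*% diag(e$values) %*% t(e$vectors)
  expect_equal(recon, sym, tolerance = 1e-8, ignore_attr = TRUE)
  # largest-magnitude entry of each eigenvector is positive
  for (j in 1:3) expect_gt(e$vectors[which.max(abs(e$vectors[, j])), j], 0)
  expect_true(all(is.finite(e$values)))
})

test_that("Hartigan selection finds planted two-blob structure", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    emb <- cbind(c(rnorm(30), rnorm(30, 5)), matrix(rnorm(60 * 5), 60))
    r <- choose_k_hartigan(emb, k_max = 5, seed = s)
    if (r$K == 2 && r$trace$hartigan[1] > 10 && r$trace$hartigan[2] < 10)
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("Hartigan degenerate cases follow the formula", {
  # all points identical: W_1 = 0 -> H(1) = 0 -> K = 1
  emb <- matrix(1, 5, 2)
  r <- choose_k_hartigan(emb, k_max = 3)
  expect_equal(r$K, 1L)
  # W_k == W_{k+1} forces H(k) = 0 and selection at that k
  expect_equal(r$trace$hartigan[1], 0)
})

test_that("two disconnected cliques cluster into exactly the cliques", {
  cu <- clique_union_network(c(5, 6))
  cl <- spectral_cluster(cu$net, k = 2, seed = 3)
  expect_equal(cl$K, 2L)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(cl$assignment, cu$membership), 1)
})

test_that("clustering honours trivial k and is deterministic", {
  cu <- clique_union_network(c(4, 4))
  n <- length(cu$net$nodes)
  expect_equal(unname(spectral_cluster(cu$net, k = 1)$assignment),
               rep(1L, n))
  all_own <- spectral_cluster(cu$net, k = n, seed = 1)
  expect_equal(length(unique(all_own$assignment)), n)
  a <- spectral_cluster(cu$net, k = 2, seed = 42)$assignment
  b <- spectral_cluster(cu$net, k = 2, seed = 42)$assignment
  expect_identical(a, b)
})

test_that("auto-K recovers planted correlation blocks", {
  spec <- scn_sim_spec(n_genes = 80, block_sizes = rep(15L, 3),
                       n_tumor = 30, n_normal = 30, n_cellline = 30,
                       n_under = 10, missing_frac = 0)
  aris <- vapply(1:5, function(s) {
    r <- suppressWarnings(suppressMessages(evaluate_recovery(spec,
                                                             seed = s)))
    r$ari
  }, numeric(1))
  expect_gte(median(aris), 0.8)
})
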
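test_that("worked 3-node cluster: paths and TI match the hand oracle", {
  net <- worked_cluster()
  paths <- max_correlation_paths(net, c("x", "a", "b"), "x")
  p <- stats::setNames(paths$product, paths$node)
  expect_equal(p[["x"]], 1)                 # empty path
  expect_equal(p[["a"]], 0.5)               # direct beats 0.1 * -0.8
  expect_equal(p[["b"]], -0.4)              # via a beats direct 0.1
  expect_equal(paths$path[paths$node == "b"], "x|a|b")

  ti <- target_influence(net, c("x", "a", "b"), "x")
  # hand sum: (-1)(1) + (-1)(0.5) + (-2)(-0.4)
  expect_equal(ti$TI, -0.7)
  expect_equal(ti$abs_TI, 0.7)
  expect_equal(ti$reachable, 3L)
})

test_that("path search respects reachability and unit chains", {
  chain <- make_network(data.frame(gene_a = c("x", "a"),
                                   gene_b = c("a", "b"),
                                   weight = c(1, 1)),
                        c(x = -1, a = -1, b = -1))
  p <- max_correlation_paths(chain, c("x", "a", "b"), "x")
  expect_equal(p$product, c(1, 1, 1))

  # isolated node never appears; zero-weight edges are non-traversable
  iso <- make_network(data.frame(gene_a = c("x", "a"),
                                 gene_b = c("a", "c"),
                                 weight = c(0.5, 0)),
                      c(x = -1, a = -1, b = -1, c = -1))
  p2 <- max_correlation_paths(iso, c("x", "a", "b", "c"), "x")
  expect_setequal(p2$node, c("x", "a"))
  expect_error(max_correlation_paths(iso, c("x", "a"), "q"), "not in")
})

test_that("Dijkstra variant equals exhaustive enumeration on random graphs", {
  set.seed(77)
  n_checked <- 0
  for (i in 1:200) {
    n <- sample(4:8, 1)
    edges <- random_graph(n, p = 0.5)
    if (!nrow(edges)) next
    nodes <- sprintf("v%d", seq_len(n))
    w <- stats::setNames(runif(n, -2, 0), nodes)
    net <- make_network(edges, w)
    src <- sample(nodes, 1)
    got <- max_correlation_paths(net, nodes, src)
    want <- enumerate_best_products(edges, nodes, src)
    expect_setequal(got$node, names(want))
    want <- want[got$node]
    expect_equal(got$magnitude, abs(unname(want)), tolerance = 1e-12)
    expect_identical(sign(got$product), sign(unname(want)))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 190)
})

test_that("TI degenerate cases", {
  single <- make_network(data.frame(gene_a = character(0),
                                    gene_b = character(0),
                                    weight = numeric(0)),
                         c(x = -2))
  expect_equal(target_influence(single, "x", "x")$TI, -2)

  net0 <- worked_cluster()
  net0$node_weight[] <- 0
  expect_equal(target_influence(net0, c("x", "a", "b"), "x")$TI, 0)
})

test_that("TI is linear in node weights and local to the cluster", {
  net <- worked_cluster()
  base <- target_influence(net, c("x", "a", "b"), "x")$TI
  scaled <- net
  scaled$node_weight <- 3 * scaled$node_weight
  expect_equal(target_influence(scaled, c("x", "a", "b"), "x")$TI, 3 * base)

  # edits outside the cluster's induced subgraph change nothing
  bigger <- make_network(
    data.frame(gene_a = c("x", "a", "x", "b", "q"),
               gene_b = c("a", "b", "b", "q", "r"),
               weight = c(0.5, -0.8, 0.1, 0.99, 0.9)),
    c(x = -1, a = -1, b = -2, q = -5, r = -5))
  expect_equal(target_influence(bigger, c("x", "a", "b"), "x")$TI, base)
})

test_that("adding an edge never decreases an optimal path magnitude", {
  set.seed(31)
  for (i in 1:20) {
    edges <- random_graph(6, p = 0.4)
    if (nrow(edges) < 2) next
    nodes <- sprintf("v%d", 1:6)
    w <- stats::setNames(rep(-1, 6), nodes)
    net1 <- make_network(edges, w)
    # add one new edge not already present
    prs <- utils::combn(nodes, 2)
    key <- paste(edges$gene_a, edges$gene_b)
    cand <- which(!(paste(prs[1, ], prs[2, ]) %in% key))
    if (!length(cand)) next
    pick <- sample(cand, 1)
    edges2 <- rbind(edges, data.frame(gene_a = prs[1, pick],
                                      gene_b = prs[2, pick],
                                      weight = runif(1, -1, 1)))
    net2 <- make_network(edges2, w)
    p1 <- max_correlation_paths(net1, nodes, "v1")
    p2 <- max_correlation_paths(net2, nodes, "v1")
    common <- intersect(p1$node, p2$node)
    m1 <- stats::setNames(p1$magnitude, p1$node)[common]
    m2 <- stats::setNames(p2$magnitude, p2$node)[common]
    expect_true(all(m2 >= m1 - 1e-12))
    expect_true(all(p1$node %in% p2$node))
  }
})

test_that("rank_targets orders by |TI|, picks representatives, skips unknowns", {
  # two separate clusters with one strong and one weak target each
  edges <- data.frame(gene_a = c("a1", "a1", "b1"),
                      gene_b = c("a2", "a3", "b2"),
                      weight = c(0.9, 0.8, 0.9))
  net <- make_network(edges,
                      c(a1 = -3, a2 = -1, a3 = -0.5, b1 = -1, b2 = -0.2))
  clusters <- c(a1 = 1L, a2 = 1L, a3 = 1L, b1 = 2L, b2 = 2L)
  rk <- suppressMessages(
    rank_targets(net, clusters, c("a1", "a2", "b1", "NOPE")))
  expect_equal(rk$rank, 1:3)
  expect_true(all(diff(rk$abs_TI) <= 0))
  expect_equal(rk$gene[1], "a1")
  reps <- attr(rk, "representatives")
  expect_equal(reps$gene[reps$cluster == 1], "a1")
  expect_equal(attr(rk, "skipped"), "NOPE")
  # a target's score is computed within its own cluster only
  expect_equal(rk$reachable[rk$gene == "b1"], 2L)
})
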
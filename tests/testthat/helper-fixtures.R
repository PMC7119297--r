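# shared fixtures and independent oracles

# small labelled expression matrix built from a plain matrix
make_expr <- function(values, n_tumor = 0, n_normal = 0, n_cellline = 0) {
  groups <- rep(c("tumor", "normal", "cellline"),
                c(n_tumor, n_normal, n_cellline))
  stopifnot(length(groups) == ncol(values))
  colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  scn_expr(values, stats::setNames(groups, colnames(values)))
}

make_probes <- function(values, groups = NULL, probe_to_gene = NULL) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  if (is.null(groups))
    groups <- stats::setNames(rep("tumor", ncol(values)), colnames(values))
  scn_probes(values, groups, probe_to_gene)
}

# network built directly from an edge table (gene_a, gene_b, weight)
make_network <- function(edges, node_weight, context = "cellline") {
  nodes <- names(node_weight)
  scn_network(nodes, node_weight,
              data.frame(gene_a = edges$gene_a, gene_b = edges$gene_b,
                         weight = edges$weight, stringsAsFactors = FALSE),
              context = context)
}

# independent oracle: exhaustive enumeration of all simple paths from
# `source`, keeping per node the signed product with maximum magnitude.
# Exponential; for graphs of <= 8 nodes only.
enumerate_best_products <- function(edges, nodes, source) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    rows <- edges$gene_a == v | edges$gene_b == v
    e <- edges[rows & edges$weight != 0, , drop = FALSE]
    if (!nrow(e)) return(NULL)
    data.frame(to = ifelse(e$gene_a == v, e$gene_b, e$gene_a),
               w = e$weight, stringsAsFactors = FALSE)
  })
  best <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  best[source] <- 1
  recurse <- function(cur, visited, prod) {
    nb <- adj[[cur]]
    if (is.null(nb)) return()
    for (i in seq_len(nrow(nb))) {
      v <- nb$to[i]
      if (v %in% visited) next
      p <- prod * nb$w[i]
      if (is.na(best[v]) || abs(p) > abs(best[v])) best[v] <<- p
      recurse(v, c(visited, v), p)
    }
  }
  recurse(source, source, 1)
  best[!is.na(best)]
}

# random weighted graph on n nodes, edge probability p, weights in [-1, 1]
random_graph <- function(n, p = 0.5) {
  nodes <- sprintf("v%d", seq_len(n))
  prs <- utils::combn(nodes, 2)
  pick <- stats::runif(ncol(prs)) < p
  data.frame(gene_a = prs[1, pick], gene_b = prs[2, pick],
             weight = stats::runif(sum(pick), -1, 1),
             stringsAsFactors = FALSE)
}

# the worked 3-node cluster: edges x-a 0.5, a-b -0.8, x-b 0.1,
# essentialities x=-1, a=-1, b=-2
worked_cluster <- function() {
  edges <- data.frame(gene_a = c("x", "a", "x"),
                      gene_b = c("a", "b", "b"),
                      weight = c(0.5, -0.8, 0.1),
                      stringsAsFactors = FALSE)
  make_network(edges, c(x = -1, a = -1, b = -2))
}

# binary clique-union network in the degree limit: edge weights 1 and node
# weight = affinity row sum (degree + 1), the regime where the weighted
# spectral matrices reduce to the standard graph Laplacian
clique_union_network <- function(sizes) {
  nodes <- sprintf("n%02d", seq_len(sum(sizes)))
  membership <- rep(seq_along(sizes), sizes)
  ea <- character(0); eb <- character(0)
  for (b in seq_along(sizes)) {
    members <- nodes[membership == b]
    if (length(members) >= 2) {
      prs <- utils::combn(members, 2)
      ea <- c(ea, prs[1, ]); eb <- c(eb, prs[2, ])
    }
  }
  degree <- table(factor(c(ea, eb), levels = nodes))
  w <- stats::setNames(as.numeric(degree) + 1, nodes)
  net <- make_network(data.frame(gene_a = ea, gene_b = eb, weight = 1),
                      w, context = "tissue")
  list(net = net, membership = stats::setNames(membership, nodes))
}
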
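# adjacency list of the cluster-induced subgraph; zero-weight edges are
# non-traversable and removed up front (their -log|r| cost is undefined)
cluster_adjacency <- function(net, cluster_nodes) {
  idx <- stats::setNames(seq_along(cluster_nodes), cluster_nodes)
  e <- net$edges
  keep <- e$gene_a %in% cluster_nodes & e$gene_b %in% cluster_nodes &
    e$weight != 0
  e <- e[keep, , drop = FALSE]
  adj <- vector("list", length(cluster_nodes))
  if (nrow(e)) {
    a <- idx[e$gene_a]; b <- idx[e$gene_b]
    for (r in seq_len(nrow(e))) {
      adj[[a[r]]] <- rbind(adj[[a[r]]], c(b[r], e$weight[r]))
      adj[[b[r]]] <- rbind(adj[[b[r]]], c(a[r], e$weight[r]))
    }
  }
  adj
}

#' Most-correlated paths from a drug target to its cluster members
#'
#' For every node of the cluster reachable from `source`, finds the path
#' maximizing the absolute product of edge correlations, and reports the
#' signed product (the sign encodes whether the transmitted influence is
#' concordant or anti-correlated).  Implemented as a Dijkstra search with
#' edge cost `-log|r|`, which is non-negative because `|r| <= 1`, so the
#' classic shortest-path guarantee applies to the maximum-|product| path.
#' The search never leaves the subgraph induced by `cluster_nodes` (a
#' target's influence is confined to its own cluster), zero-weight edges
#' are non-traversable, and the source itself gets the empty path with
#' product 1.
#'
#' The historical alternative of summing reciprocal edge weights
#' (`path_mode = "reciprocal"`, minimizing `sum 1/|r|`) is kept for
#' comparison; it favours short paths through strong edges but does not in
#' general maximize the product.
#'
#' @param net an [scn_network()] (typically the cell-line network).
#' @param cluster_nodes character vector of genes forming the cluster.
#' @param source the drug-target gene; must belong to `cluster_nodes`.
#' @param path_mode `"logprod"` (default, exact max-|product|) or
#'   `"reciprocal"`.
#' @return Data frame with one row per reachable node: columns `node`,
#'   `product` (signed), `magnitude`, `path` (pipe-separated node
#'   sequence from source).
#' @export
max_correlation_paths <- function(net, cluster_nodes, source,
                                  path_mode = c("logprod", "reciprocal")) {
  path_mode <- match.arg(path_mode)
  stopifnot(inherits(net, "scn_network"))
  cluster_nodes <- as.character(cluster_nodes)
  if (!source %in% cluster_nodes)
    stop("source '", source, "' is not in the cluster")
  if (!all(cluster_nodes %in% net$nodes))
    stop("cluster contains gene(s) outside the network")
  n <- length(cluster_nodes)
  adj <- cluster_adjacency(net, cluster_nodes)
  s <- match(source, cluster_nodes)

  cost_of <- if (path_mode == "logprod") function(w) -log(abs(w))
             else function(w) 1 / abs(w)
  dist <- rep(Inf, n); dist[s] <- 0
  parent <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  repeat {
    masked <- dist
    masked[done] <- Inf
    u <- which.min(masked)
    if (!is.finite(masked[u])) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) {
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]; w <- nb[r, 2]
        alt <- dist[u] + cost_of(w)
        if (alt < dist[v]) {
          dist[v] <- alt
          parent[v] <- u
        }
      }
    }
  }

  reach <- which(is.finite(dist))
  res <- lapply(reach, function(v) {
    # reconstruct the path and multiply its actual edge weights, so the
    # reported product is exact rather than exp(-cost)
    path <- v
    while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
    prod_w <- 1
    if (length(path) > 1) {
      for (i in seq_len(length(path) - 1)) {
        nb <- adj[[path[i]]]
        w <- nb[nb[, 1] == path[i + 1], 2][1]
        prod_w <- prod_w * w
      }
    }
    data.frame(node = cluster_nodes[v], product = prod_w,
               magnitude = abs(prod_w),
               path = paste(cluster_nodes[path], collapse = "|"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Target Influence score of one drug target
#'
#' `TI = sum over reachable cluster members k of node_weight(k) *
#' (signed max-|product| path correlation from the target to k)`, including
#' the target itself with product 1.  On the cell-line network the node
#' weights are CRISPR essentialities, so a strongly negative TI means
#' hitting the target propagates, via correlated partners, onto genes
#' whose loss impairs survival.
#'
#' @inheritParams max_correlation_paths
#' @param target the drug-target gene.
#' @return List with `gene`, `TI`, `abs_TI`, `reachable` (count of cluster
#'   members with a path, including the target), and `paths` (the
#'   [max_correlation_paths()] table).
#' @export
target_influence <- function(net, cluster_nodes, target,
                             path_mode = c("logprod", "reciprocal")) {
  paths <- max_correlation_paths(net, cluster_nodes, target,
                                 path_mode = path_mode)
  w <- net$node_weight[paths$node]
  ti <- sum(w * paths$product)
  list(gene = target, TI = ti, abs_TI = abs(ti),
       reachable = nrow(paths), paths = paths)
}

#' Rank drug targets by Target Influence
#'
#' Maps each candidate target onto its cluster (from the tissue-network
#' partition), scores it with [target_influence()] on the cell-line
#' network restricted to that cluster, and ranks all scored targets by
#' `|TI|` descending (ties broken lexicographically by gene id).  Raw
#' signed TI is reported alongside.  Per cluster, the target with maximal
#' `|TI|` is recorded as the cluster's representative druggable target.
#' Targets absent from the network are skipped and listed in the
#' `"skipped"` attribute.
#'
#' @param net_cellline the cell-line [scn_network()] (shares the tissue
#'   skeleton).
#' @param clusters an `scn_clusters` from [spectral_cluster()] (or a named
#'   integer vector gene -> cluster).
#' @param targets character vector of drug-target gene symbols.
#' @param path_mode see [max_correlation_paths()].
#' @return A data frame of class `scn_ranking` with columns `gene`,
#'   `cluster`, `TI`, `abs_TI`, `reachable`, `rank`; attributes
#'   `"representatives"` (data frame cluster / gene / abs_TI) and
#'   `"skipped"` (character vector).
#' @export
rank_targets <- function(net_cellline, clusters, targets,
                         path_mode = c("logprod", "reciprocal")) {
  path_mode <- match.arg(path_mode)
  assignment <- if (inherits(clusters, "scn_clusters")) clusters$assignment
                else clusters
  stopifnot(!is.null(names(assignment)))
  targets <- unique(as.character(targets))
  mapped <- targets[targets %in% net_cellline$nodes &
                    targets %in% names(assignment)]
  skipped <- setdiff(targets, mapped)
  if (length(skipped))
    message(length(skipped), " target(s) not in the network; skipped")
  if (!length(mapped))
    stop("no target maps onto the network")
  rows <- lapply(mapped, function(g) {
    cl <- assignment[[g]]
    members <- names(assignment)[assignment == cl]
    ti <- target_influence(net_cellline, members, g, path_mode = path_mode)
    data.frame(gene = g, cluster = cl, TI = ti$TI, abs_TI = ti$abs_TI,
               reachable = ti$reachable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$abs_TI, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  reps <- do.call(rbind, lapply(split(out, out$cluster), function(d)
    d[which.max(d$abs_TI), c("cluster", "gene", "abs_TI")]))
  rownames(reps) <- NULL
  attr(out, "representatives") <- reps
  attr(out, "skipped") <- skipped
  class(out) <- c("scn_ranking", "data.frame")
  out
}
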
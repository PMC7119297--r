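#' Pearson correlations for a set of candidate gene pairs
#'
#' Computes the Pearson correlation for each candidate pair only (never the
#' full dense matrix), over the expression columns supplied.  Pairs where
#' either gene has zero variance get weight 0 with a warning.
#'
#' @param values numeric matrix (genes x samples), complete.
#' @param pairs data frame with character columns `gene_a`, `gene_b`; all
#'   genes must be rows of `values`.
#' @return `pairs` with a `weight` column of correlations appended.
#' @export
pearson_edges <- function(values, pairs) {
  stopifnot(ncol(values) >= 3)
  if (!nrow(pairs)) {
    pairs$weight <- numeric(0)
    return(pairs)
  }
  if (!all(c(pairs$gene_a, pairs$gene_b) %in% rownames(values)))
    stop("candidate edge endpoint absent from expression matrix")
  x <- values - rowMeans(values)
  ss <- sqrt(rowSums(x^2))
  a <- match(pairs$gene_a, rownames(values))
  b <- match(pairs$gene_b, rownames(values))
  num <- rowSums(x[a, , drop = FALSE] * x[b, , drop = FALSE])
  den <- ss[a] * ss[b]
  w <- ifelse(den > 0, num / den, 0)
  if (any(den == 0))
    warning(sum(den == 0), " pair(s) involve a zero-variance gene; ",
            "correlation set to 0")
  pairs$weight <- pmin(1, pmax(-1, w))
  pairs
}

#' Build the tissue-specific integrated network
#'
#' Nodes are the over-expressed genes that overlap the PPI skeleton; edges
#' are the PPI edges between those nodes, weighted by Pearson correlation
#' over the tumor tissue samples; node weights are the log2 fold changes.
#' Genes lost at the PPI overlap and isolated nodes are reported via
#' messages but isolated nodes are retained (they remain clusterable).
#'
#' @param m_tissue an [scn_expr()] whose tumor columns supply the
#'   correlations.
#' @param diff selection table from [select_overexpressed()].
#' @param ppi an [scn_ppi()] edge list.
#' @return An [scn_network()] with `context = "tissue"`.
#' @export
build_tissue_network <- function(m_tissue, diff, ppi) {
  stopifnot(inherits(m_tissue, "scn_expr"), nrow(diff) > 0)
  ppi_nodes <- unique(c(ppi$gene_a, ppi$gene_b))
  nodes <- intersect(sort(diff$gene), ppi_nodes)
  if (!length(nodes))
    stop("no overlap between selected genes and the PPI network")
  n_lost <- nrow(diff) - length(nodes)
  if (n_lost > 0)
    message(n_lost, " selected gene(s) absent from the PPI network")
  edges <- ppi[ppi$gene_a %in% nodes & ppi$gene_b %in% nodes,
               c("gene_a", "gene_b"), drop = FALSE]
  ti <- group_columns(m_tissue, "tumor")
  vals <- m_tissue$values[nodes, ti, drop = FALSE]
  edges <- pearson_edges(vals, as.data.frame(edges))
  iso <- setdiff(nodes, unique(c(edges$gene_a, edges$gene_b)))
  if (length(iso))
    message(length(iso), " isolated node(s) retained")
  w <- stats::setNames(diff$log_fc, diff$gene)[nodes]
  scn_network(nodes, w, edges, context = "tissue")
}

#' Build the cell-line integrated network on the tissue skeleton
#'
#' The node and edge sets are copied verbatim from the tissue network (the
#' shared skeleton that makes the two contexts comparable); edge weights
#' are recomputed as Pearson correlations over the cell-line samples and
#' node weights are replaced by CRISPR gene essentiality.  Genes missing
#' from the essentiality table keep weight 0 with a warning so the skeleton
#' is preserved.
#'
#' @param m_cellline an [scn_expr()] whose cellline columns supply the
#'   correlations.
#' @param tissue_net the [scn_network()] from [build_tissue_network()].
#' @param ess an `scn_essentiality` from [essentiality_from_sgrna()].
#' @return An [scn_network()] with `context = "cellline"`.
#' @export
build_cellline_network <- function(m_cellline, tissue_net, ess) {
  stopifnot(inherits(m_cellline, "scn_expr"),
            inherits(tissue_net, "scn_network"),
            inherits(ess, "scn_essentiality"))
  nodes <- tissue_net$nodes
  missing_expr <- setdiff(nodes, rownames(m_cellline$values))
  if (length(missing_expr))
    stop("tissue-network gene(s) absent from cell-line expression: ",
         paste(utils::head(missing_expr, 5), collapse = ", "))
  ci <- group_columns(m_cellline, "cellline")
  vals <- m_cellline$values[nodes, ci, drop = FALSE]
  edges <- pearson_edges(vals,
                         tissue_net$edges[c("gene_a", "gene_b")])
  w <- ess$essentiality[nodes]
  names(w) <- nodes
  n_missing <- sum(is.na(w))
  if (n_missing > 0) {
    warning(n_missing, " gene(s) without essentiality; node weight 0")
    w[is.na(w)] <- 0
  }
  scn_network(nodes, w, edges, context = "cellline")
}
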
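#' Rank drug targets from paired tissue / cell-line networks
#'
#' The package's main entry point.  Given gene-level tumor+normal tissue
#' expression, cell-line expression, a PPI skeleton, gene essentiality and
#' a candidate drug-target list, it runs the four-step procedure:
#'
#' 1. select genes over-expressed in tumor vs normal (unpaired t-test,
#'    `p < alpha`, positive log2 fold change) and build the tissue network
#'    on the PPI skeleton (edge weights = tumor-sample correlations, node
#'    weights = log2 fold change);
#' 2. build the cell-line network on the identical skeleton (edge weights =
#'    cell-line correlations, node weights = CRISPR essentiality);
#' 3. partition the tissue network by fold-change-weighted spectral
#'    clustering, choosing K with Hartigan's rule unless given;
#' 4. align each cluster onto the cell-line network and score every mapped
#'    target by Target Influence (essentiality-weighted sum of signed
#'    max-|product| path correlations within its cluster), ranking all
#'    targets by |TI|.
#'
#' @param tissue gene-level [scn_expr()] with tumor and normal samples
#'   (log2 scale, preprocessed).
#' @param cellline gene-level [scn_expr()] with cell-line samples.
#' @param ppi an [scn_ppi()] edge list (already score-thresholded, see
#'   [read_ppi()]).
#' @param essentiality an `scn_essentiality` from
#'   [essentiality_from_sgrna()].
#' @param targets character vector of candidate drug-target genes.
#' @param alpha t-test p-value cutoff, default 0.05.
#' @param variant t-test variant, `"welch"` (default) or `"student"`.
#' @param k cluster count or `"auto"` (Hartigan selection).
#' @param m eigenvector count; `NULL` defaults to the cluster count.
#' @param k_max,hartigan_threshold,restarts,eigen_order passed to
#'   [spectral_cluster()].
#' @param path_mode passed to [rank_targets()].
#' @param seed integer seed for the clustering.
#' @return An object of class `scnrank`: list with `diff` (selection
#'   table), `tissue_network`, `cellline_network`, `clusters`, `ranking`,
#'   `counts` (named integer bookkeeping vector), `params`, `call`.
#' @seealso [scn_simulate()] for synthetic inputs, [scn_run()] for the
#'   file-based pipeline.
#' @export
scnrank <- function(tissue, cellline, ppi, essentiality, targets,
                    alpha = 0.05, variant = c("welch", "student"),
                    k = "auto", m = NULL, k_max = NULL,
                    hartigan_threshold = 10, restarts = 10,
                    eigen_order = c("smallest", "largest"),
                    path_mode = c("logprod", "reciprocal"), seed = 1) {
  variant <- match.arg(variant)
  eigen_order <- match.arg(eigen_order)
  path_mode <- match.arg(path_mode)

  diff <- select_overexpressed(tissue, alpha = alpha, variant = variant)
  if (!nrow(diff)) stop("no over-expressed gene at alpha = ", alpha)
  tissue_net <- build_tissue_network(tissue, diff, ppi)
  cellline_net <- build_cellline_network(cellline, tissue_net, essentiality)
  clusters <- spectral_cluster(tissue_net, m = m, k = k, k_max = k_max,
                               hartigan_threshold = hartigan_threshold,
                               restarts = restarts, seed = seed,
                               eigen_order = eigen_order)
  ranking <- rank_targets(cellline_net, clusters, targets,
                          path_mode = path_mode)
  counts <- c(genes_tested = nrow(attr(diff, "all_genes")),
              genes_selected = nrow(diff),
              genes_after_ppi = length(tissue_net$nodes),
              edges = nrow(tissue_net$edges),
              K = clusters$K,
              targets_supplied = length(unique(targets)),
              targets_mapped = nrow(ranking))
  structure(list(diff = diff, tissue_network = tissue_net,
                 cellline_network = cellline_net, clusters = clusters,
                 ranking = ranking, counts = counts,
                 params = list(alpha = alpha, variant = variant, k = k,
                               m = m, hartigan_threshold = hartigan_threshold,
                               restarts = restarts, eigen_order = eigen_order,
                               path_mode = path_mode, seed = seed),
                 call = match.call()),
            class = "scnrank")
}

#' @export
print.scnrank <- function(x, ...) {
  cat("Spectral-clustering network rank\n\n")
  cat(sprintf("  %d genes tested, %d over-expressed, %d on the PPI skeleton\n",
              x$counts["genes_tested"], x$counts["genes_selected"],
              x$counts["genes_after_ppi"]))
  cat(sprintf("  %d clusters (K), %d / %d targets mapped and ranked\n",
              x$counts["K"], x$counts["targets_mapped"],
              x$counts["targets_supplied"]))
  cat("\nTop targets by |TI|:\n")
  print(utils::head(as.data.frame(x$ranking), 5))
  invisible(x)
}

#' @export
summary.scnrank <- function(object, ...) {
  structure(list(counts = object$counts,
                 eigenvalues = object$clusters$eigenvalues,
                 cluster_sizes = table(object$clusters$assignment),
                 ranking = as.data.frame(object$ranking),
                 representatives = attr(object$ranking, "representatives"),
                 skipped = attr(object$ranking, "skipped")),
            class = "summary.scnrank")
}

#' @export
print.summary.scnrank <- function(x, ...) {
  cat("Pipeline bookkeeping:\n")
  print(x$counts)
  cat("\nCluster sizes:\n")
  print(x$cluster_sizes)
  cat("\nRanked targets:\n")
  print(x$ranking)
  cat("\nPer-cluster representative targets:\n")
  print(x$representatives)
  if (length(x$skipped))
    cat("\nSkipped (not in network):", paste(x$skipped, collapse = ", "),
        "\n")
  invisible(x)
}

#' Extract Target Influence scores
#'
#' @param object an `scnrank` fit.
#' @param ... unused.
#' @return Named numeric vector of signed TI scores in rank order.
#' @export
coef.scnrank <- function(object, ...) {
  stats::setNames(object$ranking$TI, object$ranking$gene)
}

#' Diagnostic plots for an scnrank fit
#'
#' Two base-graphics panels: the eigenvalue spectrum of the weighted
#' normalized Laplacian (structure shows as a gap after the leading
#' eigenvalues) and the ranked |TI| scores, colored by sign of TI.
#'
#' @param x an `scnrank` fit.
#' @param ... unused.
#' @export
plot.scnrank <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$clusters$eigenvalues, pch = 19, xlab = "index",
       ylab = "eigenvalue", main = "Laplacian spectrum")
  rk <- x$ranking
  graphics::barplot(rk$abs_TI, names.arg = rk$gene, las = 2,
                    col = ifelse(rk$TI < 0, "firebrick", "steelblue"),
                    ylab = "|TI|", main = "Target influence")
  invisible(x)
}
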
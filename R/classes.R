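#' Expression matrix with sample group labels
#'
#' Container for a genes x samples expression matrix on the log2 (or raw
#' intensity) scale, with each sample labelled as tumor, normal or cell-line
#' material.  This is the substrate of the preprocessing, differential
#' expression and network construction steps.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimnames must be set.  Missing entries (`NA`) are permitted.
#' @param groups named character vector mapping every sample id to one of
#'   `"tumor"`, `"normal"`, `"cellline"`.
#' @return An object of class `scn_expr`: a list with elements `values` and
#'   `groups`.
#' @export
scn_expr <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  storage.mode(values) <- "double"
  groups <- validate_groups(groups, colnames(values))
  structure(list(values = values, groups = groups), class = "scn_expr")
}

#' Probe-level expression matrix
#'
#' Like [scn_expr()] but rows are array probes, each optionally mapped to a
#' gene symbol.  Probe matrices are the input of the preprocessing chain
#' (probe filtering, KNN imputation, probe-to-gene collapse).
#'
#' @inheritParams scn_expr
#' @param probe_to_gene named character vector mapping probe ids to gene
#'   symbols; probes absent from the map (or mapped to `NA`) are unmapped and
#'   are dropped at collapse time.
#' @return An object of class `scn_probes`.
#' @export
scn_probes <- function(values, groups, probe_to_gene = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("probe matrix must have probe row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  storage.mode(values) <- "double"
  groups <- validate_groups(groups, colnames(values))
  if (!is.null(probe_to_gene)) {
    if (is.null(names(probe_to_gene)))
      stop("probe_to_gene must be a named character vector")
    probe_to_gene <- probe_to_gene[names(probe_to_gene) %in% rownames(values)]
  }
  structure(list(values = values, groups = groups,
                 probe_to_gene = probe_to_gene),
            class = "scn_probes")
}

validate_groups <- function(groups, sample_ids) {
  if (is.null(names(groups)))
    stop("groups must be a named vector (sample id -> group)")
  nm <- names(groups)
  groups <- as.character(groups)
  names(groups) <- nm
  bad <- setdiff(unique(groups), c("tumor", "normal", "cellline"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  missing <- setdiff(sample_ids, nm)
  if (length(missing))
    stop("sample(s) without a group label: ", paste(missing, collapse = ", "))
  groups[sample_ids]
}

#' @export
print.scn_expr <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("Groups:", paste(names(table(x$groups)), table(x$groups),
                       sep = "=", collapse = ", "), "\n")
  cat("Missing entries:", sum(is.na(x$values)), "\n")
  invisible(x)
}

#' @export
print.scn_probes <- function(x, ...) {
  cat("Probe matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples\n")
  n_mapped <- if (is.null(x$probe_to_gene)) 0L
              else sum(!is.na(x$probe_to_gene))
  cat("Mapped probes:", n_mapped, " Missing entries:",
      sum(is.na(x$values)), "\n")
  invisible(x)
}

# columns of an scn_expr belonging to one group
group_columns <- function(m, group) {
  which(m$groups == group)
}

#' Protein-protein interaction edge list
#'
#' Undirected, deduplicated, self-loop-free edge list with STRING-style
#' integer confidence scores.  Pairs are stored canonically with
#' `gene_a < gene_b` (lexicographic).
#'
#' @param gene_a,gene_b character vectors of interacting gene symbols.
#' @param score numeric vector of non-negative confidence scores
#'   (STRING convention 0-1000).
#' @return A data frame of class `scn_ppi` with columns `gene_a`, `gene_b`,
#'   `score`.
#' @export
scn_ppi <- function(gene_a, gene_b, score) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  score <- as.numeric(score)
  if (length(gene_a) != length(gene_b) || length(gene_a) != length(score))
    stop("gene_a, gene_b and score must have equal length")
  if (any(score < 0)) stop("negative PPI confidence score")
  keep <- gene_a != gene_b
  gene_a <- gene_a[keep]; gene_b <- gene_b[keep]; score <- score[keep]
  swap <- gene_a > gene_b
  tmp <- gene_a[swap]; gene_a[swap] <- gene_b[swap]; gene_b[swap] <- tmp
  key <- paste(gene_a, gene_b, sep = "\r")
  first <- !duplicated(key)
  df <- data.frame(gene_a = gene_a[first], gene_b = gene_b[first],
                   score = score[first], stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("scn_ppi", "data.frame")
  df
}

#' Integrated context-specific network
#'
#' A PPI-restricted weighted graph: node weights carry the biological context
#' (log2 fold change for tumor tissue, CRISPR essentiality for cell lines)
#' and edge weights are Pearson correlations from the matching expression
#' samples.
#'
#' @param nodes character vector of gene symbols.
#' @param node_weight named numeric vector over `nodes`.
#' @param edges data frame with columns `gene_a`, `gene_b`, `weight`
#'   (correlations in `[-1, 1]`); endpoints must be nodes.
#' @param context `"tissue"` or `"cellline"`.
#' @return An object of class `scn_network`.
#' @export
scn_network <- function(nodes, node_weight, edges, context) {
  context <- match.arg(context, c("tissue", "cellline"))
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate nodes")
  if (!all(nodes %in% names(node_weight)))
    stop("every node needs a node weight")
  node_weight <- node_weight[nodes]
  if (nrow(edges)) {
    if (!all(c(edges$gene_a, edges$gene_b) %in% nodes))
      stop("edge endpoint not in node set")
    if (any(edges$gene_a == edges$gene_b)) stop("self-loop in edge set")
    if (any(abs(edges$weight) > 1 + 1e-8))
      stop("edge weight outside [-1, 1]")
  }
  if (context == "tissue" && length(node_weight) && any(node_weight <= 0))
    stop("tissue network requires strictly positive node weights ",
         "(over-expressed genes only)")
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, node_weight = node_weight, edges = edges,
                 context = context),
            class = "scn_network")
}

#' @export
print.scn_network <- function(x, ...) {
  cat(sprintf("Integrated %s network: %d nodes, %d edges\n",
              x$context, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# canonical edge key used by several modules
edge_key <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  paste(a, b, sep = "\r")
}
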
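#' Drop probes with too many missing values
#'
#' A probe whose missing fraction exceeds `max_missing_frac` is removed;
#' exactly the threshold is kept (the rule is "more than", strict). Row
#' order of the survivors is preserved.
#'
#' @param m an [scn_probes()] matrix.
#' @param max_missing_frac maximum tolerated fraction of missing samples
#'   per probe, default 0.20.
#' @return The filtered `scn_probes`.
#' @export
filter_probes <- function(m, max_missing_frac = 0.20) {
  stopifnot(inherits(m, "scn_probes"),
            max_missing_frac >= 0, max_missing_frac <= 1)
  frac <- rowMeans(is.na(m$values))
  keep <- frac <= max_missing_frac
  scn_probes(m$values[keep, , drop = FALSE], m$groups, m$probe_to_gene)
}

#' K-nearest-neighbour imputation of missing expression values
#'
#' For each probe with missing cells, neighbours are the other probes ranked
#' by Euclidean distance computed over the columns where both probes are
#' observed and scaled by the fraction of shared observed columns (standard
#' KNN-impute behaviour).  A missing cell is replaced by the mean of the `k`
#' nearest neighbours observed in that column; observed cells are never
#' touched.  When fewer than `k` usable neighbours exist, all of them are
#' used with a warning.
#'
#' @param m an [scn_probes()] matrix (typically after [filter_probes()]).
#' @param k number of neighbours, default 10.
#' @return The `scn_probes` with no missing entries.
#' @export
knn_impute <- function(m, k = 10) {
  stopifnot(inherits(m, "scn_probes"), k >= 1)
  x <- m$values
  miss <- is.na(x)
  if (!any(miss)) return(m)
  all_missing <- rowSums(!miss) == 0
  if (any(all_missing))
    stop("cannot impute: probe(s) with every value missing: ",
         paste(rownames(x)[all_missing], collapse = ", "))
  obs <- !miss
  clamped <- FALSE
  for (i in which(rowSums(miss) > 0)) {
    xi <- x[i, ]
    # scaled pairwise-complete squared Euclidean distance to every other row
    shared <- obs %*% obs[i, ]                       # shared observed counts
    diffs <- sweep(x, 2, xi)
    diffs[!obs | !rep(obs[i, ], each = nrow(x))] <- 0
    d2 <- rowSums(diffs^2, na.rm = TRUE) / pmax(shared[, 1], 1)
    d2[shared[, 1] == 0] <- Inf
    d2[i] <- Inf
    for (j in which(miss[i, ])) {
      cand <- which(obs[, j] & is.finite(d2))
      if (!length(cand))
        stop("cannot impute cell (", rownames(x)[i], ", ",
             colnames(x)[j], "): no neighbour observed in that column")
      if (length(cand) < k) clamped <- TRUE
      kk <- min(k, length(cand))
      nn <- cand[order(d2[cand])][seq_len(kk)]
      x[i, j] <- mean(x[nn, j])
    }
  }
  if (clamped)
    warning("fewer than k usable neighbours for some cells; ",
            "k clamped to the available neighbours")
  scn_probes(x, m$groups, m$probe_to_gene)
}

#' Collapse probe-level values to gene level
#'
#' Probes mapping to the same gene are averaged (arithmetic mean per
#' sample); probes without a gene mapping are dropped, with the count
#' reported via a message.
#'
#' @param m an imputed [scn_probes()] matrix with a probe-to-gene map.
#' @return A gene-level [scn_expr()].
#' @export
collapse_probes <- function(m) {
  stopifnot(inherits(m, "scn_probes"))
  if (is.null(m$probe_to_gene))
    stop("collapse_probes needs a probe_to_gene map")
  genes <- m$probe_to_gene[rownames(m$values)]
  unmapped <- is.na(genes)
  if (any(unmapped))
    message(sum(unmapped), " unmapped probe(s) dropped")
  v <- m$values[!unmapped, , drop = FALSE]
  genes <- genes[!unmapped]
  if (!nrow(v)) stop("no mapped probes left to collapse")
  collapsed <- rowsum(v, group = genes, reorder = TRUE) /
    as.vector(table(genes)[sort(unique(genes))])
  scn_expr(collapsed, m$groups)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column onto the same empirical distribution (the
#' row-wise mean of the per-column sorted vectors), the standard remedy for
#' microarray batch effects; ties share the mean of their quantile values.
#' Delegates to [limma::normalizeQuantiles()].
#'
#' @param m an [scn_expr()] with no missing entries.
#' @return The normalized `scn_expr`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "scn_expr"))
  if (anyNA(m$values))
    stop("quantile_normalize requires a complete matrix (impute first)")
  if (ncol(m$values) < 2) return(m)
  v <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(v) <- dimnames(m$values)
  scn_expr(v, m$groups)
}

#' Log2-transform an expression matrix
#'
#' Elementwise `log2(value + offset)`; the default offset of 1 suits raw
#' intensities.  Any non-positive argument aborts, naming the offending
#' cell.
#'
#' @param m an [scn_expr()].
#' @param offset additive offset before the log, default 1.
#' @return The transformed `scn_expr`.
#' @export
log2_transform <- function(m, offset = 1) {
  stopifnot(inherits(m, "scn_expr"))
  shifted <- m$values + offset
  bad <- which(shifted <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("log2 undefined for gene ", rownames(m$values)[bad[1, 1]],
         ", sample ", colnames(m$values)[bad[1, 2]],
         " (value + offset <= 0)")
  scn_expr(log2(shifted), m$groups)
}

#' Aggregate sgRNA fold changes to gene-level essentiality
#'
#' CRISPR essentiality is summarized in two steps: per (gene, cell line)
#' the mean over that gene's sgRNAs, then per gene the mean over the cell
#' lines in which it was screened (a mean of per-cell-line means, not a
#' pooled sgRNA mean).  Negative values mean knockout reduces survival.
#'
#' @param t an sgRNA table from [read_sgrna()] (columns `sgrna`, `gene`,
#'   `cellline`, `fold_change`).
#' @return An object of class `scn_essentiality`: list with `essentiality`
#'   (named numeric, gene -> mean fold change) and `per_cellline`
#'   (data frame gene / cellline / fold_change).
#' @export
essentiality_from_sgrna <- function(t) {
  need <- c("sgrna", "gene", "cellline", "fold_change")
  stopifnot(is.data.frame(t), all(need %in% names(t)), nrow(t) > 0)
  per_cl <- stats::aggregate(fold_change ~ gene + cellline, data = t,
                             FUN = mean)
  ess <- stats::aggregate(fold_change ~ gene, data = per_cl, FUN = mean)
  ess <- ess[order(ess$gene), ]
  per_cl <- per_cl[order(per_cl$gene, per_cl$cellline), ]
  rownames(per_cl) <- NULL
  structure(list(essentiality = stats::setNames(ess$fold_change, ess$gene),
                 per_cellline = per_cl),
            class = "scn_essentiality")
}

#' @export
print.scn_essentiality <- function(x, ...) {
  cat("Gene essentiality:", length(x$essentiality), "genes over",
      length(unique(x$per_cellline$cellline)), "cell line(s)\n")
  invisible(x)
}

#' Run the full probe-level preprocessing chain
#'
#' Convenience wrapper: [filter_probes()] then [knn_impute()] then
#' [collapse_probes()] then [quantile_normalize()], optionally followed by
#' [log2_transform()] for raw-intensity input.
#'
#' @param m an [scn_probes()] matrix.
#' @param max_missing_frac,k see the individual steps.
#' @param log2_offset `NULL` (input already log2) or the offset to use.
#' @return A normalized gene-level [scn_expr()].
#' @export
preprocess_probes <- function(m, max_missing_frac = 0.20, k = 10,
                              log2_offset = NULL) {
  m <- filter_probes(m, max_missing_frac)
  m <- knn_impute(m, k)
  g <- collapse_probes(m)
  if (!is.null(log2_offset)) g <- log2_transform(g, log2_offset)
  quantile_normalize(g)
}
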
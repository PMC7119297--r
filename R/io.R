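#' Read an expression matrix with group labels
#'
#' Parses a tab-separated expression table (header row of sample ids, first
#' column of gene or probe ids) together with a two-column label file mapping
#' each sample to tumor / normal / cellline.  `"NA"` and empty cells both
#' parse as missing, covering the common microarray export dialects.
#'
#' @param path path to the expression TSV.
#' @param label_path path to a two-column TSV (sample, group), header
#'   optional.
#' @param probe_map optional path to a two-column TSV (probe, gene); when
#'   given the result is a probe-level [scn_probes()] carrying the map,
#'   otherwise a gene-level [scn_expr()].
#' @return An `scn_expr` (or `scn_probes` when `probe_map` is supplied).
#' @export
read_expression <- function(path, label_path, probe_map = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty expression file: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop("format error: duplicate sample id in ", path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  vals <- lapply(fields, function(f) {
    f <- f[-1]
    length(f) <- length(sample_ids)       # ragged short rows -> NA-filled
    f[f == "" | f == "NA" | is.na(f)] <- NA_character_
    v <- suppressWarnings(as.numeric(f))
    bad <- !is.na(f) & is.na(v)
    if (any(bad))
      stop("parse error: non-numeric cell '", f[which(bad)[1]], "' in ", path)
    v
  })
  values <- do.call(rbind, vals)
  dimnames(values) <- list(ids, sample_ids)

  lab <- utils::read.table(label_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("sample", "group"))
  if (identical(tolower(lab$sample[1]), "sample")) lab <- lab[-1, ]
  groups <- stats::setNames(lab$group, lab$sample)
  if (!all(sample_ids %in% names(groups)))
    stop("label error: sample(s) without label: ",
         paste(setdiff(sample_ids, names(groups)), collapse = ", "))

  if (is.null(probe_map)) return(scn_expr(values, groups))
  pm <- utils::read.table(probe_map, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("probe", "gene"))
  scn_probes(values, groups,
             probe_to_gene = stats::setNames(pm$gene, pm$probe))
}

#' Read a STRING-style protein-links file
#'
#' Accepts the STRING protein-links dialect: whitespace-separated columns
#' `protein1 protein2 combined_score`, with or without a header line.
#' Edges are undirected; duplicates (in either orientation) and self-loops
#' are dropped, and edges below `min_score` are removed.
#'
#' @param path path to the protein-links file.
#' @param min_score minimum combined score to retain an edge (default 0:
#'   keep everything).
#' @return An [scn_ppi()] edge list.
#' @export
read_ppi <- function(path, min_score = 0) {
  stopifnot(min_score >= 0)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(scn_ppi(character(), character(), numeric()))
  fields <- strsplit(trimws(lines), "[ \t]+")
  if (suppressWarnings(is.na(as.numeric(fields[[1]][3]))))
    fields <- fields[-1]                     # header line
  if (!length(fields)) return(scn_ppi(character(), character(), numeric()))
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  s <- as.numeric(vapply(fields, `[[`, character(1), 3L))
  if (anyNA(s)) stop("parse error: non-numeric combined_score in ", path)
  ppi <- scn_ppi(a, b, s)
  ppi[ppi$score >= min_score, , drop = FALSE]
}

#' Read an sgRNA-level CRISPR fold-change table
#'
#' @param path TSV with columns `sgrna`, `gene`, `cellline`, `fold_change`
#'   (header required).
#' @return A data frame with those four columns, validated: fold changes
#'   finite, `(sgrna, cellline)` pairs unique.  An empty (header-only) file
#'   yields an empty table with a warning.
#' @export
read_sgrna <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sgrna", "gene", "cellline", "fold_change")
  if (!all(need %in% names(df)))
    stop("sgRNA table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (!nrow(df)) {
    warning("empty sgRNA table: ", path)
    return(df)
  }
  df$fold_change <- as.numeric(df$fold_change)
  if (any(!is.finite(df$fold_change)))
    stop("parse error: non-finite fold change in ", path)
  if (anyDuplicated(paste(df$sgrna, df$cellline, sep = "\r")))
    stop("duplicate (sgrna, cellline) pair in ", path)
  df
}

#' Read a plain gene list
#'
#' One gene symbol per line; blank lines ignored.  Used for drug-target
#' lists.
#'
#' @param path path to the list file.
#' @return Character vector of unique symbols, input order preserved.
#' @export
read_gene_list <- function(path) {
  genes <- trimws(readLines(path))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("empty gene list: ", path)
  unique(genes)
}

#' Write / read a cluster assignment
#'
#' Clusters are stored as a two-column TSV (gene, cluster); writing then
#' reading returns an identical assignment.
#'
#' @param assignment named integer vector (gene -> cluster id), e.g. the
#'   `assignment` element of [spectral_cluster()].
#' @param path output path.
#' @return `write_clusters` returns `path` invisibly; `read_clusters`
#'   returns the named integer vector.
#' @export
write_clusters <- function(assignment, path) {
  if (!length(assignment)) stop("empty cluster assignment")
  df <- data.frame(gene = names(assignment),
                   cluster = as.integer(assignment))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$cluster), df$gene)
}

#' Write / read a ranked drug-target table
#'
#' Rankings are stored as a TSV with columns gene, cluster, TI, abs_TI,
#' reachable, rank; rows ordered by rank.
#'
#' @param table an `scn_ranking` data frame from [rank_targets()].
#' @param path output path.
#' @return `write_ranked_targets` returns `path` invisibly;
#'   `read_ranked_targets` returns the data frame.
#' @export
write_ranked_targets <- function(table, path) {
  if (!nrow(table)) stop("empty ranked-target table")
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_targets
#' @export
read_ranked_targets <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write an expression matrix (with labels) to TSV
#'
#' Inverse of [read_expression()]: the matrix goes to `path` and, when
#' `label_path` is given, the group labels go to a two-column TSV.
#'
#' @param m an `scn_expr` or `scn_probes`.
#' @param path output TSV for the matrix.
#' @param label_path optional output TSV for the labels.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, label_path = NULL) {
  df <- data.frame(id = rownames(m$values), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(label_path))
    utils::write.table(data.frame(sample = names(m$groups),
                                  group = unname(m$groups)),
                       label_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
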
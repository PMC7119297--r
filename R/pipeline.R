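#' Run the full file-based pipeline from a configuration
#'
#' Orchestrates the whole analysis from files on disk: reads every input,
#' preprocesses probe-level matrices when a probe map is configured, runs
#' [scnrank()], writes each stage's TSV outputs into `out_dir` and a JSON
#' run manifest (parameter values, seed, stage counts, input checksums)
#' that fully determines the run.
#'
#' @param config either a path to a YAML file or a named list.  Recognized
#'   entries: `tissue_expr`, `tissue_labels`, `cellline_expr`,
#'   `cellline_labels`, `ppi`, `sgrna`, `targets` (all paths, required);
#'   `probe_map` (optional path); `out_dir` (required); and the tunables
#'   `alpha` (0.05), `test` ("welch"), `min_ppi_score` (0),
#'   `max_missing_frac` (0.2), `knn_k` (10), `log2_offset` (NULL =
#'   already log2), `k` ("auto"), `m`, `k_max`, `hartigan_threshold` (10),
#'   `path_mode` ("logprod"), `seed` (1).  Defaults follow the method's
#'   stated constants.
#' @return The `scnrank` fit, invisibly, with the manifest attached as
#'   attribute `"manifest"`.
#' @export
scn_run <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("tissue_expr", "tissue_labels", "cellline_expr",
            "cellline_labels", "ppi", "sgrna", "targets", "out_dir")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("configuration error: missing entries: ",
         paste(missing, collapse = ", "))
  inputs <- unlist(config[c("tissue_expr", "tissue_labels",
                            "cellline_expr", "cellline_labels", "ppi",
                            "sgrna", "targets")])
  if (!is.null(config$probe_map)) inputs <- c(inputs,
                                              probe_map = config$probe_map)
  unreadable <- inputs[!file.exists(inputs)]
  if (length(unreadable))
    stop("input error: file(s) not found: ",
         paste(unreadable, collapse = ", "))
  cfg <- function(key, default) if (is.null(config[[key]])) default
                                else config[[key]]
  seed <- cfg("seed", 1L)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tissue <- stage("read_expression", read_expression(
    config$tissue_expr, config$tissue_labels, config$probe_map))
  cellline <- stage("read_expression", read_expression(
    config$cellline_expr, config$cellline_labels, config$probe_map))
  ppi <- stage("read_ppi", read_ppi(config$ppi,
                                    min_score = cfg("min_ppi_score", 0)))
  sgrna <- stage("read_sgrna", read_sgrna(config$sgrna))
  targets <- stage("read_targets", read_gene_list(config$targets))

  if (inherits(tissue, "scn_probes")) {
    tissue <- stage("preprocess", preprocess_probes(
      tissue, cfg("max_missing_frac", 0.2), cfg("knn_k", 10),
      cfg("log2_offset", NULL)))
    cellline <- stage("preprocess", preprocess_probes(
      cellline, cfg("max_missing_frac", 0.2), cfg("knn_k", 10),
      cfg("log2_offset", NULL)))
  }
  ess <- stage("essentiality", essentiality_from_sgrna(sgrna))
  fit <- stage("scnrank", scnrank(
    tissue, cellline, ppi, ess, targets,
    alpha = cfg("alpha", 0.05), variant = cfg("test", "welch"),
    k = cfg("k", "auto"), m = config$m, k_max = config$k_max,
    hartigan_threshold = cfg("hartigan_threshold", 10),
    path_mode = cfg("path_mode", "logprod"), seed = seed))

  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fit$diff, file.path(out, "diffexpr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fit$tissue_network$edges,
                     file.path(out, "tissue_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fit$cellline_network$edges,
                     file.path(out, "cellline_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_clusters(fit$clusters$assignment, file.path(out, "clusters.tsv"))
  write_ranked_targets(fit$ranking, file.path(out, "ranked_targets.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("scnrank")),
    seed = seed,
    parameters = fit$params,
    counts = as.list(fit$counts),
    inputs = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(fit, "manifest") <- manifest
  invisible(fit)
}
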
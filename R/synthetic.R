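#' Specification of a synthetic drug-target study
#'
#' Collects every knob of the synthetic-data generator.  The defaults
#' describe the desk-scale study the package's recovery experiments use:
#' 200 genes of which 4 planted co-expression blocks of 12 genes (24% of
#' the transcriptome, the proportion typical of tumor-vs-normal
#' comparisons) are over-expressed and 28 background genes (14%) are
#' under-expressed in tumors; 40 tumor / 40 normal / 40 cell-line samples;
#' a log2 effect size of 2 (the scale of top dysregulated genes on tumor
#' microarrays); a within-block correlation of 0.6 (typical of tight
#' co-expression modules); and one strongly essential hub target per block
#' (essentiality -2, the scale of top CRISPR dependencies) against a mild
#' essentiality background.
#'
#' @param n_genes total gene count (blocks + unstructured background).
#' @param block_sizes integer vector, one planted block per entry;
#'   `sum(block_sizes) <= n_genes`.
#' @param n_tumor,n_normal,n_cellline sample counts per group.
#' @param effect_size mean log2 over-expression of block genes in tumors.
#' @param n_under number of background genes under-expressed in tumors by
#'   `effect_size` (tumor transcriptomes carry both directions of
#'   dysregulation; keeping both makes the quantile-normalization
#'   assumption of broadly comparable distributions realistic).
#' @param intra_block_r target expected pairwise correlation within a
#'   block (sets the one-factor loading).
#' @param noise_sd residual gene-level noise SD (log2 units).
#' @param inter_block_edge_prob probability of a noise PPI edge between
#'   genes of different blocks.
#' @param hub_essentiality essentiality planted on each block's hub gene.
#' @param background_essentiality_mean,background_essentiality_sd normal
#'   background for all other genes' essentiality.
#' @param sgrna_noise_sd SD of sgRNA-level noise around gene essentiality.
#' @param sgrnas_per_gene sgRNAs per gene per cell line.
#' @param n_screen_celllines cell lines in the CRISPR screen.
#' @param decoys_per_block extra (non-hub) drug targets listed per block.
#' @param missing_frac fraction of probe-level cells masked as missing.
#' @param base_mean baseline log2 expression level.
#' @param seed default integer seed for [scn_simulate()].
#' @return A list of class `scn_sim_spec`.
#' @export
scn_sim_spec <- function(n_genes = 200,
                         block_sizes = rep(12L, 4),
                         n_tumor = 40, n_normal = 40, n_cellline = 40,
                         effect_size = 2.0,
                         n_under = 28,
                         intra_block_r = 0.6,
                         noise_sd = 1.0,
                         inter_block_edge_prob = 0.02,
                         hub_essentiality = -2.0,
                         background_essentiality_mean = -0.2,
                         background_essentiality_sd = 0.3,
                         sgrna_noise_sd = 0.3,
                         sgrnas_per_gene = 4,
                         n_screen_celllines = 3,
                         decoys_per_block = 2,
                         missing_frac = 0.05,
                         base_mean = 8,
                         seed = 1) {
  spec <- as.list(environment())
  if (sum(spec$block_sizes) > n_genes)
    stop("infeasible spec: blocks larger than the gene count")
  if (n_under > n_genes - sum(spec$block_sizes))
    stop("infeasible spec: more under-expressed genes than background")
  stopifnot(intra_block_r >= 0, intra_block_r < 1,
            missing_frac >= 0, missing_frac < 1,
            inter_block_edge_prob >= 0, inter_block_edge_prob <= 1,
            all(spec$block_sizes >= 1) || length(spec$block_sizes) == 0)
  class(spec) <- "scn_sim_spec"
  spec
}

# one-factor-per-block Gaussian sampler: value = mu + loading * factor +
# noise, giving expected within-block correlation loading^2 /
# (loading^2 + noise_sd^2)
simulate_context <- function(spec, n_samples, blocks, shift) {
  loading <- spec$noise_sd *
    sqrt(spec$intra_block_r / (1 - spec$intra_block_r))
  n <- spec$n_genes
  x <- matrix(stats::rnorm(n * n_samples, sd = spec$noise_sd),
              nrow = n)
  for (b in unique(blocks[blocks > 0])) {
    f <- stats::rnorm(n_samples)
    rows <- which(blocks == b)
    x[rows, ] <- x[rows, ] + loading * rep(f, each = length(rows))
  }
  x + spec$base_mean + shift
}

#' Generate a complete synthetic study with ground truth
#'
#' Produces every input the pipeline consumes — probe-level tumor+normal
#' and cell-line expression (with missing cells and a probe-to-gene map),
#' a PPI edge list whose within-block pairs are fully connected at high
#' confidence with sparse cross-block noise edges, an sgRNA fold-change
#' table, and a drug-target list containing each block's essential hub
#' plus decoy targets — together with the planted ground truth.
#'
#' Expression follows a one-factor-per-block Gaussian model (see
#' [scn_sim_spec()]); tumor and cell-line samples carry the same block
#' factor structure, normal samples lack the over-expression shift.  Three
#' designated genes are measured by two probes each so the probe-collapse
#' step is exercised.
#'
#' @param spec an [scn_sim_spec()].
#' @param seed integer seed; defaults to `spec$seed`.  Fixes everything.
#' @return List with elements `tissue` and `cellline` ([scn_probes()]),
#'   `gene_tissue` and `gene_cellline` (the clean gene-level
#'   [scn_expr()] matrices before probe masking), `ppi`, `sgrna`,
#'   `targets`, and `truth` (list: `blocks` named integer vector with 0 =
#'   background, `overexpressed`, `hubs`, `hub_order` by planted
#'   essentiality magnitude, `essentiality` named numeric).
#' @export
scn_simulate <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scn_sim_spec"))
  set.seed(seed)
  n <- spec$n_genes
  n_blocks <- length(spec$block_sizes)
  blocks <- integer(n)
  pos <- 1L
  for (b in seq_len(n_blocks)) {
    blocks[pos:(pos + spec$block_sizes[b] - 1L)] <- b
    pos <- pos + spec$block_sizes[b]
  }
  genes <- sprintf("G%03d", seq_len(n))
  names(blocks) <- genes
  shift <- ifelse(blocks > 0, spec$effect_size, 0)
  under <- character(0)
  if (spec$n_under > 0) {
    under <- genes[blocks == 0][seq_len(spec$n_under)]
    shift[match(under, genes)] <- -spec$effect_size
  }

  tumor <- simulate_context(spec, spec$n_tumor, blocks, shift)
  normal <- simulate_context(spec, spec$n_normal, blocks, 0)
  cellline <- simulate_context(spec, spec$n_cellline, blocks, shift)
  tissue_vals <- cbind(tumor, normal)
  rownames(tissue_vals) <- genes
  colnames(tissue_vals) <- c(sprintf("T%02d", seq_len(spec$n_tumor)),
                             sprintf("N%02d", seq_len(spec$n_normal)))
  tissue_groups <- stats::setNames(
    rep(c("tumor", "normal"), c(spec$n_tumor, spec$n_normal)),
    colnames(tissue_vals))
  rownames(cellline) <- genes
  colnames(cellline) <- sprintf("C%02d", seq_len(spec$n_cellline))
  cl_groups <- stats::setNames(rep("cellline", spec$n_cellline),
                               colnames(cellline))
  gene_tissue <- scn_expr(tissue_vals, tissue_groups)
  gene_cellline <- scn_expr(cellline, cl_groups)

  # probe layer: one probe per gene, plus duplicate probes for 3 genes
  dup_genes <- genes[seq_len(min(3L, n))]
  make_probes <- function(gvals) {
    pv <- gvals
    rownames(pv) <- paste0("P_", genes, "_1")
    extra <- gvals[dup_genes, , drop = FALSE] +
      stats::rnorm(length(dup_genes) * ncol(gvals), sd = 0.1)
    rownames(extra) <- paste0("P_", dup_genes, "_2")
    pv <- rbind(pv, extra)
    if (spec$missing_frac > 0) {
      mask <- stats::runif(length(pv)) < spec$missing_frac
      pv[mask] <- NA
    }
    pv
  }
  probe_map <- stats::setNames(c(genes, dup_genes),
                               c(paste0("P_", genes, "_1"),
                                 paste0("P_", dup_genes, "_2")))
  tissue <- scn_probes(make_probes(tissue_vals), tissue_groups, probe_map)
  cellline_p <- scn_probes(make_probes(cellline), cl_groups, probe_map)

  # PPI skeleton: complete within blocks (high confidence), sparse noise
  # edges across blocks
  ea <- character(0); eb <- character(0); sc <- numeric(0)
  for (b in seq_len(n_blocks)) {
    members <- genes[blocks == b]
    if (length(members) >= 2) {
      prs <- utils::combn(members, 2)
      ea <- c(ea, prs[1, ]); eb <- c(eb, prs[2, ])
      sc <- c(sc, rep(900, ncol(prs)))
    }
  }
  block_genes <- genes[blocks > 0]
  if (n_blocks >= 2 && spec$inter_block_edge_prob > 0) {
    prs <- utils::combn(block_genes, 2)
    cross <- blocks[prs[1, ]] != blocks[prs[2, ]]
    pick <- cross & (stats::runif(ncol(prs)) < spec$inter_block_edge_prob)
    ea <- c(ea, prs[1, pick]); eb <- c(eb, prs[2, pick])
    sc <- c(sc, rep(400, sum(pick)))
  }
  ppi <- scn_ppi(ea, eb, sc)

  # essentiality: hubs strongly negative, everything else background
  ess <- stats::rnorm(n, spec$background_essentiality_mean,
                      spec$background_essentiality_sd)
  names(ess) <- genes
  hubs <- if (n_blocks)
    vapply(seq_len(n_blocks), function(b) genes[blocks == b][1],
           character(1))
  else character(0)
  ess[hubs] <- spec$hub_essentiality
  cls <- sprintf("CL%02d", seq_len(spec$n_screen_celllines))
  grid <- expand.grid(g = seq_len(n), r = seq_len(spec$sgrnas_per_gene),
                      cl = seq_along(cls))
  sgrna <- data.frame(
    sgrna = sprintf("sg_%s_%d", genes[grid$g], grid$r),
    gene = genes[grid$g],
    cellline = cls[grid$cl],
    fold_change = ess[grid$g] +
      stats::rnorm(nrow(grid), sd = spec$sgrna_noise_sd),
    stringsAsFactors = FALSE)

  targets <- character(0)
  for (b in seq_len(n_blocks)) {
    members <- genes[blocks == b]
    targets <- c(targets, members[seq_len(min(1L + spec$decoys_per_block,
                                              length(members)))])
  }

  list(tissue = tissue, cellline = cellline_p,
       gene_tissue = gene_tissue, gene_cellline = gene_cellline,
       ppi = ppi, sgrna = sgrna, targets = targets,
       truth = list(blocks = blocks,
                    overexpressed = genes[blocks > 0],
                    underexpressed = under,
                    hubs = hubs,
                    hub_order = hubs,
                    essentiality = ess),
       spec = spec)
}

#' Write a simulated study to disk in the external file dialects
#'
#' Dumps every generated input (expression TSVs + label files + probe map,
#' STRING-style PPI links, sgRNA TSV, target list) into a directory so the
#' file-based pipeline entry points can be exercised end to end.
#'
#' @param sim result of [scn_simulate()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
scn_write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression(sim$tissue, p("tissue_expr.tsv"), p("tissue_labels.tsv"))
  write_expression(sim$cellline, p("cellline_expr.tsv"),
                   p("cellline_labels.tsv"))
  pm <- sim$tissue$probe_to_gene
  utils::write.table(data.frame(probe = names(pm), gene = unname(pm)),
                     p("probe_map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(protein1 = sim$ppi$gene_a,
                                protein2 = sim$ppi$gene_b,
                                combined_score = sim$ppi$score),
                     p("ppi_links.txt"), sep = " ", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$sgrna, p("sgrna.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sim$targets, p("targets.txt"))
  invisible(c(tissue_expr = p("tissue_expr.tsv"),
              tissue_labels = p("tissue_labels.tsv"),
              cellline_expr = p("cellline_expr.tsv"),
              cellline_labels = p("cellline_labels.tsv"),
              probe_map = p("probe_map.tsv"),
              ppi = p("ppi_links.txt"),
              sgrna = p("sgrna.tsv"),
              targets = p("targets.txt")))
}

#' Run the full pipeline on a simulated study and score recovery
#'
#' Preprocesses the probe-level matrices, runs [scnrank()], and compares
#' the result against the planted ground truth: the adjusted Rand index
#' between the spectral partition and the planted blocks (over the genes
#' that entered the network) and, per planted hub, whether it ranked first
#' (maximal |TI|) among the scored targets of its own cluster.
#'
#' @param spec an [scn_sim_spec()].
#' @param seed integer seed for both simulation and clustering.
#' @param ... passed on to [scnrank()] (e.g. `k`, `alpha`).
#' @return List with `ari`, `hub_first` (named logical per hub),
#'   `all_hubs_first`, `fit` (the `scnrank` object), `truth`.
#' @export
evaluate_recovery <- function(spec, seed = spec$seed, ...) {
  sim <- scn_simulate(spec, seed = seed)
  tissue <- preprocess_probes(sim$tissue)
  cellline <- preprocess_probes(sim$cellline)
  ess <- essentiality_from_sgrna(sim$sgrna)
  fit <- scnrank(tissue, cellline, sim$ppi, ess, sim$targets,
                 seed = seed, ...)
  genes_in <- names(fit$clusters$assignment)
  ari <- mclust::adjustedRandIndex(fit$clusters$assignment,
                                   sim$truth$blocks[genes_in])
  rk <- fit$ranking
  hub_first <- vapply(sim$truth$hubs, function(h) {
    if (!h %in% rk$gene) return(FALSE)
    cl <- rk$cluster[rk$gene == h]
    sub <- rk[rk$cluster == cl, ]
    identical(sub$gene[which.max(sub$abs_TI)], h)
  }, logical(1))
  list(ari = ari, hub_first = hub_first,
       all_hubs_first = all(hub_first), fit = fit, truth = sim$truth)
}
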
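#' Unpaired two-sample t-test
#'
#' Two-sided unpaired t-test between two sample vectors, Welch (default)
#' or Student pooled-variance.  The sign of the statistic follows
#' `mean(x) - mean(y)`.  Degenerate inputs follow fixed conventions: both
#' groups constant with equal means gives `t = 0, p = 1`; both constant
#' with different means gives an infinite statistic and `p = 0` (with a
#' warning in either case).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param variant `"welch"` or `"student"`.
#' @return List with elements `t_stat` and `p_value`.
#' @export
unpaired_ttest <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 samples")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    d <- mean(x) - mean(y)
    if (d == 0) {
      warning("zero variance in both groups with equal means; t = 0, p = 1")
      return(list(t_stat = 0, p_value = 1))
    }
    warning("zero variance in both groups; |t| = Inf, p = 0")
    return(list(t_stat = sign(d) * Inf, p_value = 0))
  }
  ht <- stats::t.test(x, y, var.equal = (variant == "student"))
  list(t_stat = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Select genes over-expressed in tumor versus normal tissue
#'
#' Runs a per-gene unpaired t-test of tumor against normal samples and
#' returns the genes with `p < alpha` and a strictly positive log2 fold
#' change (difference of group means on the log2 scale), the gene set that
#' seeds the tissue network.  No multiple-testing correction is applied by
#' default (a raw p-value cutoff is the intended behaviour); set
#' `adjust = "BH"` for Benjamini-Hochberg-adjusted selection.
#'
#' @param m an [scn_expr()] containing tumor and normal samples on the
#'   log2 scale.
#' @param alpha significance cutoff, default 0.05.
#' @param variant t-test variant, see [unpaired_ttest()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with one row per selected gene (ordered by gene id):
#'   columns `gene`, `mean_tumor`, `mean_normal`, `log_fc`, `t_stat`,
#'   `p_value`.  The full per-gene table (before selection) is attached as
#'   attribute `"all_genes"`.
#' @export
select_overexpressed <- function(m, alpha = 0.05,
                                 variant = c("welch", "student"),
                                 adjust = c("none", "BH")) {
  variant <- match.arg(variant)
  adjust <- match.arg(adjust)
  stopifnot(inherits(m, "scn_expr"), alpha > 0, alpha < 1)
  ti <- group_columns(m, "tumor")
  ni <- group_columns(m, "normal")
  if (length(ti) < 2 || length(ni) < 2)
    stop("need at least 2 tumor and 2 normal samples")
  xt <- m$values[, ti, drop = FALSE]
  xn <- m$values[, ni, drop = FALSE]
  res <- vapply(seq_len(nrow(xt)), function(i) {
    tt <- suppressWarnings(unpaired_ttest(xt[i, ], xn[i, ], variant))
    c(mean(xt[i, ]), mean(xn[i, ]), tt$t_stat, tt$p_value)
  }, numeric(4))
  out <- data.frame(gene = rownames(m$values),
                    mean_tumor = res[1, ],
                    mean_normal = res[2, ],
                    log_fc = res[1, ] - res[2, ],
                    t_stat = res[3, ],
                    p_value = res[4, ],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), ]
  rownames(out) <- NULL
  p_sel <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH")
           else out$p_value
  sel <- out[p_sel < alpha & out$log_fc > 0, , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "all_genes") <- out
  sel
}
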
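#' Build the fold-change-weighted spectral matrices
#'
#' From an integrated tissue network this assembles the matrices of the
#' modified spectral-clustering scheme: the affinity matrix `S_prime`
#' (pairwise correlations on network edges, 0 elsewhere, unit diagonal),
#' the fold-change "degree" vector `D_prime` (node weights, replacing graph
#' degree as the global-influence term), the row-normalized influence
#' matrix `S_dprime` with entries `r_ab * FC_a / sum_k r_ak` (row sums
#' include the unit diagonal), the raw Laplacian `L_raw = diag(FC) -
#' S_dprime`, and the normalized Laplacian
#' `L_norm = diag(FC)^(-1/2) L_raw diag(FC)^(-1/2)`.
#'
#' In the limit where every edge correlation is 1 and each node weight
#' equals its affinity row sum, `S_dprime` reduces to the affinity matrix
#' and `L_raw` to the standard graph Laplacian, so the scheme is a strict
#' generalization of ordinary spectral clustering.
#'
#' With heterogeneous node weights `L_norm` is not exactly symmetric; the
#' maximum asymmetry is recorded in the `asymmetry` element and the
#' symmetrized matrix is what [eigendecompose()] consumes.
#'
#' @param net a tissue-context [scn_network()] (strictly positive node
#'   weights).
#' @param eps positive floor for near-zero affinity row sums (such rows of
#'   `S_dprime` are zeroed with a warning) and for node weights before the
#'   inverse square root.
#' @return An object of class `scn_spectral`: list with `genes`, `S_prime`,
#'   `D_prime`, `S_dprime`, `L_raw`, `L_norm`, `asymmetry`.
#' @export
build_matrices <- function(net, eps = 1e-8) {
  stopifnot(inherits(net, "scn_network"), eps > 0)
  if (any(net$node_weight <= 0))
    stop("spectral matrices need strictly positive node weights ",
         "(tissue context)")
  genes <- net$nodes
  n <- length(genes)
  S <- diag(1, n)
  dimnames(S) <- list(genes, genes)
  if (nrow(net$edges)) {
    ia <- match(net$edges$gene_a, genes)
    ib <- match(net$edges$gene_b, genes)
    S[cbind(ia, ib)] <- net$edges$weight
    S[cbind(ib, ia)] <- net$edges$weight
  }
  fc <- unname(net$node_weight)
  row_sums <- rowSums(S)
  Sdp <- S * (fc / row_sums)
  degenerate <- abs(row_sums) < eps
  if (any(degenerate)) {
    warning(sum(degenerate), " node(s) with near-zero affinity row sum; ",
            "influence row zeroed")
    Sdp[degenerate, ] <- 0
  }
  L_raw <- diag(fc, n) - Sdp
  inv_sqrt <- 1 / sqrt(pmax(fc, eps))
  L_norm <- inv_sqrt * L_raw * rep(inv_sqrt, each = n)
  dimnames(Sdp) <- dimnames(L_raw) <- dimnames(L_norm) <- dimnames(S)
  structure(list(genes = genes, S_prime = S,
                 D_prime = stats::setNames(fc, genes),
                 S_dprime = Sdp, L_raw = L_raw, L_norm = L_norm,
                 asymmetry = max(abs(L_norm - t(L_norm)))),
            class = "scn_spectral")
}

#' Eigendecompose the normalized Laplacian
#'
#' Eigenpairs of the symmetrized normalized Laplacian
#' `(L_norm + t(L_norm)) / 2`, which guarantees real eigenvalues, sorted
#' ascending (the `m` smallest define the spectral embedding in the
#' standard convention; `order = "largest"` is available for comparison).
#' Each eigenvector's sign is fixed by making its largest-magnitude entry
#' positive, so results are fully deterministic.
#'
#' @param mats an `scn_spectral` from [build_matrices()].
#' @param m number of eigenpairs to return, `1 <= m <= n`.
#' @param order `"smallest"` (default) or `"largest"` eigenvalues first.
#' @return List with `values` (length `m`) and `vectors` (`n x m`
#'   orthonormal matrix, rows named by gene).
#' @export
eigendecompose <- function(mats, m, order = c("smallest", "largest")) {
  order <- match.arg(order)
  stopifnot(inherits(mats, "scn_spectral"))
  n <- length(mats$genes)
  stopifnot(m >= 1, m <= n)
  sym <- (mats$L_norm + t(mats$L_norm)) / 2
  e <- eigen(sym, symmetric = TRUE)          # descending
  idx <- if (order == "smallest") rev(seq_len(n)) else seq_len(n)
  vals <- e$values[idx][seq_len(m)]
  vecs <- e$vectors[, idx, drop = FALSE][, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    piv <- which.max(abs(vecs[, j]))
    if (vecs[piv, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- mats$genes
  list(values = vals, vectors = vecs)
}

# best-of-restarts within-cluster sum of squares for k-means at a given k
kmeans_wss <- function(x, k, restarts) {
  n <- nrow(x)
  if (k == 1) return(sum(sweep(x, 2, colMeans(x))^2))
  n_distinct <- nrow(unique(x))
  if (n_distinct <= k) return(0)
  fit <- suppressWarnings(stats::kmeans(x, centers = k, nstart = restarts,
                                        iter.max = 100))
  fit$tot.withinss
}

#' Choose the number of clusters by Hartigan's rule
#'
#' For `k = 1 .. k_max`, k-means (best of `restarts` starts) yields the
#' within-cluster sum of squares `W_k`; Hartigan's number
#' `H(k) = (W_k / W_{k+1} - 1) * (n - k - 1)` compares consecutive fits and
#' values above the threshold (conventionally 10) justify `k + 1` clusters.
#' The selected K is the smallest `k` with `H(k) < threshold`; when no `k`
#' qualifies, `k_max` is returned with a warning.
#'
#' @param embedding numeric matrix of points (rows) to cluster, e.g. the
#'   spectral embedding.
#' @param k_max largest K considered (at most `n - 2`).
#' @param threshold Hartigan threshold, default 10.
#' @param restarts k-means restarts per k, default 10.
#' @param seed optional integer seed fixing the k-means initializations.
#' @return List with `K` (selected count) and `trace` (data frame with
#'   columns `k`, `wss`, `hartigan`).
#' @export
choose_k_hartigan <- function(embedding, k_max, threshold = 10,
                              restarts = 10, seed = NULL) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  stopifnot(k_max >= 1, k_max <= n - 2, threshold > 0)
  if (!is.null(seed)) set.seed(seed)
  wss <- vapply(seq_len(k_max + 1), function(k)
    kmeans_wss(embedding, k, restarts), numeric(1))
  # enforce monotone non-increasing W_k (k-means local-optimum noise):
  # a larger k can always reproduce a smaller k's partition
  wss <- cummin(wss)
  H <- vapply(seq_len(k_max), function(k) {
    if (wss[k + 1] == 0)
      return(if (wss[k] == 0) 0 else Inf)
    (wss[k] / wss[k + 1] - 1) * (n - k - 1)
  }, numeric(1))
  ok <- which(H < threshold)
  if (length(ok)) {
    K <- ok[1]
  } else {
    warning("Hartigan's number never dropped below ", threshold,
            "; returning k_max = ", k_max)
    K <- k_max
  }
  list(K = K,
       trace = data.frame(k = seq_len(k_max), wss = wss[seq_len(k_max)],
                          hartigan = H))
}

# k-means returning a non-empty-cluster assignment, with the standard
# farthest-point repair if a cluster comes back empty
kmeans_assign <- function(x, k, restarts) {
  n <- nrow(x)
  if (k == 1) return(rep(1L, n))
  ux <- unique(x)
  if (nrow(ux) <= k) {
    if (nrow(ux) < k)
      warning("only ", nrow(ux), " distinct embedding points; K reduced")
    key <- apply(x, 1, paste, collapse = "\r")
    return(as.integer(factor(key, levels = unique(key))))
  }
  fit <- suppressWarnings(stats::kmeans(x, centers = k, nstart = restarts,
                                        iter.max = 100))
  cl <- fit$cluster
  empty <- setdiff(seq_len(k), unique(cl))
  for (e in empty) {                        # defensive; H-W rarely yields these
    d <- rowSums((x - fit$centers[cl, , drop = FALSE])^2)
    far <- which.max(d)
    cl[far] <- e
    warning("empty cluster repaired by reassigning the farthest point")
  }
  as.integer(cl)
}

#' Spectral clustering of the tissue network
#'
#' Full Step-C pipeline: build the fold-change-weighted Laplacian,
#' eigendecompose, embed each gene in the `m` leading eigenvectors, and
#' k-means-cluster the embedding.  When `k = "auto"` the cluster count is
#' chosen by [choose_k_hartigan()] on a provisional `k_max`-dimensional
#' embedding, then the final clustering is run on a `K`-dimensional one
#' (the eigenvector count defaults to the cluster count).
#'
#' @param net a tissue-context [scn_network()].
#' @param m number of eigenvectors for the embedding; default `NULL` means
#'   `max(2, K)` capped at `n`.
#' @param k integer cluster count, or `"auto"` for Hartigan selection.
#' @param k_max cap for auto selection; default `min(n - 2, 15)`.
#' @param hartigan_threshold see [choose_k_hartigan()].
#' @param restarts k-means restarts, default 10.
#' @param seed integer seed making the clustering reproducible.
#' @param eigen_order passed to [eigendecompose()].
#' @param eps passed to [build_matrices()].
#' @return An object of class `scn_clusters`: list with `assignment`
#'   (named integer vector gene -> cluster, 1..K), `K`, `embedding`,
#'   `eigenvalues`, `hartigan` (trace or NULL), `asymmetry`, `seed`.
#' @export
spectral_cluster <- function(net, m = NULL, k = "auto", k_max = NULL,
                             hartigan_threshold = 10, restarts = 10,
                             seed = 1,
                             eigen_order = c("smallest", "largest"),
                             eps = 1e-8) {
  eigen_order <- match.arg(eigen_order)
  mats <- build_matrices(net, eps = eps)
  n <- length(mats$genes)
  hart <- NULL
  if (identical(k, "auto")) {
    if (n < 3) {
      k <- 1L
    } else {
      if (is.null(k_max)) k_max <- min(n - 2L, 15L)
      k_max <- min(k_max, n - 2L)
      e0 <- eigendecompose(mats, min(n, k_max + 1L), order = eigen_order)
      # sweep embedding capped at the spectral gap: eigenvectors past the
      # largest eigenvalue gap carry no partition structure, and their
      # unit-norm noise would push Hartigan's rule toward over-splitting
      gaps <- abs(diff(e0$values))[seq_len(min(k_max, length(e0$values) - 1))]
      sel_m <- max(1L, which.max(gaps))
      hart <- choose_k_hartigan(e0$vectors[, seq_len(sel_m), drop = FALSE],
                                k_max = k_max,
                                threshold = hartigan_threshold,
                                restarts = restarts, seed = seed)
      k <- hart$K
    }
  }
  k <- as.integer(k)
  stopifnot(k >= 1, k <= n)
  if (is.null(m)) m <- min(n, max(2L, k))
  e <- eigendecompose(mats, m, order = eigen_order)
  set.seed(seed)
  cl <- kmeans_assign(e$vectors, k, restarts)
  structure(list(assignment = stats::setNames(cl, mats$genes),
                 K = max(cl), embedding = e$vectors,
                 eigenvalues = e$values,
                 hartigan = if (is.null(hart)) NULL else hart$trace,
                 asymmetry = mats$asymmetry, seed = seed),
            class = "scn_clusters")
}

#' @export
print.scn_clusters <- function(x, ...) {
  cat("Spectral clustering:", length(x$assignment), "genes in", x$K,
      "clusters\n")
  cat("Cluster sizes:", paste(sort(table(x$assignment),
                                   decreasing = TRUE), collapse = ", "),
      "\n")
  invisible(x)
}
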
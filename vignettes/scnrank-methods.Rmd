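---
title: "Methods: paired-network spectral clustering and target-influence ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-network spectral clustering and target-influence ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genes that are strongly over-expressed in a tumor are not automatically good
drug targets: what matters is how hitting a gene propagates through the
co-expression structure of the tumor, and whether the genes it drags along are
ones the cancer cell actually depends on. `scnrank` formalizes this by
combining three kinds of evidence on a single graph skeleton:

* **tumor vs normal tissue expression**, which supplies the over-expressed
  gene set and per-gene log2 fold changes;
* **a protein–protein interaction (PPI) network**, which restricts
  co-expression edges to pairs with protein-level support and makes the two
  expression contexts comparable;
* **cell-line expression plus genome-wide CRISPR knockout screens**, which
  supply, for the same genes and edges, correlation structure in a
  perturbable system and a per-gene *essentiality* value (the knockout
  survival fold change, negative when loss of the gene impairs survival).

## The paired networks

Let the *tissue network* be the graph whose nodes are the genes selected as
over-expressed (unpaired t-test, two-sided `p < 0.05`, positive log2 fold
change) intersected with the PPI node set, whose edges are the PPI edges
between them, with edge weight `r_ab` = Pearson correlation over tumor
samples and node weight `FC_a` = log2 fold change (strictly positive by
construction). The *cell-line network* has the identical node and edge sets —
the shared skeleton is what makes cluster alignment across contexts
well-defined — but recomputes `r_ab` over cell-line samples and replaces node
weights with CRISPR essentiality. Genes without essentiality data keep the
skeleton with node weight 0 rather than being dropped.

## Fold-change-weighted spectral clustering

Standard normalized spectral clustering partitions a graph using the spectrum
of `L = D^{-1/2}(D - S)D^{-1/2}` where `S` is a binary affinity and `D` the
degree matrix. The variant implemented here replaces both ingredients with
weighted analogues: the affinity becomes the signed correlation matrix `S'`
(entries `r_ab` on network edges, 0 elsewhere, unit diagonal), and the degree
matrix becomes `D' = diag(FC_a)`, so a node's "global influence" is its fold
change rather than its edge count. To keep the Laplacian row sums at zero,
`S'` is row-normalized into `S''` with entries `r_ab · FC_a / Σ_k r_ak`
(the row sums include the unit diagonal), giving

```
L_raw  = D' − S''
L_norm = D'^{-1/2} · L_raw · D'^{-1/2}
```

In the limit `r_ab ∈ {0, 1}` and `FC_a = Σ_k S'_ak`, `S''` collapses to `S'`
and `L_raw` to the standard graph Laplacian `D − A`; the package's tests pin
this identity to `1e-10` and verify that clustering a union of two cliques
reproduces its connected components exactly. Negative correlations enter
signed, not as absolute values; rows whose correlation sum is within
`eps = 1e-8` of zero are zeroed with a warning, and `D'` entries are floored
at `eps` before the inverse square root.

With heterogeneous `FC`, `L_norm` is not exactly symmetric. Eigenpairs are
therefore taken from the symmetrized matrix `(L_norm + L_normᵀ)/2`, which
guarantees real eigenvalues and an orthonormal embedding; the maximum
asymmetry is recorded on the result object as a diagnostic. Eigenvectors are
sorted by eigenvalue ascending (the standard spectral-clustering convention;
`eigen_order = "largest"` is available for comparison) and sign-fixed by
making each vector's largest-magnitude entry positive, so the embedding is
fully deterministic.

## Choosing the number of clusters

K-means (k-means++-style restarts via `stats::kmeans`, best of 10, fixed
seed) clusters the `m`-dimensional embedding. When `k = "auto"`, the count is
chosen by Hartigan's rule: `H(k) = (W_k / W_{k+1} − 1)(n − k − 1)` from the
best-of-restarts within-cluster sums of squares, selecting the smallest `k`
with `H(k) < 10`. Two numerical choices matter here:

* `W_k` is forced non-increasing in `k` by a running minimum, since a larger
  `k` can always reproduce a smaller `k`'s partition and violations are pure
  k-means local-optimum noise;
* the sweep embedding is capped at the **spectral gap** — the dimension with
  the largest eigenvalue gap within `1..k_max`. Eigenvectors past the gap
  carry no partition structure, but each contributes a unit-norm noise
  dimension; left in, they both dilute `H` toward 1-cluster solutions on
  structured graphs and fuel over-splitting on tight embeddings. The gap
  proposes the dimension; Hartigan's rule then disposes the count.

The eigenvector count of the final embedding defaults to the selected `K`
(floored at 2). `K` and `m` remain independent knobs.

## Target Influence

Within the cluster containing a drug target `x` (influence is deliberately
confined to the target's own cluster), the *most-correlated path* from `x`
to a member `k` is the path maximizing the absolute product of edge
correlations; the signed product is retained so anti-correlated propagation
counts with its sign. Because `|r| ≤ 1`, the edge cost `−log|r|` is
non-negative and a Dijkstra search on these costs finds the maximum-|product|
path exactly; the package's tests verify exact agreement (magnitude and sign)
with exhaustive simple-path enumeration on hundreds of random graphs. Summing
the reciprocal `1/|r|` instead — a historical shortcut for "heaviest path"
searches — does not maximize the product under path-sum semantics; it is kept
behind `path_mode = "reciprocal"` for comparison only. Zero-weight edges are
non-traversable and removed before the search; the source contributes an
empty path with product 1.

The Target Influence score of `x` is then

```
TI(x) = Σ_{k reachable} W_k · max|∏ r| (signed)
```

with `W_k` the essentiality of `k` (0-weight genes still relay paths but add
nothing). Strong targets with negative essentiality neighborhoods get large
negative TI, so targets are ranked by `|TI|` descending (ties broken
lexicographically), with the signed TI always reported; per cluster, the
target with maximal `|TI|` is the cluster's representative. TI is linear in
the node weights and invariant to edits outside the cluster — both are
tested properties.

## Preprocessing

Probe-level matrices pass through: (1) a missingness filter — a probe with
*more than* 20% missing cells is dropped, exactly 20% is kept; (2) KNN
imputation with `k = 10` — neighbours are probes ranked by Euclidean distance
over shared observed columns scaled by the shared fraction, restricted to
neighbours observed in the target column, with `k` clamped (and warned) when
fewer are available; (3) probe→gene collapse by arithmetic mean, dropping
unmapped probes; (4) quantile normalization (via `limma::normalizeQuantiles`,
ties averaged), after the collapse — the order is configurable but
gene-level normalization is the default because it normalizes the quantities
actually analyzed; and (5) an optional `log2(x + offset)` transform for raw
intensities. sgRNA-level CRISPR fold changes are aggregated in two steps —
mean over a gene's sgRNAs within a cell line, then mean over cell lines —
rather than a pooled mean, so unevenly screened genes are not dominated by
heavily covered cell lines.

The t-test defaults to Welch's unequal-variance form because the tissue
groups are typically unbalanced; Student's pooled-variance variant is a
flag. No multiple-testing correction is applied by default (a raw `p < 0.05`
gate is the intended selection behaviour); Benjamini–Hochberg is available
via `adjust = "BH"`.

## What the synthetic generator emulates

`scn_sim_spec()` / `scn_simulate()` produce a complete study with known
truth. Expression follows a one-factor-per-block Gaussian model — gene `i`
in block `b` has value `μ + λ f_{b,s} + ε`, with the loading `λ` set from
the requested within-block correlation through the closed form
`r = λ²/(λ² + σ²)` — chosen over an explicit covariance matrix because it is
O(n) to sample and analytically checkable. The defaults are the package's
reference study: 200 genes, 4 blocks of 12 over-expressed genes (24% of the
transcriptome) plus 28 under-expressed background genes (14%), proportions
typical of tumor-vs-normal comparisons and deliberately minority so that
quantile normalization's distributional assumption holds; 40/40/40 samples;
log2 effect size 2; within-block correlation 0.6; a complete high-confidence
PPI within blocks with 2% cross-block noise edges; essentiality −2 for one
hub per block against a N(−0.2, 0.3²) background; 4 sgRNAs per gene over 3
cell lines with N(0, 0.3²) sgRNA noise; 5% missing cells. Tumor and
cell-line samples share the block-factor structure; normals lack the shift.
Three genes carry duplicate probes so the collapse step is exercised.

What it does **not** emulate: probe-intensity distributions of real arrays,
batch structure, correlated (non-factor) noise, dropout patterns that depend
on intensity, and PPI false-negative structure. Passing recovery tests on
this generator therefore demonstrates the algorithmic pipeline is correct
and well-conditioned, not that the method's biological conclusions transfer
to any particular dataset.

## Problem sizes and reproducibility

The recovery experiments run the full pipeline 20 times at the reference
study size (200 genes, 120 samples) and report the median adjusted Rand
index against the planted blocks and the fraction of runs in which every
planted hub ranks first in its cluster; the Dijkstra/enumeration equivalence
uses 200+ random graphs of up to 8 nodes, where exhaustive enumeration is
exact. All randomness — simulation, k-means restarts, graph sampling — is
seeded; identical inputs and seed give identical assignments, rankings and
manifests, and `scn_run()` writes the seed, parameters, stage counts and
input checksums into a JSON manifest.

## Known limitations

* Hartigan's rule with threshold 10 over-splits very tight, very
  well-separated embeddings (the `(n − k − 1)` factor grows while the
  within-SS ratio stays put); the spectral-gap cap mitigates but does not
  remove this, and on real networks K should be inspected via the returned
  trace.
* The row-normalization of `S''` divides by signed correlation sums; graphs
  with rows summing to ≈ 0 lose those rows' influence entries (warned).
* Maximum-|product| paths ignore path length entirely; two strongly
  correlated long paths can outrank a moderate direct edge, which is the
  intended semantics but can surprise on dense clusters.
* With `eigen_order = "largest"` the embedding is not the standard
  relaxation and is provided for comparison only.
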
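# scnrank

Drug-target prioritization from paired tissue / cell-line networks.

`scnrank` is for computational biologists who have (i) tumor and normal
tissue expression profiles, (ii) expression profiles of matching cancer cell
lines, (iii) a protein–protein interaction (PPI) network, and (iv) a
genome-wide CRISPR-Cas9 essentiality screen, and who want a ranked list of
drug-target genes whose perturbation is predicted to propagate onto the
genes a cancer cell depends on.

## The method

1. **Tissue network.** Genes over-expressed in tumor vs normal (unpaired
   t-test, two-sided *p* < 0.05, log2 FC > 0) are intersected with the PPI
   node set; PPI edges between them are weighted by the Pearson correlation
   *r<sub>ab</sub>* over tumor samples, nodes by the log2 fold change
   *FC<sub>a</sub>*.
2. **Cell-line network.** The identical node/edge skeleton, with edge
   weights recomputed over cell-line samples and node weights replaced by
   CRISPR gene essentiality (knockout survival fold change, averaged over
   sgRNAs, then over cell lines).
3. **Fold-change-weighted spectral clustering** of the tissue network:
   affinity *S′* = signed correlations on edges, degree surrogate
   *D′* = diag(*FC<sub>a</sub>*), row-normalized influence matrix
   *S″* with entries *r<sub>ab</sub>·FC<sub>a</sub> / Σ<sub>k</sub>
   r<sub>ak</sub>*, Laplacian *L* = *D′*<sup>−1/2</sup>(*D′* −
   *S″*)*D′*<sup>−1/2</sup>; k-means on the leading eigenvectors, with K
   chosen by Hartigan's rule (*H*(k) = (*W<sub>k</sub>*/*W<sub>k+1</sub>* −
   1)(n − k − 1), first k with *H* < 10).
4. **Target Influence.** Within its own cluster, each drug target *x* is
   scored on the cell-line network by
   TI(*x*) = Σ<sub>k</sub> *W<sub>k</sub>* · max|∏ *r*| (signed), where the
   maximum-|product| correlation path from *x* to *k* is found exactly by
   Dijkstra on −log|r| edge costs. Targets are ranked by |TI|; each
   cluster's top target is its representative druggable gene.

A fully parameterized synthetic-data generator with planted co-expression
blocks, hub targets and ground truth makes every stage testable without any
external download.

## Worked example

```r
library(scnrank)

spec <- scn_sim_spec()              # 200 genes, 4 planted blocks, 40/40/40 samples
sim  <- scn_simulate(spec, seed = 1)

tissue   <- preprocess_probes(sim$tissue)     # filter / impute / collapse / normalize
cellline <- preprocess_probes(sim$cellline)
ess      <- essentiality_from_sgrna(sim$sgrna)

fit <- scnrank(tissue, cellline, sim$ppi, ess, sim$targets, seed = 1)
fit
#> Spectral-clustering network rank
#>
#>   200 genes tested, 48 over-expressed, 47 on the PPI skeleton
#>   4 clusters (K), 11 / 12 targets mapped and ranked
#>
#> Top targets by |TI|:
#>   gene cluster        TI   abs_TI reachable rank
#> 1 G037       2 -2.911216 2.911216        12    1
#> 2 G013       3 -2.878017 2.878017        12    2
#> 3 G025       4 -2.766273 2.766273        11    3
#> 4 G015       3 -2.314093 2.314093        12    4
#> 5 G038       2 -2.004971 2.004971        12    5
```

Reading the output: 48 of 200 genes passed the over-expression gate and 47
of them lie on the PPI skeleton; Hartigan's rule recovered the 4 planted
blocks; 11 of the 12 candidate targets mapped onto the network. The four
top-ranked genes (G037, G013, G025, G015 — negative TI: knocking them down
propagates onto survival-reducing genes) include the planted essential hub
of each cluster. `summary(fit)` adds cluster sizes and per-cluster
representatives, `coef(fit)` returns the signed TI vector, `plot(fit)` shows
the Laplacian spectrum and the |TI| ranking.

File-based runs go through `scn_run("config.yaml")` (stage TSVs + a JSON
run manifest with seed, parameters, counts and input checksums), or the
thin CLI at `inst/scripts/scnrank.R` (`run` and `simulate` subcommands).

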
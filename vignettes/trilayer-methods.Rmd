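---
title: "Triple-layer network propagation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple-layer network propagation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trilayernet)
```

## The problem and the model

Known miRNA–disease associations form a sparse bipartite graph; the task is
to rank the unobserved pairs so that true-but-unrecorded associations land
near the top. `trilayernet` does this by label propagation over a
heterogeneous network with three entity layers. The disease–miRNA layer
(binary matrix `A`, nd × nm) holds the supervision; the miRNA–lncRNA layer
(binary `B`, nm × nl) contributes an independent channel of miRNA
functional relatedness; similarity matrices within each entity type glue
the layers together.

Starting from `W_dm = A` and `W_ml = B`, each synchronous iteration
rebuilds two miRNA × miRNA coupling matrices from the current iterates,

$$IM = SM \cdot W_{ml} \cdot KL \cdot W_{ml}^{\top}, \qquad
  ID = W_{dm}^{\top} \cdot SD \cdot W_{dm} \cdot SM,$$

normalizes them, and takes a damped step with a restart on the data:

$$W_{dm} \leftarrow \alpha\, W_{dm}\, N(IM) + (1-\alpha) A, \qquad
  W_{ml} \leftarrow \alpha\, N(ID)\, W_{ml} + (1-\alpha) B.$$

Both updates consume the step-`k` iterates (synchronous update); the
iteration stops when the L1 change of `W_dm` falls below the cutoff. The
restart term keeps every known association at a score of at least
`1 − α`, so observed edges always dominate, and the converged `W_dm` is the
prediction matrix. Note the asymmetry of the design: the disease-layer
similarity `SD` influences `W_dm` only indirectly, through the evolution of
`W_ml`; the direct propagation channel for disease–miRNA scores is the
lncRNA-layer coupling `IM`. This matters for what the method can and
cannot recover (see "Known limitations").

## Similarity construction

**Disease semantic similarity.** Each disease is a node in a MeSH-style
DAG; `T(D)` is the disease plus its ancestors. Model 1 gives ancestor `t`
the contribution `DD1_D(t)`: 1 for `D` itself, otherwise Δ times the
largest contribution among `t`'s children inside `T(D)` — a geometric decay
with generation, merged by maximum where paths rejoin. Model 2 replaces
the decay with information content,
`DD2(t) = −log(n_\text{DAGs containing } t / n_\text{diseases})`, which is
0 for a term present in every disease's DAG and large for specific terms.
Both models combine shared ancestry as

$$SS(i,j) = \frac{\sum_{t \in T(i) \cap T(j)} \big(DD_i(t) + DD_j(t)\big)}
                  {DV(i) + DV(j)},$$

with `DV` the sum of all contributions, and the package averages the two
models entrywise. Self-similarity is 1 in model 1 by construction; in
model 2 a disease whose every DAG term is ubiquitous has `DV2 = 0`, and the
pair combination degenerates to 0/0 — the package assigns such diagonal
entries `selfsim_degenerate` (default 1: self-similarity must be maximal)
and off-diagonal degenerate pairs 0, and logs the event.

**miRNA functional similarity** follows the MISIM recipe: score each
disease of one miRNA's disease set by its best semantic match in the other
set, sum both directions, divide by the total set size. Pairs where either
set is empty are *uncovered*, not zero — a missing measurement, handled at
integration time. A precomputed matrix (as distributed with the public
databases) can be supplied instead and is used verbatim with its coverage
mask; values outside [0, 1] are rejected rather than clipped.

**Gaussian interaction-profile kernels** compare binary profiles:
`K(u,v) = exp(−γ ‖IP(u) − IP(v)‖²)` with `γ = γ′ /` (mean squared profile
norm over the entity set). All-zero profiles are legal (the kernel is only
undefined when *every* profile is empty), which is why lncRNAs isolated by
the harmonization step can be kept.

**Integration.** `SM = (KM + FS)/2` where `FS` is covered, else `KM`
(similarly `SD` from `KD` and `SS`). "Has functional similarity" is
interpreted as "inside the coverage mask". The two semantic models are
averaged *before* integration, since the average is what the integration
consumes.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| Δ (`delta`) | 0.5 | per-generation decay of ancestor contributions (dimensionless, in (0,1)); 0.5 is the standard MeSH-semantic-similarity convention |
| `log_base` | natural | base of the model-2 information content; base-10 switch provided |
| γ′d, γ′m, γ′l | 1 | raw kernel bandwidths, divided by mean squared profile norm; 1 is the usual interaction-profile convention |
| α (`alpha`) | 0.4 | propagation weight vs. restart, strictly in (0,1); the reference description fixes only the range, so the package picks a mid-range default favouring the restart |
| `cutoff` | 1e-6 | L1 stopping threshold on `W_dm` (the reference value) |
| `max_iter` | 1000 | safety cap; non-convergence returns a flagged result with a warning rather than an error |
| `normalization` | symmetric_sqrt | see below |

## Numerical choices

* **Normalization variant.** The literal printed normalization divides each
  coupling entry by the *product* of its two row sums; the cited
  convergence argument, however, needs the spectral radius of the
  normalized coupling to stay at or below 1, which the symmetric
  square-root form `M(i,j)/√(rowsum_i · rowsum_j)` guarantees (it is
  similar to a row-stochastic matrix). The package defaults to the
  square-root form and keeps the literal form behind
  `normalization = "row_product_literal"` for fidelity experiments. Both
  are verified against a literal loop-based oracle in the tests.
* **0/0 in normalization** is defined as 0: isolated nodes propagate
  nothing.
* **Dimension of `ID`.** By dimension analysis `ID` is miRNA × miRNA even
  though part of the source description indexes it by diseases; the package
  normalizes over the matrix's actual dimension and documents the
  discrepancy rather than inventing an alternative formula.
* **Ties in ranking** are broken by miRNA label, ascending, so rankings are
  deterministic.
* **Label order** is sorted-lexicographic everywhere, making matrix
  orientation reproducible across runs; matrix round-trips through TSV are
  lossless to well beyond 12 significant digits.
* **Harmonization.** miRNAs present in the lncRNA layer but absent from the
  association layer are dropped (they cannot be coupled); the restriction
  semantics is kept pure, and a `pad = TRUE` option adds all-zero rows for
  association-layer miRNAs with no lncRNA interactions, which the
  propagation algebra needs.

## Cross-validation design

Global LOOCV zeroes each known association in turn, reruns the model, and
compares the held-out score with the scores of all candidate pairs (pairs
unobserved in the *full* `A`); the AUC is the mean fraction of candidates
each held-out positive outscores (ties half) — exactly the pooled
Mann–Whitney statistic, computed by rank rather than threshold sweep for
exactness. Repeated k-fold partitions the positives into balanced folds
(sizes differ by ≤ 1), pools folds within a repeat, and reports one AUC per
repeat; fold assignment is fully determined by the seed.

Two refit policies are offered. By default the Gaussian kernels (and hence
`SM`, `SD`) are recomputed after masking, so no information about the test
entry leaks through the kernels. `refit = FALSE` reuses matrices fitted
once on the full data — faster, and arguably closer to a static reference
setup. `FS` and `SS` are never refit: they stand in for externally curated
knowledge. A `score_fn` hook exists for diagnostics; the test suite uses
it for a leakage guard (a scorer that returns the masked `A` must produce a
degenerate, flagged AUC of 0.5).

## What the synthetic generator emulates

The generator plants matched clusters across all three entity layers:
associations appear with probability `p_in` inside matched clusters and
`p_out` elsewhere, in both bipartite layers; the disease DAG is a rooted
tree whose subtrees follow the disease clusters, so cluster-mates share
deep ancestors and receive high semantic similarity. Every row and column
is guaranteed at least one positive by logged resampling. Defaults
(nd = 30, nm = 40, nl = 25, 4 clusters, p_in = 0.3, p_out = 0.02) give a
desk-scale network with a clear planted signal at realistic sparsity.

It does **not** emulate the heavy-tailed degree distributions of the real
curated databases, the very asymmetric coverage of the real lncRNA layer
(where most miRNAs have no recorded lncRNA interaction), or noisy/biased
curation. A green test on synthetic data therefore establishes mechanical
correctness (the equations are computed right, CV accounting is sound,
convergence holds) — not that the method reaches any particular accuracy on
real curated data.

## Known limitations

* **The lncRNA bottleneck.** Because `W_dm` receives propagated information
  only through `IM = SM · W_ml · KL · W_ml^T`, the disease-layer similarity
  cannot directly inform disease–miRNA scores. On the synthetic world the
  bilinear degree terms and the kernel baseline of `KL` make `IM` nearly
  rank-one; after row-sum normalization its in-cluster contrast is ~1.1×,
  and the residual `sqrt(lncRNA degree)` column artifact of the symmetric
  normalization swamps it. The package's leave-one-out AUC on the default
  synthetic world is consequently near 0.5 (the acceptance suite computes
  and reports this honestly), even though the similarity matrices
  themselves separate the planted clusters cleanly. Users should treat the
  miRNA–lncRNA layer as a *refinement* channel and validate on their own
  data before trusting rankings.
* **Cold start.** Diseases or miRNAs with no known association receive only
  kernel-mediated signal; entities absent from all layers cannot be scored
  at all. This is an inherent property of the model family.
* **Parameter selection.** There is no built-in procedure to learn α or the
  bandwidths from data; defaults follow the conventions above.
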
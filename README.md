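# trilayernet

Triple-layer heterogeneous network propagation for miRNA–disease
association prediction.

Experimentally confirmed miRNA–disease associations are sparse, and wet-lab
validation of new candidates is slow and expensive. `trilayernet`
prioritizes candidate associations computationally by propagating the
observed association signal through a heterogeneous network with three
entity layers — diseases, miRNAs and lncRNAs — on the guilt-by-association
principle: functionally similar miRNAs tend to be implicated in
phenotypically similar diseases, and miRNA–lncRNA interactions provide an
additional, independent channel of functional relatedness. The package is
aimed at computational biologists who have a binary disease–miRNA
association table (HMDD-style), a binary miRNA–lncRNA interaction table
(starBase-style) and a MeSH-style disease hierarchy, and want ranked
candidate miRNAs per disease plus a cross-validation estimate of ranking
quality.

## The model

Let `A` (nd × nm) be the binary disease–miRNA matrix and `B` (nm × nl) the
binary miRNA–lncRNA matrix. The package builds:

* **Disease semantic similarity** `SS = (SS1 + SS2)/2` from the disease
  DAG. Model 1 scores each ancestor `t` of disease `D` by a geometrically
  decaying contribution `DD1_D(t)` (factor Δ per generation, paths merged
  by maximum); model 2 weights each term by its information content
  `DD2(t) = −log(n_DAGs_containing_t / n_diseases)`. Both combine shared
  ancestors as
  `SS(i,j) = Σ_{t ∈ T(i)∩T(j)} (DD_i(t) + DD_j(t)) / (DV(i) + DV(j))`.
* **miRNA functional similarity** `FS` (MISIM-style) from each miRNA's
  associated disease set, via best-match semantic similarity.
* **Gaussian interaction-profile kernels** `KD`, `KM`, `KL` over the binary
  profiles of diseases, miRNAs and lncRNAs,
  `K(u,v) = exp(−γ‖IP(u) − IP(v)‖²)` with γ normalized by the mean squared
  profile norm.
* **Integrated similarities** `SM` (miRNAs) and `SD` (diseases): the mean
  of kernel and functional/semantic similarity where the latter is defined,
  the kernel alone elsewhere.

Prediction scores come from a coupled iteration started at
`W_dm = A, W_ml = B`:

```
IM   = SM · W_ml · KL · W_mlᵀ            (miRNA×miRNA, lncRNA-layer coupling)
ID   = W_dmᵀ · SD · W_dm · SM            (miRNA×miRNA, disease-layer coupling)
W_dm ← α · W_dm · N(IM) + (1 − α) · A
W_ml ← α · N(ID) · W_ml + (1 − α) · B
```

where `N(·)` normalizes by row sums (symmetric square-root form by default,
which bounds the spectral radius by 1 and guarantees convergence for
α < 1) and the iteration stops when the L1 change of `W_dm` drops below
`1e-6`. Final `W_dm` entries are the association scores; `W_ml` scores
miRNA–lncRNA interactions as a by-product.

## Worked example

```r
library(trilayernet)

# a synthetic triple-layer world with 4 planted clusters
sim <- generate_trilayer(synthetic_spec(seed = 1))

scfg <- semantic_config()                       # Δ = 0.5, natural log
SS <- combined_semantic_similarity(
  semantic_similarity_m1(sim$dag, scfg),
  semantic_similarity_m2(sim$dag, scfg))
FS <- mirna_functional_similarity(sim$disease_sets, SS)
SM <- integrate_mirna_similarity(gaussian_profile_kernel(sim$A, "cols"), FS)
SD <- integrate_disease_similarity(gaussian_profile_kernel(sim$A, "rows"), SS)
KL <- gaussian_profile_kernel(sim$B, "cols")

fit <- trilayer_propagate(sim$A, sim$B, SM, SD, KL)
fit
#> trilayer_scores: 30 x 40 disease-miRNA, 40 x 25 miRNA-lncRNA
#>   converged after 18 iterations (delta_dm = 4.83e-07)

head(rank_candidates(fit, sim$A, "d001"), 3)
#>   mirna      score
#> 1  m001 0.11574863
#> 2  m013 0.08922381
#> 3  m015 0.08746585

cv <- global_loocv(sim$A, sim$B, SS, FS)
cv
#> cv_result: mean AUC = 0.4910 over 1 run(s), 116 test pair(s)
```

The fit converges in 18 iterations; `rank_candidates` lists unobserved
miRNAs for disease `d001` by decreasing score (known associations are
excluded). The leave-one-out AUC is the probability that a held-out known
association outscores a random unobserved pair: here it is near 0.5 — on
desk-scale synthetic data the lncRNA-layer coupling that drives the
disease–miRNA update carries almost no usable cluster signal (see the
methods vignette for the analysis), so the global ranking is close to
random even though the similarity layers themselves separate the planted
clusters cleanly.

A command-line interface with the same functionality ships in
`inst/cli/trilayernet.R` (subcommands `simulate`, `similarity`, `predict`,
`evaluate`).

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
synthetic generation, all similarity matrices, propagation to convergence,
and global leave-one-out cross-validation — and writes a JSON results file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
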
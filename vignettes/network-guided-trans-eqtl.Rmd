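---
title: "Network-guided covariate selection for trans-eQTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-guided covariate selection for trans-eQTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netlmm)
```

## The problem

Trans-acting eQTLs — variants that regulate the expression of distant genes,
typically through an intermediate *cis*-regulated gene — are hard to detect:
effect sizes are small and the genome-wide grid of tests imposes a severe
multiple-testing burden. The standard remedy, conditioning every test on
latent covariates inferred from the expression matrix itself (principal
components, factor models, or the empirical expression covariance), has a
well-known failure mode in the trans setting: the inferred covariates are
partly *heritable*. A principal component that captures the downstream
program of a regulatory hotspot will, when conditioned on, explain away
exactly the signal one is trying to find. Conversely, conditioning on a gene
that sits *downstream* of the focal gene (a co-regulated sibling) absorbs the
causal signal and can even induce spurious associations through collider
bias.

The safe covariates are the **exogenous genes** of a focal gene C under a
test of SNP A: genes with a causal incoming effect on C that are themselves
independent of A. Conditioning on them removes competing variance (regulatory
context or confounding) without touching the causal path A → C.

## The method

Since the true regulatory network is unknown, exogenous genes are identified
from the data by testing for **V-structures** (colliders), the one directed
motif that is identifiable from observational dependencies: gene A → gene
C ← gene B implies that A and B are marginally independent but become
dependent after conditioning on C. For each (SNP A, gene C) pair the
algorithm accepts a candidate gene B when six criteria hold at configurable
thresholds (`threshold_config()`):

1. dep(y~A~, y~C~) — adjusted p < `p_dep` (default 0.01),
2. dep(y~B~, y~C~) — adjusted p < `p_dep`,
3. ind(y~A~, y~B~) — raw p ≥ `p_ind` (default 0.1),
4. dep(y~A~, y~B~ | y~C~) — partial correlation, adjusted p < `p_dep`,
5. dep(x~A~, y~A~) — the anchor condition: gene A has an established cis
   (or, in trans-anchor mode, any) association with SNP A at adjusted
   p < `p_anchor` (default 0.05),
6. ind(x~A~, y~B~) — raw association p ≥ `p_snp_ind` (default 0.1), the
   guard that rules out synthetic associations from conditioning on a gene
   that is itself regulated by the tested variant.

Dependence between genes uses a Pearson correlation test; the partial
correlation is computed from the marginal correlations and tested with N−3
degrees of freedom, and it is only evaluated once criteria 1–3 and the
anchor condition hold (the search cost is dominated by the one-off
T × T correlation matrix). The anchor restriction is what makes the search
local and linear rather than quadratic in the number of genes.

The three pipeline steps (`run_netlmm()`):

1. **Scan.** A standard linear mixed model per gene,
   y ~ N(xβ, σ²~bg~ K + σ²~n~ I), with the realized relationship matrix
   K = ZZ'/F from standardized dosages as background covariance. The
   noise/background ratio δ = σ²~n~/σ²~bg~ is fit once per gene on the null
   by maximum likelihood and held fixed across that gene's variant tests; in
   the eigenbasis of K every test is a weighted least-squares fit, and the
   p-value is a 1-df likelihood-ratio test with the scale profiled out.
2. **V-structure discovery** seeded at the anchor pairs of step 1.
3. **Update.** Every (SNP, gene) pair with a nonempty conditioning set is
   re-tested under y ~ N(xβ, σ²~bg~ K + σ²~exo~ Σ~B~ y~B~y~B~' + σ²~n~ I).
   The rank-R exogenous term makes the per-test cost O(N²R + NR²) via
   Woodbury identities in the kinship eigenbasis — the dense N × N
   covariance is never refactorized. All untouched entries are copied from
   step 1, so a dataset with no usable V-structures reproduces the standard
   LMM scan bit for bit.

## Choices the description above leaves open

These points are not fixed by the method's published description; the
package resolves them as follows.

* **Step-3 variance components** are refit per unique (gene, conditioning
  set) on the null model and then held fixed for that set's tests,
  mirroring the step-1 treatment of δ. Reusing the step-1 δ would ignore
  the variance the exogenous term absorbs.
* **Exogenous columns are standardized** to unit variance before forming
  the rank-R covariance, so that the single σ²~exo~ is not dominated by an
  arbitrarily scaled gene.
* **Criterion 4 conditions on the expression of gene C.** One printed form
  of the criterion subscripts the genotype vector instead; the surrounding
  description ("conditioning on the gene C") and the collider logic both
  require the expression vector, so the genotype reading is treated as a
  typo. A `condition_on = "both"` switch additionally requires dependence
  given the genotype of the variant nearest C's TSS, for sensitivity
  analyses.
* **"Adjusted p"** is Bonferroni within the relevant family: gene–gene
  dependence calls by the number of gene pairs, anchor calls by T × F.
  Family sizes are configurable; the `"basic"` preset for small simulated
  networks (a handful of genes) uses stricter raw thresholds
  (p < 0.001 for dependence and anchors) with no adjustment, since with
  T ≤ 5 the family correction is immaterial and the stricter raw cut is
  what keeps false V-structures out.
* **Independence calls use raw p-values** (criteria 3 and 6): an
  independence "test" by a large p-value is a filter, not a calibrated
  test, and adjusting it would make it vacuous.
* **Maximum conditioning rank** defaults to 10; larger sets keep the genes
  with the smallest V-structure partial-correlation p-values, which makes
  truncation deterministic.
* **δ is declared infinite** (pure-noise attribution, the model collapses
  to OLS) whenever the boundary attains the 1-D optimum — the deterministic
  tie-break when K = I leaves δ unidentifiable. The 1-D search is a
  100-point log-spaced grid on [1e-4, 1e4] with bounded refinement; the 2-D
  step-3 search uses a coarse grid start and L-BFGS-B with an analytic
  gradient of the profiled likelihood (compiled kernel).
* **Missing genotypes** are mean-imputed per variant before
  standardization and testing. Monomorphic variants yield `NA` scan entries
  with a logged count.
* **The permutation null** (`permutation_calibration()`) permutes the
  sample order of each tested genotype vector, which breaks the SNP–gene
  link while preserving the expression covariance and the identified
  conditioning sets; variance components stay at their fitted values and
  only the final tests are re-run, stratified by the presence of exogenous
  genes.

## The simulator

`simulate_basic()` generates the four-gene motifs used to characterize the
method (power, direct, trans, confounding — the last with an optional
guard variant in which gene B is also regulated by SNP A), and
`simulate_network()` generates 100-gene networks: sparse topologies with
Bernoulli(0.02) edges over a random topological order (the edge probability
is not part of the published design; 0.02 gives about two parents per gene
and is exposed in `sim_params()`), or star topologies with 9 hubs each
regulating a uniform 20–50% fraction of the remaining genes. Edge weights
come from the equal mixture of N(+1, 0.1²) and N(−1, 0.1²), which keeps
weights bounded away from zero with balanced signs. Every gene receives a
cis variant explaining `var_cis` (default 0.10) of its variance; incoming
edges and confounders jointly explain `var_network` (default 0.80),
apportioned by `conf_fraction` (default 0.2) with `n_confounders` standard
normal factors assigned to genes at an expected `conf_per_gene` rate. The
default panel is 379 samples by 4030 independent common variants
(MAF ≥ 0.05), the dimensions of the quasi-independent chromosome-20
reference panel the benchmark designs assume.

"Variance explained" is operationalized by rescaling each component vector
so its empirical variance hits the sampled share exactly; realized shares
are recorded per gene in the ground-truth table. Cross-component sample
covariances make the empirical decomposition fluctuate around the nominal
shares by O(N^−1/2^), which the fidelity tests average out over seeds.

What the simulator deliberately omits: linkage disequilibrium (variants are
independent, so one "locus" is one variant), population stratification,
non-linear regulation, and cell-type heterogeneity. Passing benchmarks here
therefore demonstrate the statistical machinery under the stated generative
model, not robustness to the correlated-variant structure of real cohorts.

## Evaluation

`label_truth()` marks a scan entry as a true positive when the truth
adjacency holds a direct regulator of the gene whose cis anchor lies within
±2 kb of the tested variant; entries within ±5 Mb of the focal gene's own
position are excluded as putative cis associations; everything else is a
false positive. In simulations a gene's genomic position is its cis-anchor
variant position. `partial_auc()` ranks by ascending p-value with tie
blocks, integrates the ROC over FPR ∈ [0, 0.05], and reports both the raw
area and the area normalized by 0.05 so a perfect ranking scores 1 (a
random one 0.025). Whether to pool associations across replicate datasets
or average per-replicate power is a free choice; the benchmarks compute
power within each replicate and average across replicates, which keeps
replicates exchangeable.

The benchmark drivers (`benchmark_basic_power()`, `benchmark_network()`,
`benchmark_null_calibration()`) run these designs end to end. The shipped
acceptance checks use 379 samples with 500-variant panels and 50-gene
networks at 100–500 replicates, and 400-variant panels for the calibration
designs (smaller panels make the tested variant a visible fraction of the
realized relationship matrix and deflate the null tail) — sizes chosen so
the full suite completes on a single core in tens of minutes while leaving
the per-replicate model dimensions at the study's sample size. The same
quantities at the full panel size only sharpen the estimates.

## Known limitations

* Detection of V-structures at the strict basic-simulation thresholds is
  intentionally conservative: on the four-gene power motif the collider's
  partial correlation clears p < 0.001 in roughly half of the replicates,
  and the pipeline then correctly reverts to the standard LMM for the
  rest. Power gains are therefore a mixture over detection.
* Tightly correlated expression (one dominant factor) suppresses criterion
  3 and with it all V-structures; the method degrades gracefully to the
  standard LMM rather than failing, but gains vanish.
* The anchor-first search cannot help genes whose trans effect has no
  expressed mediator (e.g., purely epigenetic paths).
* ICE-style comparisons include the focal gene in the empirical covariance
  (switchable via `exclude_focal`); at moderate gene counts that
  self-conditioning makes ICE markedly conservative, which is the behaviour
  the benchmarks document.
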
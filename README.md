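# netlmm

Network-guided linear mixed models for trans-eQTL mapping.

## The problem

Mapping *trans*-acting expression QTLs — variants that regulate distant
genes, typically via a *cis*-regulated intermediate — suffers from small
effects and a genome-wide testing burden. Conditioning on latent covariates
learned from the expression matrix (principal components, factor models)
helps for *cis* mapping but is dangerous in *trans*: the learned covariates
are partly heritable, so they absorb exactly the hotspot signal one wants
to detect, and conditioning on downstream (co-regulated) genes induces
collider bias.

`netlmm` instead conditions each SNP–gene test only on **exogenous genes**:
genes with a causal incoming effect on the focal gene that are independent
of the tested variant. These are found from the data by testing for
**V-structures** (colliders) in local regulatory networks.

## The method

For a test of SNP A against focal gene C, the algorithm looks for quartets
(SNP A, gene A, gene C, gene B) satisfying six (in)dependence criteria —
in field notation:

1. dep(y_A, y_C), 2. dep(y_B, y_C): adjusted p < 0.01;
3. ind(y_A, y_B): p ≥ 0.1;
4. dep(y_A, y_B | y_C): the collider signature, adjusted p < 0.01;
5. dep(x_A, y_A): gene A is a cis (or trans) **anchor** of SNP A;
6. ind(x_A, y_B): the guard against synthetic associations.

Accepted genes B enter the association model as a low-rank random effect
next to the genetic background:

    y_C ~ N( x_A beta,  sigma_bg^2 K + sigma_exo^2 * sum_B y_B y_B' + sigma_n^2 I )

with K the realized relationship matrix (ZZ'/F of standardized dosages).
The noise/background ratio is fit once per gene on the null (EMMA-X style)
and per-test statistics are 1-df likelihood-ratio tests; the rank-R
exogenous term is handled with Woodbury updates in the kinship eigenbasis,
so no dense N×N covariance is ever refactorized. Pairs without V-structures
keep their standard-LMM p-value — with no usable anchors the method *is*
the standard LMM.

The package also ships the benchmark simulators (basic four-gene motifs;
sparse and 9-hub star networks of 100 genes with confounders), the
comparator methods from the trans-eQTL literature (PC-LMM, PCselect-LMM,
ICE-LMM, oracle ideal/coreg conditioning), and the evaluation stack
(truth labelling, partial AUC at FPR < 5%, hotspot tables, permutation
calibration).

## Worked example

```r
library(netlmm)

sim <- simulate_basic("power", n = 379, f = 500, seed = 3)
res <- run_netlmm(sim$genotypes, sim$expression,
                  cfg = threshold_config("basic"))
res
#> netlmm_result: 4 genes x 500 variants; 1 anchor pair(s), 1 V-structure(s), 1 conditioned test(s)

as.data.frame(res$vstructures)[, c("snp_id", "anchor_gene", "focal_gene",
                                   "exo_gene", "r_ab_c", "p_partial")]
#>    snp_id anchor_gene focal_gene exo_gene     r_ab_c   p_partial
#> 1 snp0001       geneA      geneC    geneB -0.2254083 9.64417e-06

cbind(initial = res$initial_scan$pvalues["geneC", "snp0001"],
      updated = res$updated_scan$pvalues["geneC", "snp0001"])
#>           initial      updated
#> [1,] 0.0004823769 5.974469e-05
```

The search anchored gene A at its cis variant, recognized gene B as the
exogenous parent of gene C through the collider test (partial correlation
−0.23 after conditioning on gene C, p ≈ 1e-5), and conditioning on gene B
sharpened the true trans association by almost an order of magnitude. A
scan-wide power read-out of the same design, averaged over replicate
datasets, comes from `benchmark_basic_power()`; calibration and guard
behaviour from `benchmark_null_calibration()`.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "netlmm", package = "netlmm")` with subcommands
`scan`, `vstruct`, `update`, `run`, `calibrate`, `compare`; runs with the
same `--seed` are bit-identical.

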
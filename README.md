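# kernboost

Pathway-based kernel boosting for case-control genetic association studies.

## The problem

Genome-wide association studies test hundreds of thousands of SNPs one at a
time, which costs power and rarely explains *which biological process* is
involved. Pathway analysis groups SNPs via genes into gene-interaction
networks and tests each pathway as one unit — but single-pathway tests
(such as the logistic kernel machine test, LKMT) cannot tell causal
processes apart from pathways that merely share genes with them, face a
multiple-testing burden, and do not predict the clinical outcome.

`kernboost` addresses this by turning pathway kernels into base-learners of
a component-wise functional gradient boosting algorithm, so that *all*
pathways are modelled simultaneously, the relevant ones are picked by the
algorithm's selection mechanism (no p-values, no multiplicity correction),
and the fitted model predicts disease probability for new individuals.

## The method in brief

The disease status follows an additive logistic model

```
logit P(y_i = 1 | x_i, z_i) = x_i' beta + f_1(z_i) + ... + f_P(z_i)
```

with one nonparametric pathway effect `f_p` per gene network, represented
through the network-based genetic similarity kernel

```
K = Z A N A' Z'
```

(`Z` minor-allele counts, `A` the SNP-to-gene mapping with a `1/sqrt(m_g)`
gene-size adjustment, `N` the signed gene-interaction adjacency after
pruning/rewiring of non-genotyped genes, symmetrization and an
eigenvalue-shift to positive semidefiniteness `rho N + (1 - rho) I`).

Boosting proceeds from a covariate-only logistic offset model; each
iteration fits all pathway base-learners to the negative gradient of the
binomial loss by penalized least squares (`gamma = (K'K + lambda K)^{-1} K'u`,
with `lambda` calibrated so every learner has equal degrees of freedom,
default 4), selects the best-fitting pathway, and moves the predictor by a
step `nu = 0.1`. The number of iterations — the only capacity parameter —
is tuned by stratified subsampling over a grid that includes the empty
model. Pathways chosen at least once within the tuned path are "selected".
An LKMT implementation (Satterthwaite score test with permutation oracle)
is included as the single-pathway comparator, and a synthetic-data module
generates null and effect case-control scenarios with pseudogene LD
structure for benchmarking.

## Worked example

Simulate a 6-pathway study in which two pathways carry interconnected
genetic effects (relative risk 1.5 per allele), fit the tuned boosting
model, and compare with the LKMT:

```r
library(kernboost)

sc <- simulate_scenario("effect", n_cases = 250, n_controls = 250,
                        rr_per_allele = 1.5, n_pathways = 6,
                        genes_per_pathway = 20, density = 0.2, seed = 2026)
learners <- pathway_kernels(sc$Z, sc$annotation, sc$networks, df_target = 4)
fit <- kernel_boost_cv(sc$y, learners, nu = 0.1, m_max = 100,
                       n_folds = 10, seed = 7)
fit
#> Kernel boosting fit: n = 500, 6 pathways, m_stop = 100, nu = 0.1
#> Selected pathways (3): pw01, pw02, pw06
sc$effect$pathways
#> [1] "pw01" "pw02"

p_hat <- fitted(fit)
cut <- youden_cutpoint(sc$y, p_hat)
misclassification_rate(sc$y, p_hat, cut$cut)   # 0.358 at cut 0.502
roc_auc(sc$y, p_hat)                           # 0.702

lkmt_pathways(sc$y, learners)
#>   pathway         Q      p_value bonferroni
#> 1    pw01 1240.9919 1.372903e-02      FALSE
#> 2    pw02 2363.8421 2.563807e-07       TRUE
#> 3    pw03  657.4623 3.246488e-01      FALSE
#> 4    pw04  459.1259 6.704925e-01      FALSE
#> 5    pw05  396.8936 7.906562e-01      FALSE
#> 6    pw06 1126.0697 2.047897e-02      FALSE
```

Boosting recovers both causal pathways (plus one spurious one at this
moderate sample size), while the Bonferroni-corrected LKMT detects only the
stronger of the two — the power pattern the method is designed to exploit.
Predictions for new genotypes come from `predict_proba(fit, Z_new)`;
`save_model()` / `load_model()` round-trip fitted models through a
checksummed JSON file.

A command-line interface wrapping the same functions is installed at
`exec/kernboost` (subcommands `simulate`, `fit`, `predict`, `lkmt`,
`evaluate`).

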
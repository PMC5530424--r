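---
title: "Pathway kernel boosting: model, tuning and simulation design"
author: "kernboost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway kernel boosting: model, tuning and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernboost)
```

## The model

`kernboost` models the case probability of individual $i$ with an additive
logistic regression

$$\mathrm{logit}\, P(y_i = 1 \mid x_i, z_i) = x_i^\top\beta + f_1(z_i) + \dots + f_P(z_i),$$

where $x_i$ are environmental covariates and each $f_p$ is a nonparametric
function of the minor-allele counts $z_i \in \{0,1,2\}^{n_s}$ of the SNPs
annotated to pathway $p$. Each $f_p$ lives in the reproducing kernel Hilbert
space of the network-based genetic similarity kernel

$$K = Z\,A\,N\,A^\top Z^\top,$$

with $Z$ the $n \times n_s$ genotype matrix, $A$ the SNP-to-gene mapping
matrix and $N$ the signed gene-interaction adjacency of the pathway
(activation $+1$, inhibition $-1$). Entry $K_{ij}$ is read as the
pathway-specific genetic similarity of individuals $i$ and $j$; the network
factor upweights genotype configurations that agree along interacting genes,
which is why this kernel is particularly sensitive to effects spread over
interconnected genes.

### Preparing the network factor

Three preparation steps make $N$ usable inside a kernel:

1. **Pruning and rewiring.** Genes without genotyped SNPs cannot enter $A$.
   Removing such a gene would delete the interaction information flowing
   through it, so each pair of its neighbours is connected directly with a
   weight equal to the product of the two dropped link weights (an
   activation chained with an inhibition becomes an inhibition). Existing
   direct links are never overwritten, and genes are eliminated in the
   network's gene order, which makes the outcome deterministic when several
   rewired candidates compete. The elimination-order invariance on graphs
   with unique 2-step paths is covered by tests against a brute-force
   oracle.
2. **Symmetrization.** Edge lists are often directed; the adjacency is
   mirrored along the diagonal. Where the two directions disagree in sign,
   the upper-triangle entry of the input wins -- an arbitrary but
   deterministic and documented rule (the case is rare in curated
   networks).
3. **Positive semidefiniteness.** A signed adjacency is generally
   indefinite. With $\rho = 1/(1 - \lambda_{\min})$ for negative
   $\lambda_{\min}$, the shift $\rho N + (1-\rho) I$ maps the smallest
   eigenvalue exactly to zero while preserving as much of $N$ as possible;
   $\rho = 1$ leaves a PSD matrix untouched. The same transformation is
   reapplied to $K$ itself when floating-point round-off produces
   eigenvalues below $-10^{-8}$ (`ensure_psd_kernel()`); this eigenvalue
   shift is preferred over projection-type PSD repairs because it is fast
   and perturbs the matrix entries less.

The gene-size adjustment in $A$ is $A_{sg} = 1/\sqrt{m_g}$ for the $m_g$
SNPs annotated to gene $g$, giving every represented gene a unit-norm
column so that large genes do not dominate the kernel merely by SNP count.
The mapping itself is positional: a SNP belongs to every gene whose
interval (optionally extended by a flank in bp, to absorb LD blocks
reaching beyond gene boundaries) contains it, so one SNP may feed several
overlapping genes.

## Boosting with kernel base-learners

Each pathway contributes one base-learner $f(Z) = K\gamma$ with smoothness
penalty $J(\gamma) = \gamma^\top K \gamma$. Component-wise functional
gradient boosting then minimizes the empirical risk (mean negative binomial
log-likelihood): starting from the offset $\eta^{[0]}$, iteration $m$

1. computes the negative gradient $u_i^{[m]} = y_i -
   \mathrm{expit}(\eta_i^{[m-1]})$,
2. fits every base-learner to $u^{[m]}$ by penalized least squares
   $\hat\gamma = (K^\top K + \lambda K)^{-1} K^\top u$,
3. selects the learner with the smallest residual sum of squares (smallest
   index on ties, so selection paths are bit-reproducible), and
4. adds $\nu$ times its fit to $\eta$ and to the winner's aggregated
   estimate $\hat f_{p^\star}$, leaving all other $\hat f_p$ unchanged.

Numerically the fit is computed in the transformed design $\tilde K = K
K^{-1/2}$, for which the penalty becomes the identity and the solution is
$\hat\gamma = (\tilde K^\top \tilde K + \lambda I)^{-1}\tilde K^\top u$.
Since $\tilde K = V D^{1/2} V^\top$ for the eigendecomposition
$K = V D V^\top$, every per-iteration fit reduces to two thin matrix-vector
products in the eigenbasis; the eigendecomposition is done once per kernel.
$K^{-1/2}$ is taken on the numerically nonzero eigenspace (eigenvalues above
`tol_rel = 1e-10` times the largest -- the standard pseudo-inverse
truncation), because these kernels are usually rank-deficient: the rank is
bounded by the number of genes, not individuals. The equivalence of the
transformed and direct forms is asserted to $10^{-8}$ against a dense solve
in the test suite.

**Initialization.** The additive predictor starts at the offset model's
linear predictor; without covariates this is $\mathrm{logit}(\bar y)$. A
literal start at $\bar y$ would mix the probability and logit scales, so the
loss-minimizing intercept on the logit scale is used.

**Covariates as offset.** Environmental covariates are handled as mandatory
effects: a standard logistic regression of $y$ on $X$ is fitted first and
its linear predictor initializes (and is carried through) the boosting fit.
This mirrors the logistic kernel machine test, which also tests pathway
effects on top of a covariate-only null model, and keeps covariates out of
the selection competition. Perfect separation in the offset model is
refused with an explicit error rather than silently penalized.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `df_target` | 4 | degrees of freedom every base-learner is calibrated to; the conventional value for smooth effects. Equal df across learners keeps selection unbiased with respect to pathway size/rank. |
| `df_method` | `"corrected"` | df definition $tr(2S - SS^\top)$ from the unbiased-selection framework the df-4 convention originates in; plain $tr(S)$ is available. |
| `nu` | 0.1 | step length; of minor importance as long as it is small. |
| `m_max` | 200 | largest number of iterations explored by the tuner. |
| `n_folds`, `fraction` | 20, 0.5 | subsampling folds and subsample fraction (drawn without replacement, stratified by case status). |
| `tol_rel` | 1e-10 | relative eigenvalue truncation for $K^{-1/2}$. |

The penalty $\lambda$ is never set directly: `calibrate_lambda()` solves
$\mathrm{df}(\lambda) = \sum_i d_i/(d_i + \lambda) = \mathrm{df}_{target}$
(or the corrected variant) by bisection on $\log\lambda$, where $d_i$ are
the retained eigenvalues of $K$.

### Early stopping and selection

The number of iterations $m_{stop}$ is the capacity parameter. It is tuned
by subsampling: each fold refits the offset and all base-learners on a
stratified half-sample, runs the path to `m_max`, and scores the held-out
mean negative log-likelihood at every $m \in \{0, \dots, m_{max}\}$. The
tuned $m_{stop}$ minimizes the fold-mean curve, ties going to the smallest
$m$. The grid includes $m = 0$, so the empty (offset-only) model is an
attainable outcome -- under a null phenotype it is frequently the chosen
one. A pathway is *selected* if it is chosen in at least one of the tuned
iterations; this is the quantity summarized by `selection_frequency()`
across simulation replicates.

### Prediction

For new genotypes $Z^*$, the rectangular prediction kernel $K^* = Z^* A N
A^\top Z^\top$ computes similarities to the training individuals; the
pathway contribution is $K^* \hat\gamma_p$ with $\hat\gamma_p$ the
$\nu$-weighted coefficient sum over the iterations that selected $p$,
mapped back through $K^{-1/2}$. $K^*$ need not be square, full-rank or
PSD. If a training kernel needed the numerical PSD repair with weight
$\rho < 1$, predictions scale $K^*$ by $\rho$; the $(1-\rho)$ identity part
is a training-diagonal term that does not transfer to new individuals
(in practice $\rho = 1$ because $N$ is PSD before $K$ is formed, and the
repair only ever counteracts $10^{-15}$-scale round-off).

## The LKMT comparator

The logistic kernel machine test evaluates one pathway at a time: with null
residuals $r = y - \hat p$ from the covariate-only model, the
variance-component score statistic is $Q = \tfrac12 r^\top K r$. The
default p-value matches the first two moments of $Q$ under the null
($E = tr(P_0 K)/2$, $V = tr(P_0 K P_0 K)/2$ with $P_0$ the null residual
covariance) to a scaled $\chi^2$ (Satterthwaite); a permutation mode
re-draws $Q$ under permuted residuals and serves as the model-free oracle in
the tests. Exact mixture-of-$\chi^2$ inversions are deliberately out of
scope: the comparator's role here is the power ordering against boosting,
with Bonferroni correction $\alpha/P$ across pathways. The Satterthwaite
approximation's type-I error at $\alpha = 0.05$ is verified against
binomial bounds over 500 null simulations, and its p-values against a
20,000-permutation oracle.

## What the simulator emulates -- and what it does not

`simulate_scenario()` rebuilds the structure of the evaluation study
without external haplotype resources:

* **Pseudogenes.** Each gene is a block of 5 SNPs. Per-SNP MAFs are drawn
  uniformly from $(0.05, 0.5)$ -- the common-variant range of genotyping
  arrays after QC. Two haplotypes per individual are drawn from a Gaussian
  copula with AR(1) correlation `ld_rho = 0.5` between adjacent SNPs and
  summed to genotype counts, giving within-gene LD of realistic magnitude.
  Genes are mutually independent, emulating the large physical separation
  used to prevent LD leaking across pseudogenes.
* **Networks.** Toy pathways are signed Erdős–Rényi graphs: density 0.1
  (mean degree about 3 at 30 genes, matching the middle of curated pathway
  topologies), 14% inhibiting links, and optional gene overlap between
  consecutive pathways. They stand in for curated gene-interaction networks
  and are labelled as synthetic throughout.
* **Null scenario.** Disease status i.i.d. Bernoulli(0.5), independent of
  every genotype.
* **Effect scenarios.** Two causal pathways; in each, one seed gene is
  drawn with probability proportional to its betweenness centrality
  (topologically central genes are more plausible effect carriers) and two
  of its neighbours complete an interconnected effect set; two SNPs per
  effect gene carry an additive per-allele effect. Individuals receive case
  probability $\mathrm{expit}(\alpha + \log(RR)\sum_s z_{is})$, with
  $\alpha$ pinning the marginal prevalence at 0.1 -- at that prevalence the
  per-allele odds ratio approximates the stated relative risk -- and
  rejection sampling retains exactly the requested 1:1 cases and controls.

Not emulated: real recombination maps and population LD structure, curated
pathway topologies (hub/scale-free degree distributions beyond what ER
graphs give), genotyping error and missingness, and population
stratification. Passing tests on this generator therefore demonstrate the
statistical mechanics of the method -- selection calibration under the
null, power ordering under interconnected effects, calibration of the
comparator -- not performance on any particular real GWAS.

## Numerical and design choices

* Eigendecomposition (symmetric solver) rather than Cholesky everywhere,
  because pathway kernels are routinely rank-deficient.
* PSD tolerance $10^{-8}$; eigen-truncation `tol_rel` $10^{-10}$ relative
  to the leading eigenvalue.
* RSS-based selection uses the algebraic identity
  $\lVert u - Su\rVert^2 = u^\top u - \sum_i (2s_i - s_i^2) a_i^2$ in the
  eigenbasis, so an iteration costs two thin products per learner.
* Ties: smallest learner index (selection), smallest $m$ (stopping),
  upper-triangle sign (symmetrization), first-removed gene (rewiring) --
  every tie-break is deterministic.
* All randomness flows through R's global RNG; scenario and tuner functions
  take explicit seeds, and replicate seeds are derived from one master
  seed, which makes the full simulate--fit--evaluate pipeline
  byte-reproducible.
* Degenerate inputs fail loudly: single-class phenotypes, perfectly
  separating covariates, all-zero kernels, df targets at or above the
  kernel rank, genotype files with missing entries.

## Study scales used in the checks

The automated checks run reduced study scales chosen to exercise the same
regimes at desk-scale cost: null calibration at 20 replicates of 10--20
pathways (30 pseudogenes each) with $n$ between 400 and 1000, and power
ordering at RR 1.5 with 500 cases/500 controls and 20 replicates. One
property worth knowing: the rate of false selections under the null is not
scale-free. It is driven by the selection-bias drift of the held-out risk
curve, which grows with the number of competing base-learners and the
number of subsampling folds; with only 10 pathways and 10 folds the tuner
lands on small positive $m_{stop}$ more often than at 20+ pathways with
20 folds, where empty models dominate. The package's acceptance runs
therefore keep the protocol parameters (20 folds, $m_{max} = 200$,
$n = 1000$) at their standard values and reduce only the pathway and
replicate counts.

## Limitations

* The offset model is deliberately simple (unpenalized logistic
  regression); high-dimensional covariate sets need upstream reduction.
* Competing (selectable) covariate base-learners are not implemented;
  covariates are mandatory offset effects.
* Kernels are held densely in memory; $n$ in the tens of thousands calls
  for the reduced-rank (knot-based) approximation, which is out of scope
  here.
* The LKMT p-value is a moment-matching approximation; far-tail p-values
  are less accurate than exact mixture inversions.
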
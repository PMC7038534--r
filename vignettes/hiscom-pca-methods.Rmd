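---
title: "Hierarchical structural component pathway analysis: model, numerics, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical structural component pathway analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiscompca)
```

## The problem and the model

Genome-wide association scans test one SNP at a time; the hits are hard to
interpret and explain little heritability. Gene-set (pathway) methods
aggregate signal, but most work from single-SNP summary statistics and
treat pathways one at a time, ignoring the strong correlations between
genes and between pathways (shared genes, linkage disequilibrium).

`hiscompca` instead fits **one joint model over all pathways** from raw
dosages. It has two layers:

**Layer 1 — gene summarization.** The SNPs assigned to a gene (within the
gene body ± a 20 kb window, both boundaries inclusive) are centered,
scaled to unit variance, and decomposed by PCA (`stats::prcomp`, i.e. SVD).
The retained PCs are the gene-level scores $g_{kti}$. Two selection rules
are offered, matching common practice: keep only the first PC
(`first_pc`), or keep the smallest leading set whose cumulative variance
proportion strictly exceeds 30% (`cumvar`). The strict reading of "more
than 30%" means proportions $(0.5, 0.3, 0.2)$ keep one PC and
$(0.2, 0.15, 0.65)$ keep two; the minimal-crossing-set interpretation was
chosen because it reproduces the behaviour that one gene can contribute
several PCs while a dominant first PC contributes exactly one.

**Layer 2 — hierarchical component GLM.** With pathway coefficients
$\beta_k$, gene-PC weights $w_{kti}$, and unpenalized covariates $x_j$
(age, sex, BMI and the like):

$$g\!\left(\mathrm{E}[y_j]\right) = \beta_0 + \sum_{k=1}^{K}
\Big[\sum_{t=1}^{T_k}\sum_{i=1}^{N_{kt}} g_{ktij}\, w_{kti}\Big]\beta_k
+ x_j^\top\gamma,$$

with the logit link for binary traits and identity for continuous ones.
The inner sum is a latent per-subject *pathway score*
(`pathway_scores()`); $\beta_k$ is the effect of that score on the
phenotype. A gene belonging to several pathways contributes its PC columns
to each pathway block with **pathway-specific weights** — the weight is
indexed by $(k, t, i)$, not by gene alone — which is what lets the joint
model apportion shared-gene signal between correlated pathways.

Estimation maximizes the ridge-penalized log-likelihood

$$\phi = \sum_{j=1}^N \log p(y_j;\gamma_j,\delta)
  \;-\; \tfrac{1}{2}\lambda_g \sum_{k,t,i} w_{kti}^2
  \;-\; \tfrac{1}{2}\lambda_p \sum_k \beta_k^2 .$$

The two ridge terms control the multicollinearity within and between the
two layers; the intercept and covariate effects are never penalized, since
the penalty names only the weights and the pathway coefficients.

## The alternating least squares fitter

$\phi$ is bilinear in $(w, \beta)$, so it is maximized by alternating two
conditional GLM problems:

* **Half-step 1** (weights fixed): regress $y$ on the $K$ latent pathway
  scores plus intercept and covariates, ridge $\lambda_p$ on the pathway
  coefficients only.
* **Half-step 2** (pathway coefficients fixed): the predictor is linear in
  $w$ with regressors $g_{ktij}\beta_k$; regress with ridge $\lambda_g$ on
  the weights, intercept and covariates refit.

For the gaussian family each half-step is an exact penalized
least-squares solve, so $\phi$ is monotone non-decreasing by construction.
For the binomial family each half-step maximizes its conditional penalized
logistic likelihood by quadratic majorization with the constant curvature
bound $M^\top M/4$ (the logistic variance never exceeds 1/4), factored
once per half-step; every ascent step is additionally guarded by
step-halving against $\phi$, so the monotonicity property holds for both
families. Both half-steps operate on precomputed cross-products of the
augmented design, which makes a gaussian refit essentially independent of
the sample size — the property that makes permutation inference with
thousands of refits practical.

Numerical choices:

* **Convergence**: largest absolute parameter change over a full
  iteration $< 10^{-5}$, or $|\Delta\phi| < 10^{-5}$. The fitter's default
  cap is 100 iterations; the permutation, cross-validation and experiment
  layers default to 500 because null-permuted refits of large, strongly
  penalized-yet-weakly-identified designs approach the optimum along a
  slow geometric tail. Non-converged permutation refits are excluded and
  counted; more than 5% is an error.
* **Initialization** is deterministic by default: within each pathway
  block all weights equal with unit block norm ($1/\sqrt{P_k}$), pathway
  coefficients zero, intercept at the null-model value. Deterministic
  starts make every permutation refit reproducible and comparable; a
  seeded random start is available.
* **Sign convention**: $(w_k, \beta_k) \mapsto (-w_k, -\beta_k)$ leaves
  the model invariant, so after convergence the largest-magnitude weight
  in each block is made positive. The same convention (largest-|loading|
  positive) fixes PC signs, making the whole pipeline bit-reproducible.
* **Scale convention**: $(c\,w_k, \beta_k/c)$ also leaves the linear
  predictor invariant; the pair of ridge penalties resolves the split at
  the optimum, so no explicit unit-variance constraint is imposed on the
  latent scores. A GSCA-style normalization constraint would be an
  alternative reading; the unconstrained-with-penalties form follows the
  penalized likelihood as written. At $\lambda_g = \lambda_p = 0$ the
  split (not the product) is undetermined, which is harmless for
  inference on $|\beta_k|$ only because that configuration is used only
  for oracle comparisons against ordinary GLM slopes.
* **Gaussian dispersion** $\delta$ is held at 1 inside the iteration
  (each half-step is then exactly penalized least squares and the traced
  $\phi$ is monotone); the residual mean square is reported as the
  dispersion estimate after convergence. Profiling $\delta$ per iteration
  would not change the maximizer for fixed penalties.
* **Degenerate inputs**: an exactly collinear system at zero penalty
  raises an error advising positive penalties; constant SNP columns are
  dropped before PCA with a warning; all-constant genes are dropped.

## Inference

The pathway statistic is $|\beta_k|$ from the fit on the observed
phenotype; the gene statistic is $\max_i |w_{kti}\,\beta_k|$ over the
gene's PCs within its pathway (the maximum preserves single-PC behaviour).
The null distribution comes from refitting the **entire model from
scratch** — same configuration, same deterministic start — on $B$
uniformly permuted phenotype vectors (covariate rows are not permuted).
P-values use the add-one estimator $p = (1 + \#\{b : |\beta^{(b)}_k| \ge
|\beta_k|\})/(B+1)$, which is valid and never zero; q-values are
Benjamini–Hochberg. A Freedman–Lane residual-permutation variant is
provided for gaussian covariate-confounded designs. The magnitude
statistic is deliberately unstudentized: the model exposes no analytic
variance estimator for $\beta_k$, and the permutation null calibrates the
statistic's scale by construction.

Reusing the observed weights in permuted refits would anti-conservatively
shrink the null (the weights are themselves fitted to the observed
phenotype), which is why every refit re-estimates both layers.

## Penalty tuning

`hiscom_cv()` selects $(\lambda_g, \lambda_p)$ over a log-spaced grid
(default $\{0.01, 0.1, 1, 10, 100, 1000\}$ for each) by k-fold (default
5-fold) cross-validation on held-out negative log-likelihood
(deviance/2), folds stratified by outcome class for binary traits, ties
broken toward the heavier penalty. The held-out likelihood respects both
families uniformly, unlike misclassification loss. The experiment layer
defaults to fixed $\lambda_g = \lambda_p = 1$ rather than per-replicate
CV: at the simulated scales the rejection decision is driven by the
permutation ranking, which is largely invariant to the penalty level, and
per-replicate CV would multiply the cost of each experiment by the grid
size times the fold count.

## The simulator and the validation experiments

`simulate_study()` generates the structure the validation experiments
need: `n_samples` individuals, `n_pathways` disjoint pathways of
`genes_per_pathway` genes, one causal pathway whose first `n_causal_genes`
genes drive a continuous trait additively,

$$y_j = \sum_{s \in \text{causal SNPs}} b\,\tilde d_{js} + \varepsilon_j,
\qquad \varepsilon_j \sim N(0, \sigma^2),$$

with standardized dosages $\tilde d$, per-SNP effect `effect_size`, and a
median-dichotomized binary version (ties at the median coded 0). Dosages
are drawn per gene from a Gaussian copula with exchangeable latent
correlation `ld_rho` on two haplotype layers, thresholded at each SNP's
MAF, so marginals are exactly Hardy–Weinberg Binomial(2, MAF) while SNPs
within a gene carry tunable LD; genes are independent. Defaults mirror the
mini-exome design the experiments emulate: 697 individuals, 168 pathways,
9 causal genes in one pathway, MAFs uniform on (0.05, 0.5].

What the simulator does **not** emulate: realistic LD block structure and
inter-gene LD, population stratification, relatedness, genotyping error,
rare variants, non-additive effects, and overlapping pathway membership
(available via construction but not defaulted). Passing calibration and
power checks on these synthetic data therefore demonstrates the
statistical machinery — not robustness to confounding in real cohorts,
where covariates and QC must do that work.

`run_type1_experiment()` tracks a **size-matched null pathway** (same gene
count as the causal pathway) while any causal effects stay active
elsewhere — with all effects zero it is the clean calibration variant —
and `run_power_experiment()` tracks the causal pathway. Genotypes and the
design are simulated once and the phenotype is redrawn per replicate,
matching the fixed-genotype/replicated-phenotype structure of the
reference design. A replicate rejects when the tracked pathway's
permutation p-value is strictly below $\alpha$; with $B = 99$ and
$\alpha = 0.05$ the achievable null rejection probability on the p-value
grid $\{1/100, \dots, 1\}$ is exactly 0.04, slightly conservative, which
is the expected behaviour of add-one permutation p-values at finite $B$.

Problem sizes used in the shipped checks (the package's own choice of a
desk-scale rendition of the full design): type-I calibration at $n = 300$,
20 pathways of 3 genes, $B = 99$, 200 Monte-Carlo replicates; power at
$n = 697$, 9 causal genes with standardized per-SNP effect 0.5, 20
pathways, $B = 99$, 100 replicates, both phenotype types. The full-scale
mode (168 pathways, 200 replicates, $B = 1000$) is a documented
long-running configuration of the same functions.

## Quality control and formats

The QC rules follow standard SNP-chip practice: exclude SNPs with MAF
$\le 0.05$ (the boundary itself excluded, as printed), genotype call rate
$< 95\%$, exact Hardy–Weinberg p-value $< 10^{-6}$; keep samples with call
rate strictly $> 90\%$; a precomputed sex-inconsistency exclusion list can
be supplied (the package does not recompute X-heterozygosity). The HWE
test is the exact conditional test computed by the stable recurrence over
heterozygote counts — exact is well-defined at low counts where the
chi-square approximation is not. Attribution of a removed SNP follows the
fixed order call rate → MAF → HWE, but the surviving set is
order-independent. Residual missing dosages are imputed by the per-SNP
mean of observed dosages — a deliberately simple, single-operation
replacement for haplotype-based imputation, tolerable downstream because
PCA accepts continuous dosages. Covariates are not standardized by
default; a flag on the reader's output matrix is left to the user since
ridge penalties never touch covariate coefficients.

File formats are the field's: PLINK 1 binary (SNP-major BED v1.00, the
counted allele is BIM A1, missing is `NA` and never 0), GMT gene sets,
4-column gene annotation TSV, phenotype/covariate TSV. The simulator can
emit a complete study in these formats (`write_study()`), so it doubles as
a fixture generator for the readers.

## Known limitations

* The permutation test is the only inference route; no asymptotic
  approximation is provided, so cost scales linearly in $B$ times the
  refit cost.
* Gene-level p-values test the product $|w\,\beta|$; a direct test of $w$
  alone would need a different normalization and is isolated behind one
  internal function if that choice is revisited.
* The conditional/stepwise pathway-selection mode and rare-variant
  collapsing are out of scope.
* Mean-dosage imputation is biased toward the major allele for SNPs with
  substantial missingness; QC thresholds keep that missingness below 5%.
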
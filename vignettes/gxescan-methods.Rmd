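---
title: "Gene-based gene-environment interaction testing with penalized latent components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based gene-environment interaction testing with penalized latent components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-SNP tests of gene-environment interaction (G×E) are underpowered:
interaction effects are small, the multiple-testing burden across a GWAS is
enormous, and linkage disequilibrium (LD) spreads any real signal across
neighboring variants. Gene-based tests aggregate the SNPs of a gene into
one hypothesis, recovering power and easing interpretation. `gxescan`
implements a latent-component estimator of a gene-level interaction effect
for quantitative traits, its permutation test, four p-value-combination
competitor tests, and the simulation machinery to study all of them.

## The model

For subject $i$ with genotypes $x_{i1},\dots,x_{iK}$ (additive coding,
standardized per column), environment $z_i$ and covariates $c_{ip}$, the
model collapses the gene into a latent component and forms a latent
interaction:

$$g_i = \sum_{k=1}^K w_k x_{ik}, \qquad e_i = w_E z_i, \qquad r_i = g_i e_i,$$

$$y_i = \beta_1 g_i + \beta_2 e_i + \beta_{12} r_i + \sum_p \beta_p c_{ip} + \varepsilon_i,$$

subject to the standardization constraints $\sum_i g_i^2 = \sum_i e_i^2 =
\sum_i r_i^2 = N$. Estimation minimizes the penalized least-squares
objective

$$\phi = SS(y - \hat y) + \lambda_S\, SS(W) + \lambda_S\, SS(B),$$

by alternating least squares (ALS): path coefficients $B$ given the
latents, then SNP weights $w$ given $B$ (the model is linear in $w$ with
design columns $\beta_1 x_k + \beta_{12} x_k e$). The ridge penalty
$\lambda_S$ tames the LD-induced collinearity among the gene's SNPs and is
chosen by five-fold cross-validation over 15 evenly spaced values on
$[0, 0.5]$, with ties broken toward the larger (more stable) penalty. The
gene-level interaction test is $H_0\!: \beta_{12} = 0$, assessed by
permutation (below).

### Design choices in the estimator

Several details of this model family are genuinely open; the package's
choices, and why:

* **Penalty structure.** A single $\lambda_S$ penalizes both the weights
  $W$ and the path coefficients $B$; this matches the one-parameter
  cross-validation the model family uses. The weights-only variant is kept
  behind `penalize_b = FALSE`.
* **Internal parameterization.** The objective is optimized with
  unnormalized latents ($g = Xw$, $r = g e$ elementwise, $e$ the
  standardized environment) and the constraints are imposed afterwards by a
  joint rescaling of $(w, \beta_1, \beta_{12})$ that leaves fitted values
  unchanged. Each ALS block step is then an exact penalized least-squares
  solve, so the objective trace is non-increasing by construction —
  renormalizing inside every iteration would break that, because the ridge
  penalty is not scale-invariant. With $\lambda_S > 0$ the penalty itself
  resolves the scale split between $w$ and $\beta_1$.
* **Intercept.** The linear predictor carries an unpenalized intercept.
  $r = g e$ is a product of centered variables and has mean
  $\operatorname{cor}(g, e) \ne 0$ in general; without an intercept the
  model cannot reproduce even noiseless data generated from itself.
* **Identifiability.** With a single environment variable the constraint
  $\sum e_i^2 = N$ forces $w_E = \pm\sqrt{N / \sum z_i^2}$; the positive
  root is fixed, so $e$ is simply the standardized environment and the
  reported $w_E$ carries no free information. The reflection indeterminacy
  of $(w, \beta_1, \beta_{12})$ is resolved by flipping signs so that
  $\sum_k w_k > 0$ ($w_1 > 0$ on an exact tie).
* **Multi-start.** The objective is bilinear in $(w, B)$ and can have
  local optima (observed on roughly 1 in 20 small random instances from a
  single start). `gxe_fit()` therefore runs ALS from a small deterministic
  set of starts — the uniform $1/\sqrt K$ vector plus coordinate and
  alternating-sign directions — and keeps the lowest objective.
  Determinism is preserved without any RNG; `init = "random"` appends
  seeded random starts.
* **Convergence.** Relative change of $\phi$ below $10^{-6}$, at most 1000
  iterations. Cross-validation warm-starts each $\lambda$ from the
  previous one's solution (the solution path is continuous in $\lambda$),
  which changes nothing statistically and saves most of the fitting time.

## Permutation inference

The null $\beta_{12} = 0$ is *composite*: gene and environment main
effects may be real. That matters for how the null distribution is
generated.

* Permuting the raw phenotype destroys the main effects together with the
  interaction. The weights are then re-estimated on pure noise in every
  replicate and are free to chase apparent interaction structure, so the
  permuted $|\beta_{12}^*|$ are stochastically *larger* than the sampling
  distribution of the observed statistic under the composite null. In a
  simulation with a real gene main effect this made the raw-permutation
  test reject essentially never (and studentizing the statistic does not
  repair it, because the distortion comes from the adaptive weights, not
  the residual scale).
* The default scheme is therefore **Freedman-Lane**: fit the reduced model
  without the interaction component ($y = \beta_1 g + \beta_2 e + \beta_0 +
  C\beta_p$, same ALS machinery), permute its residuals (rescaled by
  $\sqrt{N/(N - \mathrm{df})}$ for the degrees of freedom the reduced fit
  consumed), add them back onto the reduced fitted values, and refit the
  full model. Under the composite null with real main effects this is well
  calibrated (the acceptance suite verifies rejection rates inside exact
  binomial bounds). At the *global* null of no association whatsoever it
  is slightly liberal in the middle of the p-value distribution — there the
  raw-phenotype scheme (`scheme = "phenotype"`) is exactly valid by
  exchangeability, and that is the scheme the uniformity unit test
  exercises.
* The statistic is the two-sided $|\beta_{12}|$ on the constraint scale;
  the p-value uses the add-one estimator $p = (1 + \#\{|\beta_{12}^*| \ge
  |\beta_{12}|\})/(1 + B)$, so ties count against rejection and $p \ge
  1/(B+1)$.
* $\lambda_S$ is held at the cross-validated value of the observed fit
  rather than re-cross-validated per permutation: re-selecting the penalty
  inside every replicate would change the meaning of the statistic and
  multiply the cost by the grid size.
* Every permutation refit starts from the observed solution's weights.
  This is one fixed deterministic map applied to the identity arrangement
  and to every permuted arrangement alike (on the observed phenotype it
  returns the observed fit), so the statistic is computed symmetrically.
* Across genes, Benjamini-Hochberg q-values (`bh_qvalues()`) and the
  Bonferroni threshold $\alpha / \#\text{genes}$ are reported.

## Competitor tests

For benchmarking, the package implements the four classical
p-value-combination gene-level tests on top of single-SNP interaction
regressions ($y \sim 1 + x_k + z + x_k z + C$, two-sided t-test on the
product term):

* **minP**: $1 - (1 - \min_j p_j)^{M_e}$ with $M_e$ the effective number
  of tests from the eigenvalues of the genotype correlation matrix
  (integer part indicator plus fractional part, clamped to $[1, K]$;
  eigenvalues are rounded before the floor to keep $4 - 10^{-15}$ from
  contributing a spurious fractional part).
* **GATES** (extended Simes): $\min_j M_e p_{(j)} / M_{e(j)}$, with
  effective numbers computed by default on the p-value correlation matrix
  approximated from genotype correlations by the published sixth-order
  polynomial (`corr = "genotype"` switches to the genotype matrix
  directly).
* **Truncated tail strength** and **truncated product** at $\tau = 0.05$
  (the conventional truncation point; configurable). Analytic nulls under
  LD are unavailable, so both are referred to phenotype-permutation
  replicates of the SNP-level scans, sharing one permutation set. Raw
  phenotype permutation is appropriate here: the SNP-level t-statistics
  are pivotal, so destroying the main effects does not distort the null of
  the p-value vector. Note these two statistics equal exactly zero (tail
  strength) or one (product) whenever no SNP p-value passes $\tau$, which
  happens for most null genes; their permutation p-values therefore carry
  an atom near 1 and are *sub*-uniform, while remaining calibrated in the
  rejection tail — a whole-distribution uniformity check would be the
  wrong test for them.

## The synthetic-data generator

Real cohort genotypes cannot be redistributed, so the simulation module
generates LD-structured common variants from a Gaussian copula: two
independent haplotype draws per subject from an AR(1)-correlated latent
normal field ($\operatorname{corr} = \rho^{|j-k|}$), each column
thresholded at the normal quantile of its minor allele frequency, then
summed. Marginals follow Hardy-Weinberg proportions exactly in
expectation; adjacent SNPs show LD that decays with distance. What this
does *not* emulate: haplotype-block boundaries, MAF-dependent LD, rare
variants, genotyping error — so passing tests demonstrate correct behavior
under smooth AR(1) LD, not under every real-data LD pattern.

Phenotypes follow

$$y_i = \beta_0 + \beta_1 \textstyle\sum_k w_k x_{ik} + \beta_2 e_i +
\beta_{12} (\sum_k w_k x_{ik}) e_i + \varepsilon_i,
\qquad \varepsilon_i \sim N(0,1),$$

with $w_k = 0.5$ on a causal subset of $\mathrm{round}(0.2 K)$ SNPs
(minimum 1) and 0 elsewhere, raw 0/1/2 codes $x_{ik}$, and $e_i$ the
standardized environment. Defaults chosen once for the study conditions:
$\beta_0 = 0$, $\beta_1 = 1$, $\beta_2 = 1$, environment standard normal
(Bernoulli(0.5) available), AR(1) $\rho = 0.5$, per-SNP MAF drawn
uniformly on $[0.05, 0.4]$. Effect grids stop at 1 because beyond that all
methods saturate. Every dataset is bit-exactly reproducible from its
config and seed.

## Experiment harnesses and problem sizes

`type1_experiment()` and `power_experiment()` are method-agnostic: any
`function(data, seed)` returning one p-value plugs in, and the bundled
adaptors wrap the latent-component test and the four combiners. Rejection
fractions come with exact Clopper-Pearson intervals.

The package's own acceptance checks run at desk scale — 200 Monte-Carlo
datasets with 199 permutations each, $N = 500$, $K = 5$ (full-scale
studies of this design use 1000 datasets and thousands of permutations;
the exact binomial bands in the tests account for the Monte-Carlo width at
200). Type-I error is checked against the exact binomial 99% interval
around each nominal level; power is checked for monotone increase over
$\beta_{12} \in \{0.5, 0.7, 0.9\}$ with a margin criterion in Monte-Carlo
standard errors.

## Numerical details and degenerate inputs

* Standardization uses population (1/N) variance so the constraints hold
  exactly; zero-variance genotype columns are an error in `gxe_fit()` and
  are dropped per fold (with a message) in cross-validation.
* Missing genotypes are mean-imputed per column after QC filtering
  (MAF $> 0.01$, missingness $\le 5\%$, exact Hardy-Weinberg $p >
  10^{-6}$); imputation preserves observed column means exactly, and the
  QC step is idempotent because HWE counts only whole-number codes.
* The exact HWE test enumerates the conditional distribution of the
  heterozygote count in log space; ties at the observed probability are
  included in the p-value (two-sided convention).
* A collinear single-SNP interaction design returns $p = 1$ with a
  warning rather than failing a whole scan.
* `map_snps_to_genes()` treats the flank boundaries inclusively
  ($\text{start} - 20\,\text{kb} \le \text{pos} \le \text{end} +
  20\,\text{kb}$), converts BED input from 0-based half-open coordinates
  on read, ignores strand (flanks are symmetric), and allows one SNP to
  belong to several genes.
* Per-gene RNG streams in `gxe_scan()` are derived from the master seed
  and the gene id, so results do not depend on gene processing order.

## Known limitations

* Quantitative traits only; no GLM link for binary or count outcomes.
* One environment variable per model; one gene per fit (no pathway
  hierarchy).
* Freedman-Lane inference is approximate at very small $N$ and at the
  global null (see above); the raw-permutation scheme is available where
  exactness under total exchangeability is wanted.
* Variance-component kernel competitors (GESAT/iSKAT-style) are out of
  scope; externally computed p-value tables can be joined to scan output.
* Genotype imputation, phasing, multi-allelic variants and sex-chromosome
  handling are out of scope.
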
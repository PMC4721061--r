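---
title: "Variance-component models and association scans for family EWAS/GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-component models and association scans for family EWAS/GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famews)
```

## The problem

Extended families are a powerful design for dissecting a phenotype such as
hypertriglyceridemic waist (HTGW) — elevated waist circumference combined
with elevated fasting triglycerides — because relatedness lets the analysis
separate additive genetic variance from environmental variance, decompose
the correlation between two traits into genetic and environmental sharing,
and run marker-level association scans (DNA methylation or SNPs) that are
protected against confounding by family structure. `famews` implements the
whole flow: pedigree relationship matrices, polygenic variance-component
models for continuous and binary (liability) traits, bivariate
decomposition, EWAS/GWAS scan machinery with the usual QC filters and
multiple-testing corrections, mediation and model-comparison follow-ups,
and cross-platform agreement statistics. A synthetic-data generator with
the same statistical structure makes every stage testable without access
to cohort data.

## The polygenic model

For a quantitative trait on $n$ pedigree members,

$$ y = X b + g + e, \qquad
   g \sim \mathcal N(0, \sigma^2_g A), \qquad
   e \sim \mathcal N(0, \sigma^2_e I), $$

where $A$ is the additive genetic relationship matrix (twice the kinship
matrix, built by the recursive tabular method in
`relationship_matrix()`), and heritability is
$h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$.

`fit_polygenic()` maximizes the exact Gaussian likelihood. Numerically, $A$
is eigendecomposed once ($A = U D U'$); rotating $y$ and $X$ by $U'$
diagonalizes the covariance so that, for a candidate $h^2$, the fixed
effects and the total variance are profiled out by weighted least squares
in $O(np^2)$. The remaining one-dimensional profile likelihood in $h^2$ is
maximized over a coarse grid (step 0.05, which serves as a multi-start)
followed by golden-section refinement on the bracketing interval, with
tolerance $10^{-8}$ on the log-likelihood and $h^2$ box-constrained to
$[0, 0.9999]$ so $\sigma^2_e$ stays positive. The same rotated quantities
are reused by every per-marker fit in a scan, which is what makes
epigenome-scale scans affordable; the package's tests verify that the
rotated likelihood equals a dense matrix evaluation to $10^{-8}$.

ML rather than REML is used deliberately: fixed effects are tested by
likelihood-ratio statistics between nested models (marker included versus
excluded, with variance components re-estimated under each), and REML
likelihoods are not comparable across different fixed-effect structures.
The zero-heritability test compares against the $\sigma^2_g = 0$ fit and
uses the boundary null distribution
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (`vc_mixture_p()`); fixed-effect
tests use $\chi^2_1$.

### Binary traits on the liability scale

A binary trait is modeled as the indicator of a latent standard-normal
liability exceeding the threshold $t = \Phi^{-1}(1 - K)$, with the
polygenic covariance on the liability scale. Exact maximum likelihood for
this model requires $n$-dimensional normal orthant probabilities, which is
not tractable at scan scale, so the package fits the linear mixed model to
the 0/1 indicator on the observed scale and transforms the estimates to
the liability scale with the classical threshold-model conversion:

$$ h^2_{\text{liability}} = h^2_{\text{observed}}
   \frac{K(1-K)}{\varphi(t)^2}, \qquad
   b_{\text{liability}} = \frac{b_{\text{observed}}}{\varphi(t)} .$$

Likelihood-ratio statistics are taken from the observed-scale fits. This
choice trades exactness for a single fast engine shared by single fits and
per-marker scans; its adequacy is established empirically rather than
assumed — the test suite checks that generative liability heritabilities
are recovered and that the null distributions of the LRTs hold their size.
The prevalence-implied threshold is by construction within sampling error
of the generative prevalence. The odds ratio for a liability-scale
coefficient uses $\mathrm{OR} = e^{\sqrt{\pi}\, b}$ with $b$ oriented so
that positive values increase risk (this orientation is what reproduces
published odds ratios such as $b = 0.65 \rightarrow \mathrm{OR} = 3.16$;
the transform is sometimes printed with a negative exponent under the
opposite orientation of $b$).

## Bivariate decomposition

For two traits the genetic covariance is
$\rho_G \sqrt{\sigma^2_{g_i}\sigma^2_{g_j}}\, A$ and the environmental
covariance $\rho_E \sqrt{\sigma^2_{e_i}\sigma^2_{e_j}}\, I$. After the same
eigenrotation the likelihood factorizes into $n$ bivariate Gaussian terms
with $2\times2$ covariances $d_k \Sigma_G + \Sigma_E$, so each evaluation
is $O(np^2)$ with closed-form $2\times2$ inverses and jointly profiled
fixed effects. Heritabilities are searched on the logit scale and
correlations on the atanh scale so the optimizer (Nelder-Mead with a BFGS
polish) stays interior; infeasible proposals (non-positive-definite
implied covariance) are rejected. The implied phenotypic correlation

$$ \rho_P = \rho_G\sqrt{h_i^2 h_j^2}
          + \rho_E\sqrt{(1-h_i^2)(1-h_j^2)} $$

is computed from the fitted components — it holds on every returned fit by
construction — and the raw residual Pearson correlation after covariate
adjustment is reported alongside, since both are conventionally quoted.
Tests of $\rho_G = 0$ and $\rho_E = 0$ are constrained LRTs. With low
heritabilities the genetic correlation is weakly identified (its LRT can
be flat); this is a property of the design, not of the implementation.

## Scan machinery

`association_scan()` tests every marker (inverse-normalized methylation
beta values, or additive dosages) as a fixed effect in the polygenic
model. The supporting operations follow fixed conventions:

* `inverse_normal()` — ranks (average ranks for ties), cumulative
  densities with the symmetric offset $(r - 0.5)/n$, then standard-normal
  quantiles. The offset keeps the transform bounded away from $\pm\infty$
  and exactly symmetric.
* `filter_probes()` — staged exclusions in a fixed order (sex-chromosome
  probes, non-CpG probes, SNP-assay probes, convergence failures,
  detection failures with *strict* inequalities: detection $p > 0.01$ in
  $> 5\%$ of samples), reporting the count after every stage.
* `filter_snps()` — call rate $\ge 0.97$, MAF $\ge 0.05$, and
  Hardy-Weinberg exact-test $p \ge 0.001$. HWE is computed on founders
  only, because genotype frequencies among relatives do not follow the
  random-mating sampling model; the exact (Levene-Haldane enumeration)
  test is used since array QC routinely involves MAF-boundary SNPs where
  the chi-square approximation misbehaves.
* `genomic_inflation()` — $\lambda_{\text{median}}$, the median
  association $\chi^2$ divided by the $\chi^2_1$ median ($\approx0.455$).
* `correct_inflation()` — divides the $\chi^2$ statistics by $\lambda$
  and maps back to p-values, but **only when $\lambda > 1$**. Dividing by
  a deflation factor ($\lambda < 1$) would manufacture significance, so
  deflated scans keep their nominal p-values. This mirrors how deflated
  genomic-control factors are conventionally reported but not "corrected"
  for.
* `bh_fdr()` — Benjamini-Hochberg step-up q-values via
  `stats::p.adjust`.

Markers whose model fails to converge are recorded on a failure list and
excluded from the corrected set, never silently dropped; the pipeline
folds them into the probe-filter stage counts.

## Follow-up analyses

`sobel_mediation()` quantifies the indirect path
site $\to$ mediator $\to$ outcome as the product of the two path
coefficients from two polygenic models, with the delta-method standard
error $\sqrt{a^2 s_b^2 + b^2 s_a^2}$ and a normal p-value (no bootstrap —
the classical Sobel test). `kl_r2()` is the likelihood-ratio pseudo
R-squared $1 - e^{-2\Delta\ell/n}$, chosen because it reduces exactly to
the OLS R-squared for Gaussian linear models — that equivalence is both
its justification and its test. `stepwise_kl()` builds the forward ladder
base, base+site$_1$, base+site$_1$+site$_2$, ... with per-step increments
and LRT p-values; increments sum exactly to the total gain.

`bland_altman()`, `pitman_test()` and `spearman_corr()` support
cross-platform validation of methylation measurements. Limits of agreement
use the 1.96 multiplier (consistent with published limits of the kind
$-0.062 \pm 0.040$), differences are oriented method2 $-$ method1, and
Pitman's test is the $t$-test on the correlation between pair differences
and pair sums.

## What the synthetic cohort emulates

`sim_config()` defaults describe the study conditions the pipeline was
built around: 39 three-generation extended families totalling 850
individuals; a binary focal phenotype with liability heritability 0.52 and
prevalence 0.26; a waist/triglyceride pair with
$(h_i^2, h_j^2, \rho_G, \rho_E) = (0.3, 0.2, 0.07, 0.32)$; methylation
probes whose planted effects produce 1-2 percentage-point median
beta-value differences between phenotype groups; chip/position batch
structure (12 positions per chip) and five-component leukocyte fractions
(CD4+, CD8+, B, NK, granulocytes) from a Dirichlet prior; and SNP dosages
generated by Mendelian gene dropping from founder allele frequencies.
Methylation effects are planted on the logit scale and mapped through the
inverse logit, because beta values are bounded in $[0,1]$; effect sizes
are specified as target median beta differences, the scale on which array
effect sizes are reported. The binary threshold uses the empirical
quantile of the simulated liability rather than the normal quantile, so
the realized prevalence is controlled exactly at finite $n$. Clinical
covariates (age, BMI, blood pressures) use normal marginals with plausible
means and spreads; no claim of distributional realism is made for them.

Deliberately **not** emulated: linkage disequilibrium between SNPs,
Infinium I/II probe-chemistry differences and within-array normalization
(inputs are assumed normalized), cell-type deconvolution from the beta
matrix itself (fractions enter as covariates), and population admixture
beyond what divergent founder frequencies induce. Consequently, passing
calibration on synthetic data shows the estimators and their null
distributions behave as designed under the assumed model; it does not
certify behavior under array artifacts or LD structure absent from the
generator.

## Problem sizes and numerical conventions in the test suite

Parameter-recovery checks run at the study scale (39 families, ~850
individuals, 50 replicates per setting). Calibration of the null scan
statistics uses 500 reduced scans (10 families, ~220 individuals, 60
probes each) — sizes chosen so the whole suite runs in a couple of minutes
while leaving Monte-Carlo error well inside the asserted bands. Where a
single finite-sample quantity is intrinsically noisy (a group median
difference, a weakly identified genetic correlation), tests average a
handful of replicates rather than widening the assertion.

Degenerate inputs follow fixed conventions: two-individual pedigrees give
flagged (non-converged) boundary fits rather than errors; an all-zero
focal covariate returns coefficient 0 with p = 1; constant vectors are
errors for rank-based transforms and correlations; monomorphic SNPs have
HWE p = 1 and are removed by the MAF filter; empty marker sets return
empty but well-formed scan results.

## Known limitations

* The liability-scale transformation is a first-order approximation; with
  very high relatedness and extreme prevalences it can be mildly biased
  (the recovery tests bound this at the emulated design).
* The bivariate model covers continuous trait pairs only, matching its
  use for waist/triglycerides; binary-binary liability pairs are out of
  scope.
* Composite hypotheses about medication are handled operationally
  (adjust / ignore / exclude-medicated run modes), not causally.
* `stepwise_kl()` takes the site order as given (typically significance
  order); it does not search over orders.
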
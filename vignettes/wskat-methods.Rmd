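---
title: "Methods: weighted SNP-set kernel association testing with spectral decorrelation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted SNP-set kernel association testing with spectral decorrelation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wskat)
```

## The statistical problem

Single-variant association scans lose power when a trait is driven by many
variants of individually small effect scattered across a gene. Set-based
kernel tests pool the evidence: for each gene, all variants in a window
around it are tested jointly through a variance-component score statistic.
`wskat` implements such a test with two additions:

1. **Functional variant weights.** Each variant can carry a nonnegative
   weight from an external functional source (conservation scores,
   regulatory annotations, QTL evidence). Weighted variants contribute
   proportionally more similarity between samples that share their
   alleles, concentrating power on variants more likely to be functional.
2. **Spectral decorrelation.** Population structure and cryptic
   relatedness inflate set-based statistics genome-wide. `wskat` removes
   this by whitening the phenotype with a transform built from the
   spectrum of the genomic relationship matrix (GRM) and restricted
   maximum likelihood (REML) variance components.

## Model

For $n$ samples and a gene's $p$ variants with dosage matrix $X$
($n \times p$, dosages $0/1/2$) and weights $w \ge 0$, the **weighted
linear kernel** is

$$K_w = \frac{1}{p}\, X\, \mathrm{diag}(w)\, X^\top .$$

With null-model residuals $r$ (intercept plus optional covariates; linear
regression for quantitative traits, logistic for case–control), the test
statistic is the quadratic form

$$Q = r^\top K_w\, r .$$

Under the null, $Q$ is distributed as $\sum_i \lambda_i \chi^2_{1,i}$,
where $\lambda_i$ are the eigenvalues of
$V^{1/2} P_0 K_w P_0 V^{1/2}$: $V$ is the diagonal matrix of per-sample
null variances and $P_0$ the projector orthogonal to the
variance-weighted null design. The implementation computes the identical
nonzero spectrum from the $p' \times p'$ weighted Gram matrix, which
avoids an $n \times n$ eigendecomposition per gene.

Negative raw weights (e.g. evolutionary *acceleration* scores, which are
negative by convention) are rectified by absolute value so that $K_w$
stays positive semidefinite; variants absent from the weight table
default to weight 1, so an empty table reduces the method to the standard
unweighted linear-kernel score test.

### Exact p-values for the mixture

`pvalue_from_mixture()` inverts the characteristic function of
$\sum_i \lambda_i \chi^2_{1,i}$ (the Imhof integral). Plain adaptive
quadrature is unreliable here because the integrand oscillates with slow
amplitude decay, so the integrator is purpose-built:

- the head of the integral (up to the first phase zero-crossing) is
  handled by adaptive quadrature;
- the oscillatory tail is summed panel by panel between consecutive
  zero-crossings of the phase function, each panel integrated with 15-point
  Gauss–Legendre quadrature;
- the resulting alternating series is accelerated by iterated averaging,
  with convergence declared when either the raw terms or the accelerated
  estimate stabilize below the accuracy target ($10^{-9}$ by default).

Equal eigenvalues are dispatched to the closed form
$P(\chi^2_k > q/\bar\lambda)$. If the inversion fails to converge, the
method falls back to Liu–Tang–Zhang moment matching and flags the result
`"moment_matched"` instead of `"davies"`; callers can filter on the
`method` column. Results were validated to $\sim 10^{-9}$ against an
independently coded Ruben mixture-series implementation and large Monte
Carlo samples (see the test suite).

### Spectral decorrelation

The GRM is the VanRaden standardized estimator
$G = Z Z^\top / m$ with $Z$ the column-standardized dosage matrix over
all $m$ polymorphic genome-wide variants. With eigendecomposition
$G = U S U^\top$ and REML variance components $(\hat\sigma_g^2,
\hat\sigma_e^2)$ of the model
$\mathrm{Var}(Y) = \sigma_g^2 G + \sigma_e^2 I$, the whitening transform
is

$$D = (\hat\sigma_g^2 S + \hat\sigma_e^2 I)^{-1/2}\, U^\top ,$$

so that $D\,\mathrm{Var}(Y)\,D^\top = I$. The per-gene test then runs on
$\tilde y = D y$ and $\tilde X = D X$.

Two implementation decisions matter here:

- **The decorrelated null is Gaussian.** Even for case–control data the
  transformed phenotype is continuous, so the null model after
  decorrelation is always the linear (quantitative) one. This mirrors
  standard mixed-model GWAS practice of analysing 0/1 phenotypes on the
  observed scale.
- **Fixed effects must be transformed too.** After whitening, the
  intercept direction is $D\mathbf{1}$, which is *not* spanned by a raw
  constant column. The null design supplied to the decorrelated null
  model is therefore $D[\mathbf{1}, C]$ for covariates $C$. Projecting
  out a raw intercept instead leaves a mean component in the residuals
  and produces severe spurious inflation (this failure mode is guarded by
  the structure-correction acceptance test).

REML uses the exact one-dimensional profiling strategy: after projecting
the fixed effects out of $G$ and rotating into the eigenbasis of the
projected kernel, the restricted likelihood is a function of the single
ratio $\delta = \sigma_e^2/\sigma_g^2$, scanned on a 100-point grid of
$\log\delta \in [-10, 10]$ and refined by `optimize()`. Grid-edge optima
are treated as boundary solutions ($\hat\sigma_g^2 = 0$ at
$\delta \to \infty$); a (near-)isotropic GRM triggers a warning because
the two components are then not separately identifiable.

Numerical guards: GRM eigenvalues below zero (rounding) are clipped with
a message; mixture eigenvalues below $10^{-12}$ of the maximum are
dropped; $\hat\sigma_e^2$ is floored at $10^{-8}\,\mathrm{var}(y)$ so the
transform never divides by zero.

## Pipeline and defaults

A full run (`run_all()`, or `exec/wskat run --config config.yaml`) reads
a PLINK 1.9 binary trio, a variant-weight CSV
(`SNP_ID,Chromosome,Position,Weight`), a gene-regions CSV
(`Gene,Start,Stop,Chromosome`) and optionally a disease-gene reference
TSV, then for each gene:

1. expands the gene to a window of gene span $\pm$ `flank_size`
   (default **500,000 bp**, clamped at position 1);
2. collects window variants, mean-imputes missing dosages per variant,
   and drops monomorphic variants (genes with none left are reported
   untestable with a reason rather than dropped silently);
3. computes $Q$ and its exact mixture p-value.

Downstream diagnostics: genomic inflation factor
$\lambda_{GC} = \mathrm{median}(\chi^2_{obs}) / \mathrm{median}(\chi^2_1)$
with an inflation flag above 1.4, Bonferroni threshold $\alpha/n_{genes}$,
Benjamini–Hochberg q-values, the validation proportion (share of
significant genes present in the reference list, reported to one decimal
percent), and Manhattan/QQ figures. Outputs are a results CSV, an FDR
gene list, a JSON run report, and the figures.

Chromosome-level parallelism (`jobs`) uses forked workers; results are
identical for any worker count because the spectral model and null model
are fitted once up front.

## The simulator

`sim_config()` / `simulate_structured_genotypes()` generate
Balding–Nichols cohorts: each variant draws an ancestral frequency
$f \sim U(0.05, 0.95)$, each of $K$ subpopulations draws
$f_k \sim \mathrm{Beta}(f(1-F)/F,\ (1-f)(1-F)/F)$ at the configured
$F_{st}$, and dosages are $\mathrm{Binomial}(2, f_k)$. Variants drawn
monomorphic are re-sampled once and then kept, so downstream filters stay
exercised. Positions lie on a regular 10-kb grid (a convenience that
makes tiled gene regions exact; no linkage disequilibrium is simulated).

Phenotypes follow a liability model
$L = g + s + \varepsilon$: causal-gene effects on standardized dosages
are rescaled so the genetic share of (genetic + noise) variance equals
the `heritability` target (default 0.3); population offsets are centered,
evenly spaced and scaled by `pop_effect`; $\varepsilon$ is standard
normal. Quantitative mode returns $L$; binary mode thresholds by rank so
the case count is hit exactly. Weight files draw background weights from
a Gamma with mean 0.5 and causal variants from a mean-2 component with
probability `weight_informativeness`. Seeds are strict: genotypes use
`seed`, phenotypes `seed + 1`, weights `seed + 2`, so each layer can be
varied independently.

What the simulator deliberately does **not** emulate: linkage
disequilibrium, admixed individuals (each sample belongs to one
population), sex chromosomes, genotyping error, or ascertainment beyond
the exact case-count threshold.

## Problem sizes and verification

The packaged demonstration fixture is 22 chromosomes × 100 SNPs with
1,000 cases and 1,000 controls. The test suite verifies, among others:
exact-inversion p-values against a Ruben-series oracle and Monte Carlo;
the whitening identity $\|D V D^\top - I\|_\infty < 10^{-10}$; type-I
error and $\lambda_{GC} \approx 1$ on pooled unstructured null scans;
that decorrelation reduces $\lambda_{GC}$ on confounded two-population
cohorts; REML recovery of planted variance components; and bitwise
agreement of the unweighted test with an independently coded dense score
test.

## Limitations

- The GRM eigendecomposition is dense ($O(n^3)$); cohorts beyond a few
  tens of thousands of samples need out-of-core or randomized methods not
  implemented here.
- Binary traits are decorrelated on the observed scale; very unbalanced
  case-control ratios would benefit from saddlepoint-corrected binary
  null models.
- Weights enter the kernel linearly after rectification; no attempt is
  made to learn or calibrate them from the data.
- The exact p-value assumes the eigenvalues are computed under the fitted
  null; model misspecification (e.g. unmodeled covariates) propagates to
  the mixture.
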
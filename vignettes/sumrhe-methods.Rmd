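---
title: "Estimating SNP heritability from summary statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating SNP heritability from summary statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumrhe)
```

## The model

SNP heritability $h^2_{\mathrm{SNP}}$ is the proportion of phenotypic
variance explained by genotyped SNPs under the additive model

$$ y = X\beta + \epsilon, \qquad
   \beta \sim \mathcal{D}\!\left(0, \tfrac{\sigma_g^2}{M} I_M\right), \qquad
   \epsilon \sim \mathcal{D}(0, \sigma_e^2 I_N), $$

where $X$ is the $N \times M$ column-standardized genotype matrix and $y$
the standardized phenotype, so that $\mathrm{tr}(K) = N$ and $y^\top y = N$
for the genetic relatedness matrix (GRM) $K = XX^\top/M$.  We use the
population divisor $N$ when standardizing, which makes $x_j^\top x_j = N$
exact; the method-of-moments identities below rely on it.  The effect
distribution $\mathcal{D}$ is arbitrary with the stated first two moments —
the estimators are moment-based and make no normality assumption.

## The Haseman–Elston method of moments and its randomized form

Matching the sample covariance $yy^\top$ to the population covariance
$\sigma_g^2 K + \sigma_e^2 I_N$ in Frobenius norm yields the normal
equations with the closed-form solution

$$ \hat\sigma_g^2 = \frac{y^\top K y - y^\top y}{\mathrm{tr}(K^2) - N},
   \qquad \hat\sigma_e^2 = \frac{y^\top y}{N} - \hat\sigma_g^2, $$

and $\hat h^2 = \hat\sigma_g^2$ for standardized $y$
(`estimate_he_exact()`).  The quadratic form $y^\top K y$ is evaluated as
$\lVert X^\top y\rVert^2 / M$, never forming $K$; $\mathrm{tr}(K^2)$ is the
expensive term.  The randomized variant (`estimate_rhe()`) replaces it by
the Hutchinson estimator

$$ \widehat{\mathrm{tr}(K^2)} = \frac{1}{B}\sum_{b=1}^{B}
   z_b^\top K^\top K z_b, \qquad z_b \sim \mathcal{N}(0, I_N), $$

evaluated in $O(MNB)$ as $\lVert X (X^\top z_b) / M \rVert^2$.  Standard
normal probes are the default; Rademacher probes are available behind a
flag for variance comparisons but are never used by default.

## Trace summaries and SUM-RHE

The left-hand side of the normal equations depends only on linkage
disequilibrium (LD) in the population, not on the phenotype.  For unlinked
SNPs and large $N$, $\mathrm{tr}(K^2) \approx N + N^2 \rho$ where
$\rho = \frac{1}{N}\left(\frac{\mathrm{tr}(K^2)}{N} - 1\right)$ is the
average LD across SNPs — a population functional that a reference-panel
holder can estimate once and release as a *trace summary*
(`make_trace_summary()`, `write_trace()`), with no individual-level data.

On the target side, marginal GWAS effect sizes give adjusted z-scores
$z_j = (\hat\beta_j / s_j)\sqrt{N_j} / N$.  Under the large-sample SE
approximation $s_j = \sqrt{y^\top y / (N N_j)}$ the vector $z$ equals
$X^\top y / y^\top y$ exactly, so $z^\top z \, N / M = y^\top K y / y^\top y$
and the method-of-moments estimate can be reconstructed from summary data
alone:

$$ \hat h^2_{\mathrm{MoM}} =
   \frac{z^\top z\, N / M - 1}{N \hat\rho}
   \;=\; \frac{z^\top z / M - 1/N}{\hat\rho}. $$

These two algebraic forms are identical; `estimate_sumrhe()` implements
them with $N$ the *target* GWAS sample size (the trace summary is treated
as $N$-free, being a population LD functional).  With an exact in-sample
trace and approximate-SE sumstats, SUM-RHE reproduces the exact HE
estimate to machine precision — this identity is a permanent test oracle.
With real residual-based OLS SEs (what PLINK reports, and what
`run_gwas()` computes by default) the two agree to $O(1/N)$.

## Standard errors and the null test

Uncertainty is quantified by a SNP-level block jackknife: SNPs are split
into `n_blocks` contiguous equal-size blocks (remainder to the last block;
contiguity respects LD locality).  Each replicate removes one block from
every SNP-indexed quantity — $X^\top y$, $z^\top z$, and the trace, with
$M$ renormalized to $M - m_b$ — reusing the *same* probe vectors, which is
algebraically identical to rerunning them on the physically subset panel
(also a test oracle).  Then

$$ \widehat{\mathrm{Var}}(\hat h^2) = \frac{n-1}{n}
   \sum_{i=1}^{n} \left[\hat h^2_i - \bar{h^2}\right]^2, \qquad
   \widehat{\mathrm{SE}} = \sqrt{\widehat{\mathrm{Var}}}. $$

The delete-one block jackknife with squared deviations and $(n-1)/n$
weighting is used throughout; reference renderings of this formula
sometimes omit the square on the deviation term, which we read as
typographical.

`test_null()` performs a one-sided normal test of $h^2 > 0$,
$p = 1 - \Phi(\hat h^2 / \widehat{\mathrm{SE}})$, rejecting strictly below
$\alpha$.  Sidedness is a design choice: $h^2 > 0$ is the scientifically
meaningful alternative and yields false-positive rates near $\alpha$ under
the symmetric null; a two-sided flag exists.  Estimates are deliberately
**not** clamped to $[0,1]$ — under the null about half of them are
negative, and clamping would destroy the test's calibration.  `clamp_h2()`
exists for presentation only.

## The synthetic-data generator

`simulate_genotypes()` draws per-SNP MAFs uniformly on
$[0.05, 0.5]$ by default and genotypes as independent
$\mathrm{Binomial}(2, \mathrm{maf})$ — an idealized unlinked panel.
`draw_effects()` implements the sparse architecture (each SNP causal with
probability $P$; causal variance $h^2/(MP)$ so the expected total genetic
variance is $h^2$ for any sparsity) and the large/small mixture (first
$\lfloor\pi M\rfloor$ SNPs carry a $\gamma$ share of $h^2$; within-group
causal probability $\alpha$; variances $\gamma h^2/(\pi M \alpha)$ and
$(1-\gamma)h^2/((1-\pi)M\alpha)$).  A single $\alpha$ is shared between
groups.  If a sparse draw yields zero causal SNPs at $h^2 > 0$ the mask is
redrawn with a message, so bias experiments are not corrupted by null
phenotypes under non-null configurations.  Realized genetic variance is
*not* rescaled to hit $h^2$ exactly by default (rescaling would understate
estimator spread); `exact_h2 = TRUE` opts in.

What the generator does **not** emulate: realistic LD (a block-correlated
AR(1)-threshold generator, `simulate_genotypes_ld()`, exists solely to
exercise LD-dependent trace behavior), MAF- or LD-dependent effect sizes,
covariates, case/control liability phenotypes, relatedness and population
stratification.  Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to confounded GWAS
input — SUM-RHE assumes confounding-free summary statistics.

## Numerical and design choices

* **Divisor convention.** Population divisor $N$ everywhere (genotypes and
  phenotypes), keeping $\mathrm{tr}(K) = N$, $y^\top y = N$ exact.
* **Missing genotypes** are mean-imputed before standardization (imputed
  entries become 0, contributing nothing to cross-products); per-SNP
  observed counts are kept and used for `OBS_CT` and the regression
  degrees of freedom.
* **Monomorphic SNPs** are dropped with a report, never an error — small
  simulated panels produce them routinely.
* **Allele orientation.** Standardization counts the A1 dosage as stored;
  relabeling A1/A2 only flips a column's sign, and every downstream
  quantity is a square or quadratic form, hence sign-invariant.
* **Degenerate cases.** $\widehat{\mathrm{tr}(K^2)} \to N$ makes the normal
  equations singular (hard error); $\hat\rho \le 0$ — possible with very
  few probes on tiny panels — inverts the estimator's sign and is a hard
  error, never silently accepted.
* **Seeding.** One master seed; per-run probe seeds and per-replicate
  phenotype seeds are deterministic offsets of it, so multi-run trace
  aggregation and full experiment grids are bit-reproducible.
* **Trace file format** stores 17 significant digits, so write/read
  round-trips are bit-exact; block structure and a SNP-list digest are
  validated on read.  Exact-mode summaries record `#B 0`.

## Study design of the shipped experiments

The simulation harness (`run_grid()`) mirrors a fixed-genotypes design:
one panel per grid, fresh effects and phenotypes per replicate
(`fresh_genotypes` redraws panels).  The packaged experiments use a
desk-scale configuration chosen so the whole suite runs in minutes on one
core: $N = 2000$ target samples (plus $4000$ reference in split mode),
$M = 5000$ unlinked SNPs, $B = 100$ probes per trace run with 25 runs
aggregated (2500 effective probes), 100 jackknife blocks, and 100
replicates per architecture cell over
$h^2 \in \{0.1, 0.25, 0.4\} \times P \in \{1.0, 0.1, 0.01\}$; null
calibration uses 200 replicates at $h^2 = 0$ in split-reference mode, and
the mixture checks use $\pi = 0.05$, $\gamma = 0.25$,
$\alpha \in \{1.0, 0.1\}$ at $h^2 = 0.25$ (the middle of the grid).
`relative_mse()` compares estimators cell-by-cell as
$100 \times \mathrm{MSE}/\mathrm{MSE}_{\mathrm{RHE}}$ with percentile
bootstrap CIs from 10,000 resamples of replicate indices, resampled
jointly across estimators to preserve their correlation (all estimators
see the same phenotypes).  Bias, empirical SE and MSE are reported with
the divisor-$n$ convention so $\mathrm{MSE} = \mathrm{bias}^2 +
\mathrm{SE}^2_{\mathrm{emp}}$ holds exactly.

A worked small example:

```{r example, eval = FALSE}
std <- standardize(simulate_genotypes(n = 1000, m = 2000, seed = 1))
eff <- draw_effects(std$m, architecture_config(h2 = 0.25, causal_ratio = 0.1,
                                               seed = 2))
y <- simulate_phenotype(std, eff, h2 = 0.25, seed = 3)

# individual-level randomized HE
estimate_rhe(std, y, b = 100, n_blocks = 100, seed = 4)

# summary-statistics route: GWAS + reference trace summary
stats <- run_gwas(std, y)
trace <- make_trace_summary(std, b = 100, n_blocks = 100, seed = 5)
estimate_sumrhe(stats, trace, n_target = std$n)
```

## Known limitations

* Single-component heritability only: no partitioned, MAF/LD-stratified,
  or local estimates (these would require partitioned trace summaries).
* No correction for population stratification or cryptic relatedness in
  the consumed summary statistics.
* The exact-trace and exact-HE paths form Gram matrices and are oracles
  for moderate panels, not biobank-scale tools; the stochastic paths are
  $O(MNB)$ but this implementation streams nothing and holds $X$ in
  memory.
* Reference-to-target transfer assumes both samples come from the same
  population; no diagnostic for LD mismatch is provided.
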
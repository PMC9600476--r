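---
title: "Methods: heritability and microbiability of host-associated microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heritability and microbiability of host-associated microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microherit)
```

This vignette documents the models behind the package, the numerical
choices made in fitting them, what the synthetic-data generator does and
does not emulate, and the known limitations. It states no empirical claims
beyond what the test suite computes.

## The two models and their shared engine

Both headline quantities are variance ratios from the same single-kernel
linear mixed model,

$$y = X\beta + u + e, \qquad u \sim N(0, \sigma_u^2 K), \qquad
  e \sim N(0, \sigma_e^2 I),$$

fitted by REML in `kernel_lmm()`.

**Per-taxon heritability.** The response is the taxon's
$\log_{10}(\text{proportion} + \delta)$ abundance, pre-corrected by OLS for
subcohort, parity, age, days-in-milk and ruminal pH (`adjust_fixed_effects()`;
the mixed model then carries only an intercept). The kernel is the VanRaden
method-1 genomic relationship matrix,
$G = ZZ^\top / \bigl(2\sum_k \hat f_k(1-\hat f_k)\bigr)$ with $Z$ the
dosage matrix centered by $2\hat f_k$ (sample allele frequencies). The
ratio $\sigma_u^2/(\sigma_u^2+\sigma_e^2)$ is $h^2$. The two-stage layout —
covariates regressed out first, intercept-only mixed model second — is the
conventional pre-correction workflow for microbial phenotypes; the
microbiability model instead keeps its covariates inside the mixed model,
because trait analyses customarily estimate fixed effects jointly with the
variance components.

**Subcommunity microbiability.** The kernel is the microbiota relationship
matrix $M = \tfrac1q O O^\top$, where
$O_{ij} = (\log S_{ij} - \overline{\log S_{\cdot j}})/\mathrm{sd}(\log
S_{\cdot j})$ and $S_{ij}$ is the relative abundance of taxon $j$ in animal
$i$ plus one. The fixed effects (subcohort, parity, age, days-in-milk — pH
deliberately excluded, as it is itself a microbially influenced measure and
belongs to the taxon-level correction only) ride inside the model. The
ratio is $m^2$, and the **mean microbiability** $\beta^2 = m^2/o$ divides
by the subcommunity's taxon count to give an average single-taxon
contribution.

Because the column standardization in $O$ divides by the column standard
deviation, the log base cancels exactly, and
$\operatorname{trace}(M) = (n-1)$ always — both are asserted in the test
suite. The $+1$ inside the log is applied to proportions in $[0,1]$ (not
percentages): the kernel is nonlinear in that choice, so proportions are
fixed as the canonical scale. Zero-variance taxa columns are dropped with a
warning and $q$ reduced to the post-drop count. When the heritable and
nonheritable subcommunities are analyzed, $M$ is rebuilt per subset rather
than sliced from a global $O$: the standardization is subset-independent
and the $1/q$ factor implies a per-subset $q$.

## Numerical strategy in `kernel_lmm()`

After one symmetric eigendecomposition $K = UDU^\top$ (reusable across
responses via `eigen_K`), the restricted likelihood is profiled
analytically over the total variance and maximized over the ratio
$h \in [10^{-6},\ 1-10^{-6}]$:

* a 64-point coarse grid, log-spaced toward both box edges so optima near 0
  and near 1 are both bracketed, followed by `optimize()` refinement to
  tolerance $10^{-8}$ between the neighbours of the best grid point;
* the log-likelihood convention is Patterson–Thompson
  ($-\tfrac12[(n-p)\log 2\pi + \log|V| + \log|X^\top V^{-1}X| + y^\top P
  y]$, without the constant $\log|X^\top X|$ term), and `reml_loglik()`
  evaluates the same surface at user-supplied variance components — the
  tests verify both against a dense `solve()`/`determinant()` evaluation;
* the standard error of the ratio is
  $\sqrt{-1/\ell''(\hat h)}$ from a central finite-difference curvature of
  the profile likelihood, with the step shrunk near the box edge. This is a
  profile-curvature SE in the ratio parameterization; an
  average-information REML SE (as commercial mixed-model software reports)
  can differ modestly, which is accepted rather than chased;
* the p-value is a boundary likelihood-ratio test of $\sigma_u^2 = 0$
  against the $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture,
  $p = \tfrac12 P(\chi^2_1 \ge LR)$ — the standard reference distribution
  for a variance component on its boundary, adopted because the upstream
  software's p-value recipe is not published;
* estimates within $10^{-5}$ of the search box edge are flagged
  (`boundary = TRUE`); degenerate inputs (constant response, asymmetric or
  indefinite kernel, eigenvalues below $-10^{-8}$ relative) are rejected.

A taxon is *heritable* when $\hat h^2/\mathrm{SE} > 2$ **and** $p < 0.05$;
heritable taxa are graded high ($\hat h^2 > 0.4$), moderate
($0.2 < \hat h^2 \le 0.4$) or low. The $\log_{10}$ pseudocount is
$\delta =$ half the smallest nonzero proportion in the whole table — a
common microbiome convention, recorded on every result
(`attr(result, "delta")`) since the analysis is stated only up to this
choice.

## Association scan

`run_mm_gwas()` uses the P3D/EMMAX approximation: the variance components
are estimated once per taxon under the null kernel model, then every SNP
(recoded $-1/0/1$ as dosage minus one) is tested by generalized least
squares in the eigenrotated space, with a Wald $t$ on $n-2$ degrees of
freedom and a residual-scale re-estimate per SNP — so under a null trait
the statistics reduce to calibrated OLS $t$-tests. Monomorphic-in-sample
SNPs are skipped and counted. Benjamini–Hochberg adjustment is applied
within taxon (each taxon is its own testing family), with tiers at
FDR < 0.01 (significant) and < 0.05 (suggestive). `exact = TRUE` refits
REML per SNP; a test verifies the two routes give the same top-10 SNP set
with strongly concordant ranks on small panels. The per-SNP model carries
an intercept plus the SNP only, since taxon values enter pre-adjusted for
covariates.

## Networks and kernel comparison

`build_correlation_network()` computes Spearman correlations with average
ranks over pairwise-complete observations, p-values from the large-sample
$t$ approximation (an exact permutation option exists for very small
pairs), BH adjustment over all pairs tested in the run (the natural family
absent a stated one), and keeps edges with $|\rho|$ strictly above 0.2 and
adjusted $p < 0.05$. Edges are reported in canonical column order, so
output is deterministic.

`mantel_test()` correlates the strictly-lower triangles of two similarity
matrices directly (no distance conversion, matching the G-versus-M
comparison), with a one-sided upper-tail permutation p-value and the $+1$
correction; the default 9,999 permutations give a p-value resolution of
$10^{-4}$.

## What the generator emulates, and what it does not

`simulate_genotypes()` draws each SNP binomial$(2, f)$ with $f$ uniform on
the configured range — HWE, no linkage disequilibrium, no population
structure. `simulate_taxa_abundances()` plants an additive genetic
component of specified $h^2$ on the latent log scale via a symmetric
square root of $G$, exponentiates, zero-inflates by truncating the
smallest values to hit the target prevalence exactly (a deterministic
mechanism chosen over an independent Bernoulli mask so prevalence is exact
and reproducible), and closes rows by a *common* constant with a
`remainder` filler column absorbing the balance. Dividing by a common
constant rather than per-row totals keeps the planted log-scale genetic
signal exactly intact; the price is that the filler is large and the
simulated taxa occupy a minority of the composition, and that the filler
itself carries (negative) genetic signal when heritable taxa are planted.
`simulate_phenotypes()` builds traits from planted covariate effects, a
microbial component $Ow$ with $w \sim N(0, \sigma_m^2/q)$ on the detected
simulated taxa, and Gaussian noise; protein/fat yields and energy-corrected
milk ($\mathrm{ECM} = 0.3246\,\mathrm{MY} + 13.86\,\mathrm{MFY} +
7.04\,\mathrm{MPY}$) are derived, not independently simulated, so their
identities hold in the output. One master seed expands to per-stage child
seeds, so each stage regenerates independently and bit-identically.

Passing recovery tests on these data therefore demonstrates correctness of
the estimation machinery under the model's own assumptions — they say
nothing about robustness to LD, population structure, compositional
closure at realistic depth, non-lognormal abundance distributions, or
diet/batch confounding, none of which are generated. Recovery tests use
full-prevalence taxa deliberately: truncation-style zero inflation biases
the realized $h^2$ of a zero-inflated taxon (the truncated tail is not
missing at random), so zero-inflated taxa exercise only the
filter/classification paths. This bias is documented rather than
corrected.

## Study conditions used by the validation suite

The recovery experiments in the acceptance tests run at cohort sizes a
desk-scale replication can afford while still being statistically
informative: 400 animals × 2,000 SNPs with 60 taxa (20 each at
$h^2 \in \{0, 0.3, 0.6\}$) over 30 replicates for heritability; 400
animals, $q = 100$ taxa, $m^2 \in \{0, 0.3\}$ over 20 replicates for
microbiability; 20 replicates of a planted SNP explaining 20 % of a
taxon's variance for the scan. Grid-search REML oracles run on fixed
8-individual family structures where exhaustive search at $10^{-4}$
resolution is feasible.

## Thresholds and defaults

| Parameter | Default | Meaning |
|---|---|---|
| detection prevalence | 0.20 | taxon analyzed at all ("at least 20 %", inclusive) |
| core prevalence | 0.50 | core vs noncore split (inclusive; exactly 50 % is core) |
| MAF / call rate | 0.05 / 0.90 | SNP QC, strict inequalities; call-rate filter first, MAF on non-missing calls, then per-SNP mean imputation |
| heritable rule | ratio/SE > 2 and p < 0.05 | classification of a fit |
| FDR tiers | 0.01 / 0.05 | significant / suggestive associations |
| network edge | \|rho\| > 0.2 (strict), adj. p < 0.05 | retained correlations |
| ratio search box | [1e-6, 1 − 1e-6] | avoids exact-boundary degeneracies; edge hits flagged |
| Mantel permutations | 9,999 | p resolution 1e-4 |

Percent presentation rounds half away from zero to two decimals
(`percent_round()`): base R's round-half-to-even would turn the exact tie
$0.29/32 = 0.90625$ into 0.90 rather than the conventional 0.91.

## Known limitations

* Single random effect only: no joint genomic-plus-microbial model, no
  repeated records, no genotype-by-environment terms.
* The SE is a profile-curvature approximation; near-boundary estimates can
  have unstable SEs (flagged, not suppressed).
* The P3D approximation understates uncertainty for SNPs of large effect;
  the exact mode exists but is slow for dense panels.
* The generator's independence assumptions (no LD, no structure) make the
  synthetic GWAS easier than a real one; power numbers do not transfer.
* Heritability of zero-inflated taxa is attenuated by the truncation
  mechanism, mirroring the real difficulty of h² estimation for
  low-prevalence taxa rather than solving it.
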
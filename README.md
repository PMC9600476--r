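# microherit

Variance-component analysis of host genetics and the rumen microbiome for
quantitative-genetics and microbiome researchers working with livestock
cohorts. The package asks two linked questions about a cohort of genotyped
animals with microbial relative-abundance profiles and production records:

1. **Which microbial taxa are heritable?** For each taxon, the log10
   abundance (after fixed-effect correction) is fitted with the animal model

   y* = 1μ + Za + e,  a ~ N(0, G σ²ₐ),  e ~ N(0, I σ²ₑ)

   where **G** is the VanRaden genomic relationship matrix built from SNP
   dosages, and narrow-sense heritability is h² = σ²ₐ / (σ²ₐ + σ²ₑ).
   A taxon is *heritable* when h²/SE > 2 and the boundary
   likelihood-ratio p < 0.05; heritable taxa are graded high (h² > 0.4),
   moderate (0.2 < h² ≤ 0.4) or low.

2. **How much do heritable vs nonheritable subcommunities contribute to
   host traits?** For each subcommunity, a microbiota relationship matrix
   **M** = (1/q) O Oᵀ is built from the column-standardized log of
   (relative abundance + 1), and each trait is fitted with

   y** = 1μ + Uc + Lm + e,  m ~ N(0, M σ²ₘ)

   giving the microbiability m² = σ²ₘ / (σ²ₘ + σ²ₑ) and the
   **mean microbiability** β² = m² / o (the average single-taxon
   contribution, with o the subcommunity's taxon count).

Both models are special cases of one single-kernel REML engine,
`kernel_lmm()`, which profiles the restricted likelihood over the variance
ratio after one eigendecomposition of the kernel. Around it the package
provides genotype QC, Mantel tests between kernels, prevalence-based
detection and core/noncore classification, P3D (EMMAX-style) mixed-model
association scans with per-taxon Benjamini–Hochberg FDR, thresholded
Spearman correlation networks, and a synthetic-data generator that plants
known per-taxon h² and per-trait m² so every stage can be validated against
ground truth.

## Worked example

A self-contained synthetic cohort: 150 animals, 400 SNPs, 20 taxa of which
10 are simulated with h² = 0.6 and 10 with h² = 0 (half of each group
zero-inflated to 60 % prevalence), and milk/VFA traits carrying planted
microbial components.

```r
library(microherit)
cfg <- list(
  simulate = list(n_individuals = 150, n_snps = 400,
                  taxa_h2 = rep(c(0.6, 0.6, 0, 0), 5),
                  taxa_prevalence = rep(c(1, 0.6), 10)),
  thresholds = list(mantel_n_perm = 199),
  traits = c("MY", "ECM", "acetate", "propionate", "total_vfa"))
res <- run_full_pipeline(cfg, out_dir = "demo_run", seed = 2022)
cat(readLines("demo_run/summary.txt"), sep = "\n")
```

```
microherit pipeline summary
seed: 2022
samples: 150  SNPs kept: 399  SNPs dropped: 1
taxa detected: 21  undetected dropped: 0
heritable taxa: 8  nonheritable: 13
non-converged fits: 0
Mantel G vs M: r = 0.0606, p = 0.005
```

The eight heritable calls are six of the ten planted h² = 0.6 taxa, one
false-positive null taxon (1/10, at the method's nominal error level), and
the compositional `remainder` filler — whose abundance is one minus the sum
of the planted taxa and therefore genuinely carries their genetic signal.
The top heritability estimates:

```r
h <- res$heritability
head(h[order(-h$h2), c("taxon_id","h2","se","p_value","heritable","category")], 5)
#>      taxon_id    h2    se  p_value heritable category
#> 13 taxon_0013 0.688 0.141 3.35e-05      TRUE     high
#> 6  taxon_0006 0.684 0.128 2.32e-06      TRUE     high
#> 17 taxon_0017 0.660 0.159 1.31e-04      TRUE     high
#> 5  taxon_0005 0.609 0.167 6.13e-04      TRUE     high
#> 9  taxon_0009 0.590 0.145 1.25e-04      TRUE     high
```

and the heritable-subcommunity microbiabilities, with β² = m²/o:

```r
head(res$microbiability, 4)
#>        trait     group    m2  m2_se  p_value o  beta2
#> 1         MY heritable 0.199 0.1006 4.26e-06 8 0.0248
#> 2        ECM heritable 0.115 0.0702 3.72e-04 8 0.0144
#> 3    acetate heritable 0.324 0.1272 1.14e-09 8 0.0405
#> 4 propionate heritable 0.341 0.1270 5.03e-12 8 0.0426
```

So for acetate, the eight heritable taxa jointly explain m² ≈ 32 % of the
trait variance, an average of `percent_round(0.0405)` ≈ 4.05 % per taxon.
Every stage writes a TSV into `out_dir` together with a manifest of MD5
hashes and the resolved configuration; re-running with the same config and
seed reproduces every file bit-identically.

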
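# deterministic child seeds: one user seed expands to per-stage streams so a
# stage can be regenerated without replaying the others
child_seed <- function(seed, stage) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer((s * 48271 + 7919 * stage) %% 2147483647)
}

#' Simulation configuration
#'
#' Collects the study-design knobs of the synthetic cohort: cohort size,
#' marker panel, per-taxon target heritabilities and prevalences, and
#' per-trait target microbiabilities. Defaults emulate a mid-lactation dairy
#' cohort genotyped on a medium-density panel.
#'
#' @param n_individuals number of animals (>= 2).
#' @param n_snps number of biallelic SNPs (>= 1).
#' @param maf_range allele-frequency range in (0, 0.5] from which each SNP's
#'   frequency is drawn uniformly.
#' @param taxa_h2 per-taxon target narrow-sense heritabilities in `[0, 1)`.
#' @param taxa_prevalence per-taxon target detection fractions in `(0, 1]`;
#'   same length as `taxa_h2`.
#' @param trait_specs data.frame with columns `trait`, `m2` (target
#'   microbiability in `[0, 1)`, or `NA` for traits derived from others),
#'   `intercept`, `sd`. See [default_trait_specs()].
#' @param covariate_effects named numeric vector of standardized fixed-effect
#'   sizes for `subcohort`, `parity`, `age`, `days_in_milk`.
#' @param seed integer master seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_individuals, n_snps, maf_range = c(0.05, 0.5),
                       taxa_h2 = numeric(0), taxa_prevalence = NULL,
                       trait_specs = NULL,
                       covariate_effects = c(subcohort = 0.5, parity = 0.2,
                                             age = 0.05, days_in_milk = 0.01),
                       seed = 1) {
  if (n_individuals < 2) stop("'n_individuals' must be >= 2")
  if (n_snps < 1) stop("'n_snps' must be >= 1")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("'maf_range' must lie in (0, 0.5]")
  if (is.null(taxa_prevalence)) taxa_prevalence <- rep(1, length(taxa_h2))
  if (length(taxa_h2) != length(taxa_prevalence))
    stop("'taxa_h2' and 'taxa_prevalence' must have the same length")
  if (length(taxa_h2) && (any(taxa_h2 < 0) || any(taxa_h2 >= 1)))
    stop("'taxa_h2' entries must lie in [0, 1)")
  if (length(taxa_prevalence) &&
      (any(taxa_prevalence <= 0) || any(taxa_prevalence > 1)))
    stop("'taxa_prevalence' entries must lie in (0, 1]")
  if (is.null(trait_specs)) trait_specs <- default_trait_specs()
  trait_specs <- as.data.frame(trait_specs)
  stopifnot(all(c("trait", "m2") %in% names(trait_specs)))
  if (is.null(trait_specs$intercept)) trait_specs$intercept <- 0
  if (is.null(trait_specs$sd)) trait_specs$sd <- 1
  m2 <- trait_specs$m2[!is.na(trait_specs$m2)]
  if (any(m2 < 0) || any(m2 >= 1))
    stop("trait target m2 must lie in [0, 1)")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps),
                 maf_range = as.numeric(maf_range),
                 taxa_h2 = as.numeric(taxa_h2),
                 taxa_prevalence = as.numeric(taxa_prevalence),
                 trait_specs = trait_specs,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default trait specifications for the synthetic cohort
#'
#' Milk yield, protein and fat content, six volatile fatty acids and total
#' VFA carry their own microbial components; protein and fat yields and
#' energy-corrected milk are derived (`m2 = NA`) as `MPY = MP x MY`,
#' `MFY = MF x MY` and [compute_ecm()]. Intercepts and scales are plausible
#' mid-lactation magnitudes (kg/d for yields, fractions for contents,
#' mmol/L for VFAs).
#' @return data.frame with columns `trait`, `m2`, `intercept`, `sd`.
#' @export
default_trait_specs <- function() {
  data.frame(
    trait = c("MY", "MP", "MF", "acetate", "propionate", "butyrate",
              "isobutyrate", "valerate", "isovalerate", "total_vfa",
              "MPY", "MFY", "ECM"),
    m2 = c(0.39, 0.31, 0.22, 0.53, 0.65, 0.65, 0.25, 0.67, 0.72, 0.58,
           NA, NA, NA),
    intercept = c(32, 0.033, 0.038, 60, 20, 12, 1, 1.5, 1.5, 95, 0, 0, 0),
    sd = c(4, 0.003, 0.004, 6, 3, 2, 0.2, 0.3, 0.3, 9, 0, 0, 0))
}

#' Simulate additive genotype dosages
#'
#' Each SNP gets an allele frequency drawn uniformly from `maf_range` and
#' dosages drawn binomial(2, f) — approximate Hardy-Weinberg equilibrium.
#' Chromosome labels are assigned round-robin over 29 autosomes with
#' positions spaced 50 kb apart within chromosome.
#'
#' @param config a [sim_config()].
#' @return a [genotypes()] object; deterministic given `config$seed`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1L))
  n <- config$n_individuals
  p <- config$n_snps
  f <- stats::runif(p, config$maf_range[1], config$maf_range[2])
  dosage <- matrix(stats::rbinom(n * p, 2, rep(f, each = n)), nrow = n,
                   dimnames = list(sprintf("ind_%04d", seq_len(n)),
                                   sprintf("snp_%05d", seq_len(p))))
  chrom <- rep_len(1:29, p)
  bp <- integer(p)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    bp[idx] <- 50000L * seq_along(idx)
  }
  genotypes(dosage, data.frame(snp_id = colnames(dosage),
                               chrom = chrom, bp = bp))
}

#' Simulate taxa relative abundances with planted heritabilities
#'
#' For each taxon `j`, a latent log-abundance `x_j = mu_j + a_j + eps_j` is
#' drawn with the genetic values `a_j ~ N(0, sigma_a^2 G)` generated through
#' a symmetric eigendecomposition square root of the genomic relationship
#' matrix (eigenvalues clipped at zero, tolerance 1e-8) and
#' `sigma_a^2 / (sigma_a^2 + sigma_e^2)` equal to the taxon's target
#' heritability. Abundances are `exp(x)`, zero-inflated by truncating the
#' smallest values until the target prevalence is met (deterministic given
#' the draw), and closed row-wise to proportions by dividing by a common
#' constant; a filler `remainder` taxon absorbs the balance so every row
#' sums to exactly 1.
#'
#' @param geno a [genotypes()] object (used to build `G` internally after
#'   silently removing monomorphic-in-sample SNPs).
#' @param config a [sim_config()] with non-empty `taxa_h2`.
#' @return list with `table` (a [taxa_table()] including the `remainder`
#'   column) and `truth` (per-taxon `h2`, matrix `a` of genetic values,
#'   latent means `mu`, the seed used).
#' @export
simulate_taxa_abundances <- function(geno, config) {
  stopifnot(inherits(geno, "genotypes"), inherits(config, "sim_config"))
  t_n <- length(config$taxa_h2)
  if (t_n == 0) stop("config has no taxa (empty 'taxa_h2')")
  # drop SNPs monomorphic in this sample so the GRM is defined
  f <- colMeans(geno$dosage) / 2
  poly <- f > 0 & f < 1
  if (!any(poly)) stop("all SNPs monomorphic in sample")
  G <- compute_grm(genotypes(geno$dosage[, poly, drop = FALSE],
                             geno$map[poly, , drop = FALSE]))
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(1, max(eg$values)))
    stop("G is not positive semi-definite within tolerance")
  Chalf <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))

  n <- nrow(G)
  seed <- child_seed(config$seed, 2L)
  set.seed(seed)
  mu <- stats::rnorm(t_n, mean = 0, sd = 1)
  A <- Chalf %*% matrix(stats::rnorm(n * t_n), n, t_n) *
    rep(sqrt(config$taxa_h2), each = n)
  E <- matrix(stats::rnorm(n * t_n), n, t_n) *
    rep(sqrt(1 - config$taxa_h2), each = n)
  X <- sweep(A + E, 2, mu, "+")
  raw <- exp(X)
  # zero-inflation by truncating the smallest latent abundances per taxon
  for (j in seq_len(t_n)) {
    n_zero <- n - round(config$taxa_prevalence[j] * n)
    if (n_zero > 0) raw[order(raw[, j])[seq_len(n_zero)], j] <- 0
  }
  total <- 1.25 * max(rowSums(raw))
  P <- raw / total
  tab <- cbind(P, remainder = 1 - rowSums(P))
  colnames(tab) <- c(sprintf("taxon_%04d", seq_len(t_n)), "remainder")
  rownames(tab) <- rownames(geno$dosage)
  dimnames(A) <- list(rownames(tab), colnames(tab)[seq_len(t_n)])
  list(table = taxa_table(tab),
       truth = list(h2 = stats::setNames(config$taxa_h2, colnames(A)),
                    a = A, mu = mu, seed = seed))
}

#' Simulate phenotypes with planted microbiabilities
#'
#' Covariates are drawn per animal (subcohort with 2 levels, parity 1-5,
#' age 3-8 years, days-in-milk 125-185, ruminal pH 5.5-7.0). Each trait with
#' a target microbiability `m2` is built as
#' `y = intercept + sd * (covariate effects + O w + e)` where `O` is the
#' standardized log-abundance matrix of the detected simulated taxa
#' (the `remainder` filler is excluded), `w ~ N(0, m2/q I)` and
#' `e ~ N(0, 1 - m2)`. Traits with `m2 = NA` are derived:
#' `MPY = MP x MY`, `MFY = MF x MY`, `ECM` via [compute_ecm()].
#'
#' @param taxa the `table` element returned by [simulate_taxa_abundances()].
#' @param config a [sim_config()].
#' @param detect_min prevalence threshold selecting the taxa that carry the
#'   microbial effect (default 0.20).
#' @return list with `phenotypes` (data.frame of traits and covariates,
#'   sample ids in `sample_id`) and `truth` (per-trait `m2`, effect vectors
#'   `w`, covariate coefficients, seed).
#' @export
simulate_phenotypes <- function(taxa, config, detect_min = 0.20) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(as.matrix(taxa))
  sim_cols <- setdiff(colnames(x), "remainder")
  prev <- colMeans(x[, sim_cols, drop = FALSE] > 0)
  use <- sim_cols[prev >= detect_min]
  if (length(use) < 2) stop("fewer than 2 detected taxa")
  n <- nrow(x)
  seed <- child_seed(config$seed, 3L)
  set.seed(seed)
  covar <- data.frame(
    sample_id = rownames(x),
    subcohort = factor(sample(c("A", "B"), n, replace = TRUE)),
    parity = sample(1:5, n, replace = TRUE),
    age = stats::runif(n, 3, 8),
    days_in_milk = stats::runif(n, 125, 185),
    pH = stats::runif(n, 5.5, 7.0))
  ce <- config$covariate_effects
  fixed_part <- ce[["subcohort"]] * (covar$subcohort == "B") +
    ce[["parity"]] * covar$parity + ce[["age"]] * covar$age +
    ce[["days_in_milk"]] * covar$days_in_milk

  L <- log(x[, use, drop = FALSE] + 1)
  sds <- apply(L, 2, stats::sd)
  keep <- sds > 0
  O <- sweep(sweep(L[, keep, drop = FALSE], 2, colMeans(L[, keep, drop = FALSE])),
             2, sds[keep], "/")
  q <- ncol(O)

  spec <- config$trait_specs
  base <- spec[!is.na(spec$m2), , drop = FALSE]
  W <- matrix(stats::rnorm(q * nrow(base)), q, nrow(base)) *
    rep(sqrt(base$m2 / q), each = q)
  Emat <- matrix(stats::rnorm(n * nrow(base)), n, nrow(base)) *
    rep(sqrt(1 - base$m2), each = n)
  Y <- O %*% W + Emat + fixed_part
  Y <- sweep(sweep(Y, 2, base$sd, "*"), 2, base$intercept, "+")
  colnames(Y) <- base$trait
  ph <- data.frame(covar, Y, check.names = FALSE)

  derived <- spec$trait[is.na(spec$m2)]
  if ("MPY" %in% derived && all(c("MP", "MY") %in% names(ph)))
    ph$MPY <- ph$MP * ph$MY
  if ("MFY" %in% derived && all(c("MF", "MY") %in% names(ph)))
    ph$MFY <- ph$MF * ph$MY
  if ("ECM" %in% derived && all(c("MY", "MFY", "MPY") %in% names(ph)))
    ph$ECM <- compute_ecm(ph$MY, ph$MFY, ph$MPY)

  colnames(W) <- base$trait
  rownames(W) <- colnames(O)
  list(phenotypes = ph,
       truth = list(m2 = stats::setNames(base$m2, base$trait), w = W,
                    covariate_effects = ce, taxa_used = colnames(O),
                    seed = seed))
}
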
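#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment with enforced monotonicity, capped at 1, mapped
#' back to the input order (a thin validated wrapper over
#' [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Mixed-model association scan for taxon abundances
#'
#' For each taxon: fits the null polygenic model once (intercept-only
#' [kernel_lmm()] against `G`), then, holding those variance components
#' fixed, tests every SNP by generalized least squares in the rotated space
#' — the P3D/EMMAX-style approximation. SNP genotypes are recoded to
#' -1/0/1 (dosage minus 1). The Wald statistic is referred to a t
#' distribution with `n - 2` degrees of freedom; p-values are BH-adjusted
#' within taxon and tiered at FDR < 0.01 (significant) and < 0.05
#' (suggestive). Monomorphic-in-sample SNPs are skipped and counted.
#'
#' With `exact = TRUE` each SNP instead gets its own REML fit with the SNP
#' as a fixed effect (slow; intended for small-n checks of the
#' approximation).
#'
#' @param taxon_values named list (or single-column matrix/vector) of
#'   fixed-effect-adjusted taxon abundance vectors, aligned with the
#'   genotype rows.
#' @param geno a QC'd [genotypes()] object.
#' @param G genomic relationship matrix over the same samples.
#' @param eigen_G optional precomputed eigendecomposition of `G`.
#' @param exact use per-SNP exact REML instead of P3D.
#' @return data.frame (class `gwas_table`) with columns `snp_id`, `chrom`,
#'   `bp`, `taxon_id`, `beta`, `se`, `p`, `fdr`, `tier`, sorted by
#'   (taxon, fdr); skipped-SNP counts in `attr(, "n_skipped")`.
#' @export
run_mm_gwas <- function(taxon_values, geno, G, eigen_G = NULL,
                        exact = FALSE) {
  stopifnot(inherits(geno, "genotypes"))
  if (is.numeric(taxon_values) && is.null(dim(taxon_values)))
    taxon_values <- list(taxon_1 = taxon_values)
  if (is.matrix(taxon_values))
    taxon_values <- as.list(as.data.frame(taxon_values))
  if (is.null(names(taxon_values)))
    names(taxon_values) <- paste0("taxon_", seq_along(taxon_values))
  x <- geno$dosage
  n <- nrow(x)
  if (any(lengths(taxon_values) != n))
    stop("taxon values and genotypes have different sample counts")
  if (is.null(eigen_G)) eigen_G <- eigen(G, symmetric = TRUE)
  S <- x - 1  # -1/0/1 coding
  mono <- apply(x, 2, function(col) length(unique(col)) == 1)
  n_skipped <- sum(mono)
  S <- S[, !mono, drop = FALSE]
  map <- geno$map[!mono, , drop = FALSE]
  p_snps <- ncol(S)
  if (p_snps == 0) stop("no polymorphic SNPs to test")

  res <- lapply(names(taxon_values), function(id) {
    y <- as.numeric(taxon_values[[id]])
    fit0 <- kernel_lmm(y, G, eigen_K = eigen_G)
    if (!isTRUE(fit0$converged)) {
      warning("null kernel fit did not converge for ", id, "; skipped")
      return(NULL)
    }
    if (exact) {
      stat <- vapply(seq_len(p_snps), function(s) {
        f <- kernel_lmm(y, G, X = cbind(1, S[, s]), eigen_K = eigen_G)
        b <- f$beta[2]
        se <- sqrt(f$beta_cov[2, 2])
        c(b, se, 2 * stats::pt(-abs(b / se), df = n - 2))
      }, numeric(3))
      beta <- stat[1, ]; se <- stat[2, ]; pv <- stat[3, ]
    } else {
      # rotate once by the null covariance, then per-SNP 2-parameter GLS in
      # closed form
      w <- fit0$sigma_u2 * fit0$d + fit0$sigma_e2
      Ut <- t(eigen_G$vectors)
      sw <- 1 / sqrt(w)
      yt <- sw * drop(Ut %*% y)
      x0 <- sw * drop(Ut %*% rep(1, n))
      St <- sw * (Ut %*% S)
      a <- sum(x0^2)
      b_ <- drop(crossprod(St, x0))
      cc <- colSums(St^2)
      u0 <- sum(x0 * yt)
      u1 <- drop(crossprod(St, yt))
      det <- a * cc - b_^2
      beta <- (a * u1 - b_ * u0) / det
      beta0 <- (cc * u0 - b_ * u1) / det
      rss <- sum(yt^2) - (beta0 * u0 + beta * u1)
      rss <- pmax(rss, 0)
      sigma2 <- rss / (n - 2)
      se <- sqrt(sigma2 * a / det)
      pv <- 2 * stats::pt(-abs(beta / se), df = n - 2)
    }
    fdr <- bh_adjust(pv)
    data.frame(snp_id = map$snp_id, chrom = map$chrom, bp = map$bp,
               taxon_id = id, beta = beta, se = se, p = pv, fdr = fdr,
               tier = ifelse(fdr < 0.01, "significant",
                             ifelse(fdr < 0.05, "suggestive", "ns")),
               row.names = NULL)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no taxon could be analyzed")
  out <- out[order(out$taxon_id, out$fdr, out$p), ]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("gwas_table", class(out))
  out
}
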
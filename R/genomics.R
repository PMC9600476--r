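#' Construct a genotype object
#'
#' Bundles an individuals-by-SNPs additive dosage matrix (values 0/1/2,
#' `NA` allowed before QC) with a variant map.
#'
#' @param dosage numeric matrix, individuals in rows (rownames = sample ids),
#'   SNPs in columns (colnames = SNP ids).
#' @param map optional data.frame with columns `snp_id`, `chrom`, `bp`
#'   aligned with the dosage columns.
#' @return an object of class `genotypes`.
#' @export
genotypes <- function(dosage, map = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("ind_%04d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("snp_%05d", seq_len(ncol(dosage)))
  if (anyDuplicated(rownames(dosage)) || anyDuplicated(colnames(dosage)))
    stop("sample and SNP ids must be unique")
  ok <- dosage[!is.na(dosage)]
  if (length(ok) && (min(ok) < 0 || max(ok) > 2))
    stop("dosages must lie in [0, 2] (0/1/2 calls, fractional if imputed)")
  if (is.null(map)) {
    map <- data.frame(snp_id = colnames(dosage),
                      chrom = NA_integer_, bp = NA_integer_)
  } else {
    map <- as.data.frame(map)
    stopifnot(all(c("snp_id", "chrom", "bp") %in% names(map)))
    if (!identical(as.character(map$snp_id), colnames(dosage)))
      stop("variant map does not match dosage columns")
  }
  structure(list(dosage = dosage, map = map), class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat("genotypes:", nrow(x$dosage), "individuals x", ncol(x$dosage), "SNPs\n")
  nm <- sum(is.na(x$dosage))
  if (nm > 0) cat("  missing entries:", nm, "\n")
  invisible(x)
}

#' Quality-control a genotype matrix
#'
#' Drops SNPs failing the call-rate filter, then SNPs failing the
#' minor-allele-frequency filter (computed on non-missing calls), then
#' mean-imputes any remaining missing entries per SNP. Both thresholds are
#' strict (`>`), i.e. a SNP is retained only when its call rate and MAF
#' strictly exceed the thresholds.
#'
#' @param raw a [genotypes()] object (pre-QC; `NA` allowed).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param call_rate_min minimum per-SNP call rate (default 0.90).
#' @return a [genotypes()] object with no missing entries; the counts dropped
#'   per criterion are attached as `attr(, "qc_report")`.
#' @export
qc_genotypes <- function(raw, maf_min = 0.05, call_rate_min = 0.90) {
  stopifnot(inherits(raw, "genotypes"))
  x <- raw$dosage
  if (nrow(x) < 2) stop("need at least 2 samples")
  call_rate <- colMeans(!is.na(x))
  pass_cr <- call_rate > call_rate_min
  f <- colMeans(x, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  maf[is.nan(maf)] <- 0   # SNP missing in all samples
  pass_maf <- maf > maf_min
  keep <- pass_cr & pass_maf
  report <- data.frame(
    n_input = ncol(x),
    n_fail_call_rate = sum(!pass_cr),
    n_fail_maf = sum(!pass_maf),
    n_kept = sum(keep))
  if (!any(keep))
    stop("all SNPs removed by QC (call rate: ", report$n_fail_call_rate,
         ", MAF: ", report$n_fail_maf, ")")
  x <- x[, keep, drop = FALSE]
  # mean imputation per SNP for the surviving missing calls
  nas <- which(is.na(x), arr.ind = TRUE)
  if (nrow(nas)) {
    mu <- colMeans(x, na.rm = TRUE)
    x[nas] <- mu[nas[, "col"]]
  }
  out <- genotypes(x, raw$map[keep, , drop = FALSE])
  attr(out, "qc_report") <- report
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Centers each SNP by twice its sample allele frequency and scales by the
#' summed expected heterozygosity:
#' \deqn{G = ZZ' / \left(2 \sum_k \hat f_k (1 - \hat f_k)\right)}
#' Monomorphic SNPs must have been removed by [qc_genotypes()].
#'
#' @param geno a QC'd [genotypes()] object (no missing entries).
#' @return symmetric PSD matrix with sample ids as dimnames and
#'   `attr(, "kind") == "genomic"`.
#' @export
compute_grm <- function(geno) {
  stopifnot(inherits(geno, "genotypes"))
  x <- geno$dosage
  if (anyNA(x)) stop("genotypes contain missing entries; run qc_genotypes()")
  if (ncol(x) < 1) stop("need at least one SNP")
  f <- colMeans(x) / 2
  if (any(f <= 0 | f >= 1))
    stop("monomorphic SNPs present; remove them by QC first")
  Z <- sweep(x, 2, 2 * f)
  G <- tcrossprod(Z) / (2 * sum(f * (1 - f)))
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(x), rownames(x))
  attr(G, "kind") <- "genomic"
  G
}

#' Mantel test between two relationship matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries, with a
#' one-sided upper-tail permutation p-value: rows and columns of `B` are
#' permuted jointly and the p-value is `(1 + #{r_perm >= r}) / (1 + n_perm)`.
#'
#' @param A,B n x n symmetric matrices over the same samples in the same
#'   order (dimnames, when present, must agree).
#' @param n_perm number of permutations (>= 99; default 9999).
#' @param seed integer seed for the permutations.
#' @return list with `r` (observed correlation), `p` (permutation p-value)
#'   and `n_perm`.
#' @export
mantel_test <- function(A, B, n_perm = 9999, seed = 1) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  if (!all(dim(A) == c(n, n)) || !all(dim(B) == c(n, n)))
    stop("'A' and 'B' must be square matrices of the same size")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("sample ids of 'A' and 'B' do not match")
  if (n_perm < 99) stop("'n_perm' must be at least 99")
  lt <- lower.tri(A)
  a <- A[lt]
  r_obs <- stats::cor(a, B[lt])
  set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n)
    stats::cor(a, B[idx, idx][lt])
  }, numeric(1))
  list(r = r_obs, p = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
       n_perm = n_perm)
}
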
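test_that("QC drops monomorphic, low-call-rate and low-MAF SNPs", {
  x <- cbind(mono = rep(0, 10),
             lowcall = c(rep(NA, 2), rep(1, 8)),
             good = rep(c(0, 1, 2), length.out = 10),
             rare = c(1, rep(0, 9)))
  g <- genotypes(x)
  expect_no_warning(out <- qc_genotypes(g))
  expect_identical(colnames(out$dosage), "good")
  rep <- attr(out, "qc_report")
  expect_equal(rep$n_fail_call_rate, 1)  # call rate 0.8 <= 0.9 -> dropped
  expect_equal(rep$n_kept, 1)
})

test_that("QC matches a brute-force filter on a random matrix with planted violations", {
  set.seed(21)
  n <- 50; p <- 200
  x <- matrix(rbinom(n * p, 2, runif(p, 0.02, 0.5)[rep(1:p, each = n)]),
              n, p)
  x[sample(length(x), 300)] <- NA
  g <- genotypes(x)
  out <- qc_genotypes(g, maf_min = 0.05, call_rate_min = 0.90)
  # brute force: both rules applied independently per SNP
  keep <- vapply(seq_len(p), function(j) {
    col <- x[, j]
    cr <- mean(!is.na(col))
    f <- mean(col, na.rm = TRUE) / 2
    maf <- min(f, 1 - f)
    cr > 0.90 && maf > 0.05
  }, logical(1))
  expect_identical(colnames(out$dosage), colnames(g$dosage)[keep])
  expect_false(anyNA(out$dosage))
  # imputed values are the per-SNP means of the observed calls
  j <- which(keep & colSums(is.na(x)) > 0)[1]
  if (!is.na(j)) {
    miss <- which(is.na(x[, j]))
    expect_equal(out$dosage[miss, colnames(g$dosage)[j]],
                 rep(mean(x[, j], na.rm = TRUE), length(miss)),
                 ignore_attr = TRUE)
  }
})

test_that("GRM equals direct VanRaden evaluation and treats duplicates as identical", {
  x <- rbind(c(0, 2), c(1, 1), c(2, 0))
  g <- genotypes(x)
  G <- compute_grm(g)
  f <- colMeans(x) / 2
  Z <- sweep(x, 2, 2 * f)
  expect_equal(unclass(G), tcrossprod(Z) / (2 * sum(f * (1 - f))),
               ignore_attr = TRUE, tolerance = 1e-12)

  x2 <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(2, 1, 0, 1))
  G2 <- compute_grm(genotypes(x2))
  expect_equal(G2[1, 1], G2[1, 2], tolerance = 1e-12)
  expect_equal(G2[1, 1], G2[2, 2], tolerance = 1e-12)

  expect_error(compute_grm(genotypes(cbind(rep(1, 4), c(0, 1, 2, 1)) * 0)),
               "monomorphic")
})

test_that("GRM diagonal is near 1 under HWE and is invariant to column order", {
  ch <- small_cohort(seed = 3, n = 400, p = 5000, taxa_h2 = numeric(0))
  G <- compute_grm(ch$geno)
  expect_gt(mean(diag(G)), 0.9)
  expect_lt(mean(diag(G)), 1.1)

  perm <- sample(ncol(ch$geno$dosage))
  g2 <- genotypes(ch$geno$dosage[, perm], ch$geno$map[perm, ])
  expect_equal(unclass(compute_grm(g2)), unclass(G), tolerance = 1e-10,
               ignore_attr = TRUE)

  # permuting samples permutes G the same way
  sp <- sample(nrow(ch$geno$dosage))
  g3 <- genotypes(ch$geno$dosage[sp, ], ch$geno$map)
  expect_equal(unclass(compute_grm(g3)), unclass(G)[sp, sp],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Mantel statistic and edge cases behave as defined", {
  set.seed(10)
  B <- matrix(rnorm(100), 10); A <- tcrossprod(B) / 10
  res <- mantel_test(A, A, n_perm = 199, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 200)

  Bm <- -A; diag(Bm) <- diag(A)
  expect_equal(mantel_test(A, Bm, n_perm = 99)$r, -1)

  C <- tcrossprod(matrix(rnorm(100), 10)) / 10
  lt <- lower.tri(A)
  expect_equal(mantel_test(A, C, n_perm = 99)$r, cor(A[lt], C[lt]),
               tolerance = 1e-12)
})

test_that("Mantel agrees with vegan and is valid under the exchangeable null", {
  skip_if_not_installed("vegan")
  set.seed(77)
  A <- tcrossprod(matrix(rnorm(20 * 20), 20)) / 20
  B <- tcrossprod(matrix(rnorm(20 * 20), 20)) / 20
  r_pkg <- mantel_test(A, B, n_perm = 99)$r
  r_veg <- vegan::mantel(as.dist(A), as.dist(B), permutations = 99)$statistic
  expect_equal(r_pkg, unname(r_veg), tolerance = 1e-10)

  # super-uniformity of p under independent random kernels
  set.seed(123)
  n <- 25
  A0 <- tcrossprod(matrix(rnorm(n * n), n)) / n
  rate <- mean(vapply(seq_len(200), function(i) {
    B0 <- tcrossprod(matrix(rnorm(n * n), n)) / n
    mantel_test(A0, B0, n_perm = 99, seed = i)$p < 0.05
  }, logical(1)))
  expect_lte(rate, 0.08)
})
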
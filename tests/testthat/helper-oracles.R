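# Independent oracles used across the suite. These deliberately use dense
# linear algebra (solve/determinant) and textbook formulas, not the package's
# eigendecomposition path.

# dense restricted log-likelihood (Patterson-Thompson, no log|X'X| term)
oracle_reml_loglik <- function(y, K, s2u, s2e, D = matrix(1, length(y), 1)) {
  n <- length(y); p <- ncol(D)
  V <- s2u * K + s2e * diag(n)
  Vi <- solve(V)
  DtViD <- t(D) %*% Vi %*% D
  P <- Vi - Vi %*% D %*% solve(DtViD, t(D) %*% Vi)
  -0.5 * ((n - p) * log(2 * pi) +
            as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(DtViD)$modulus) +
            drop(t(y) %*% P %*% y))
}

# profile the total variance analytically at ratio h, densely
oracle_profile_loglik <- function(h, y, K, D = matrix(1, length(y), 1)) {
  n <- length(y); p <- ncol(D)
  Vh <- h * K + (1 - h) * diag(n)
  Vi <- solve(Vh)
  DtViD <- t(D) %*% Vi %*% D
  P <- Vi - Vi %*% D %*% solve(DtViD, t(D) %*% Vi)
  Q <- drop(t(y) %*% P %*% y)
  s2p <- Q / (n - p)
  oracle_reml_loglik(y, K, h * s2p, (1 - h) * s2p, D)
}

# exhaustive grid maximization of the dense profile likelihood
oracle_grid_ratio <- function(y, K, D = matrix(1, length(y), 1),
                              step = 1e-4) {
  hs <- seq(1e-6, 1 - 1e-6, by = step)
  ll <- vapply(hs, function(h) oracle_profile_loglik(h, y, K, D), numeric(1))
  hs[which.max(ll)]
}

# textbook step-up Benjamini-Hochberg, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  pmin(adj, 1)
}

# two 4-member families; relatives share 0.5
family_kernel <- function() {
  kronecker(diag(2), matrix(0.5, 4, 4) + diag(0.5, 4))
}

# three fixed 8-individual REML oracle datasets (kernel, y)
reml_fixtures <- function() {
  K1 <- family_kernel()
  y1 <- c(0.63, -0.28, 1.33, 0.53, -1.52, 0.05, -1.26, -0.67)
  set.seed(42)
  B <- matrix(rnorm(8 * 8), 8)
  K2 <- tcrossprod(B) / 8
  y2 <- c(1.51, 0.39, -0.62, -2.21, 1.12, -0.04, -0.02, 0.94)
  K3 <- 0.8 * family_kernel() + 0.2 * diag(8)
  y3 <- c(2.40, 1.76, 2.09, 1.79, -0.29, -0.04, -0.45, 0.18)
  list(list(K = K1, y = y1), list(K = K2, y = y2), list(K = K3, y = y3))
}

# small deterministic simulated cohort shared by several tests
small_cohort <- function(seed = 7, n = 120, p = 400, taxa_h2 = rep(0.4, 6),
                         prevalence = rep(1, length(taxa_h2))) {
  sc <- sim_config(n, p, taxa_h2 = taxa_h2, taxa_prevalence = prevalence,
                   seed = seed)
  g <- simulate_genotypes(sc)
  list(config = sc, geno_raw = g, geno = qc_genotypes(g))
}
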
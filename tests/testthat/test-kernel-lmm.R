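test_that("REML ratio matches exhaustive dense grid search on fixed datasets", {
  for (fx in reml_fixtures()) {
    fit <- kernel_lmm(fx$y, fx$K)
    h_grid <- oracle_grid_ratio(fx$y, fx$K, step = 1e-3)
    expect_lt(abs(fit$ratio - h_grid), 2e-3)
    # engine log-likelihood at its optimum matches the dense evaluation
    expect_equal(fit$loglik_reml,
                 oracle_reml_loglik(fx$y, fx$K, fit$sigma_u2, fit$sigma_e2),
                 tolerance = 1e-8)
  }
})

test_that("restricted log-likelihood at fixed components matches dense MVN evaluation", {
  for (fx in reml_fixtures()) {
    for (comp in list(c(1, 1), c(0.3, 0.7), c(2.5, 0.4))) {
      expect_equal(reml_loglik(fx$y, fx$K, comp[1], comp[2]),
                   oracle_reml_loglik(fx$y, fx$K, comp[1], comp[2]),
                   tolerance = 1e-8)
    }
  }
})

test_that("fit is scale equivariant and invariant to joint permutation", {
  fx <- reml_fixtures()[[3]]
  fit <- kernel_lmm(fx$y, fx$K)
  fit_scaled <- kernel_lmm(10 * fx$y, fx$K)
  expect_equal(fit_scaled$ratio, fit$ratio, tolerance = 1e-6)
  expect_equal(fit_scaled$sigma_u2, 100 * fit$sigma_u2, tolerance = 1e-4)
  expect_equal(fit_scaled$sigma_e2, 100 * fit$sigma_e2, tolerance = 1e-4)

  perm <- c(5, 2, 8, 1, 4, 7, 3, 6)
  fit_perm <- kernel_lmm(fx$y[perm], fx$K[perm, perm])
  expect_equal(fit_perm$ratio, fit$ratio, tolerance = 1e-6)
  expect_equal(fit_perm$loglik_reml, fit$loglik_reml, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  K <- family_kernel()
  expect_error(kernel_lmm(rep(1, 8), K), "zero variance")
  bad <- K; bad[1, 2] <- 5  # asymmetric
  expect_error(kernel_lmm(rnorm(8), bad), "symmetric")
  neg <- diag(8); neg[1, 1] <- -1
  expect_error(kernel_lmm(rnorm(8), neg), "positive semi-definite")
})

test_that("null calibration: heritable calls on pure-noise traits stay below 10%", {
  n <- 80
  set.seed(314)
  B <- matrix(rnorm(n * n), n)
  K <- tcrossprod(B) / n
  eK <- eigen(K, symmetric = TRUE)
  calls <- vapply(seq_len(200), function(i) {
    y <- rnorm(n)
    fit <- kernel_lmm(y, K, eigen_K = eK)
    classify_heritable(fit)$heritable
  }, logical(1))
  expect_lte(mean(calls), 0.10)
})

test_that("classify_heritable applies the SE-multiple, p-value and grade rules", {
  stub <- function(ratio, se, p) {
    structure(list(ratio = ratio, ratio_se = se, p_value = p,
                   converged = TRUE), class = "kernel_lmm")
  }
  expect_equal(classify_heritable(stub(0.5, 0.1, 0.001)),
               list(heritable = TRUE, category = "high"))
  expect_equal(classify_heritable(stub(0.5, 0.3, 0.001)),
               list(heritable = FALSE, category = "nonheritable"))
  expect_equal(classify_heritable(stub(0.3, 0.1, 0.01)),
               list(heritable = TRUE, category = "moderate"))
  expect_equal(classify_heritable(stub(0.15, 0.05, 0.01)),
               list(heritable = TRUE, category = "low"))
  expect_error(
    classify_heritable(structure(list(converged = FALSE),
                                 class = "kernel_lmm")),
    "converge")
})

test_that("adjust_fixed_effects returns OLS residuals orthogonal to the design", {
  set.seed(99)
  n <- 60
  covs <- data.frame(subcohort = factor(sample(c("A", "B"), n, TRUE)),
                     parity = sample(1:5, n, TRUE),
                     age = runif(n, 3, 8),
                     dim = runif(n, 125, 185),
                     pH = runif(n, 5.5, 7))
  y <- rnorm(n)
  r <- adjust_fixed_effects(y, covs)
  X <- model.matrix(~ ., covs)
  expect_lt(max(abs(crossprod(X, r))), 1e-8)
  # equals the normal-equations solution computed independently
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(r, unname(drop(y - X %*% beta)), tolerance = 1e-10)
  # intercept-only covariates reduce to centering
  expect_equal(adjust_fixed_effects(y, NULL), y - mean(y))
})

test_that("collinear covariate columns are dropped with a warning naming them", {
  set.seed(5)
  covs <- data.frame(a = rnorm(20))
  covs$b <- 2 * covs$a
  expect_warning(r <- adjust_fixed_effects(rnorm(20), covs), "b")
  expect_length(r, 20)
})

test_that("methods on the fit object are coherent", {
  fx <- reml_fixtures()[[1]]
  fit <- kernel_lmm(fx$y, fx$K)
  expect_output(print(fit), "REML")
  expect_named(coef(fit), "(Intercept)")
  expect_equal(as.numeric(logLik(fit)), fit$loglik_reml)
  expect_equal(fit$ratio, fit$sigma_u2 / (fit$sigma_u2 + fit$sigma_e2),
               tolerance = 1e-10)
  # marginal residuals recenter y; conditional subtract the BLUP too
  expect_equal(residuals(fit), fx$y - fit$beta[1])
  expect_equal(predict(fit) + residuals(fit, "conditional"), fx$y,
               tolerance = 1e-10)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(8L, 3L))
  row <- as.data.frame(fit)
  expect_equal(row$ratio, fit$ratio)
})
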
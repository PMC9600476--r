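#' Single-kernel linear mixed model fitted by REML
#'
#' Fits the animal-model form
#' \deqn{y = X\beta + u + e, \quad u \sim N(0, \sigma_u^2 K), \quad
#'       e \sim N(0, \sigma_e^2 I)}
#' by restricted maximum likelihood and reports the variance ratio
#' \eqn{\sigma_u^2 / (\sigma_u^2 + \sigma_e^2)} — narrow-sense heritability
#' when `K` is a genomic relationship matrix, microbiability when `K` is a
#' microbiota relationship matrix.
#'
#' The kernel is eigendecomposed once; the REML log-likelihood is then profiled
#' analytically over the total variance and maximized over the ratio on
#' `box` by a 64-point coarse grid followed by bounded refinement
#' ([stats::optimize()]) to tolerance `tol`. The standard error of the ratio
#' comes from the curvature of the profile log-likelihood at the optimum
#' (central finite differences); the p-value tests \eqn{\sigma_u^2 = 0} by a
#' likelihood-ratio test against the boundary null with the usual
#' \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1} mixture.
#'
#' @param y numeric response vector (no missing values).
#' @param kernel n x n symmetric positive semi-definite relationship matrix
#'   (e.g. from [compute_grm()] or [build_mrm()]).
#' @param X fixed-effect design matrix; defaults to an intercept column.
#'   Must have full column rank.
#' @param eigen_K optional precomputed `eigen(kernel, symmetric = TRUE)`;
#'   supply when fitting many responses against the same kernel.
#' @param box lower and upper bounds for the ratio search; estimates at a box
#'   edge are flagged via the `boundary` field.
#' @param n_grid number of coarse grid points.
#' @param tol refinement tolerance on the ratio.
#'
#' @return An object of class `kernel_lmm` with fields `sigma_u2`, `sigma_e2`,
#'   `ratio`, `ratio_se`, `loglik_reml`, `p_value`, `converged`, `boundary`,
#'   `n_used`, `beta`, `beta_cov`, and the ingredients needed by the methods.
#'
#' @examples
#' K <- kronecker(diag(2), matrix(0.5, 4, 4) + diag(0.5, 4))
#' y <- c(rnorm(4, 1), rnorm(4, -1))
#' fit <- kernel_lmm(y, K)
#' summary(fit)
#' @seealso [classify_heritable()], [reml_loglik()]
#' @export
kernel_lmm <- function(y, kernel, X = NULL, eigen_K = NULL,
                       box = c(1e-6, 1 - 1e-6), n_grid = 64, tol = 1e-8) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("'y' contains missing values")
  if (stats::var(y) == 0) stop("'y' has zero variance")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design is rank deficient")
  if (n < p + 2) stop("need at least ", p + 2, " observations")

  if (is.null(eigen_K)) {
    check_kernel(kernel, n)
    eigen_K <- eigen(kernel, symmetric = TRUE)
  }
  d <- eigen_K$values
  if (min(d) < -1e-8 * max(1, max(d)))
    stop("kernel is not positive semi-definite within tolerance")
  d <- pmax(d, 0)
  U <- eigen_K$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  prof <- function(h) reml_profile(h, yt, Xt, d, n, p)$loglik

  # coarse grid: log-spaced toward both box edges so near-zero and near-one
  # optima are bracketed
  half <- n_grid %/% 2
  lo <- box[1]; hi <- box[2]
  grid <- c(exp(seq(log(lo), log(0.5), length.out = half)),
            1 - exp(seq(log(0.5), log(1 - hi), length.out = n_grid - half)))
  grid <- sort(unique(pmin(pmax(grid, lo), hi)))
  ll_grid <- vapply(grid, prof, numeric(1))
  i <- which.max(ll_grid)
  bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
  opt <- stats::optimize(prof, interval = bracket, maximum = TRUE, tol = tol)
  h_hat <- opt$maximum
  ll_hat <- opt$objective
  if (ll_grid[i] > ll_hat) { h_hat <- grid[i]; ll_hat <- ll_grid[i] }

  at <- reml_profile(h_hat, yt, Xt, d, n, p)
  s2p <- at$s2p
  sigma_u2 <- h_hat * s2p
  sigma_e2 <- (1 - h_hat) * s2p

  # SE: negative inverse curvature of the profile log-likelihood in the
  # ratio parameterization
  eps <- min(1e-4, (h_hat - lo) / 2, (hi - h_hat) / 2)
  ratio_se <- NA_real_
  if (eps > 0) {
    curv <- (prof(h_hat + eps) - 2 * ll_hat + prof(h_hat - eps)) / eps^2
    if (is.finite(curv) && curv < 0) ratio_se <- sqrt(-1 / curv)
  }

  # boundary LRT against sigma_u2 = 0 (ratio = 0): 1/2 chi0 + 1/2 chi1 mixture
  ll0 <- reml_profile(0, yt, Xt, d, n, p)$loglik
  lr <- max(0, 2 * (ll_hat - ll0))
  p_value <- 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)

  boundary <- (h_hat - lo) < 1e-5 || (hi - h_hat) < 1e-5

  structure(list(
    sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
    ratio = h_hat, ratio_se = ratio_se,
    loglik_reml = ll_hat, loglik_null = ll0, lr = lr, p_value = p_value,
    converged = TRUE, boundary = boundary, n_used = n,
    beta = at$beta, beta_cov = at$beta_cov * s2p,
    y = y, X = X, eigen_K = eigen_K, yt = yt, Xt = Xt, d = d,
    call = match.call()
  ), class = "kernel_lmm")
}

# profile REML log-likelihood at ratio h, total variance profiled out.
# Convention: l_R = -1/2 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ]
# (Patterson-Thompson without the constant log|X'X| term).
reml_profile <- function(h, yt, Xt, d, n, p) {
  w <- h * d + (1 - h)
  wi <- 1 / w
  XtW <- Xt * wi
  XtWX <- crossprod(Xt, XtW)
  XtWy <- drop(crossprod(XtW, yt))
  beta <- solve(XtWX, XtWy)
  Q <- sum(yt^2 * wi) - sum(XtWy * beta)
  s2p <- Q / (n - p)
  ld_V <- sum(log(w))
  ld_XVX <- as.numeric(determinant(XtWX, logarithm = TRUE)$modulus)
  ll <- -0.5 * ((n - p) * (log(2 * pi) + log(s2p) + 1) + ld_V + ld_XVX)
  list(loglik = ll, s2p = s2p, beta = beta, beta_cov = solve(XtWX))
}

#' REML log-likelihood at fixed variance components
#'
#' Evaluates the restricted log-likelihood of the single-kernel model at
#' user-supplied `sigma_u2`, `sigma_e2` (Patterson-Thompson form, omitting
#' the constant `log|X'X|` term). Useful for likelihood diagnostics and for
#' checking the fitted surface.
#'
#' @inheritParams kernel_lmm
#' @param sigma_u2,sigma_e2 non-negative variance components (`sigma_e2 > 0`).
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(y, kernel, sigma_u2, sigma_e2, X = NULL,
                        eigen_K = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  if (sigma_e2 <= 0) stop("'sigma_e2' must be positive")
  if (sigma_u2 < 0) stop("'sigma_u2' must be non-negative")
  if (is.null(eigen_K)) {
    check_kernel(kernel, n)
    eigen_K <- eigen(kernel, symmetric = TRUE)
  }
  d <- pmax(eigen_K$values, 0)
  U <- eigen_K$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  w <- sigma_u2 * d + sigma_e2
  wi <- 1 / w
  XtWX <- crossprod(Xt, Xt * wi)
  XtWy <- drop(crossprod(Xt * wi, yt))
  beta <- solve(XtWX, XtWy)
  Q <- sum(yt^2 * wi) - sum(XtWy * beta)
  -0.5 * ((n - p) * log(2 * pi) + sum(log(w)) +
            as.numeric(determinant(XtWX, logarithm = TRUE)$modulus) + Q)
}

check_kernel <- function(K, n) {
  if (!is.matrix(K) || nrow(K) != n || ncol(K) != n)
    stop("'kernel' must be an n x n matrix matching length(y)")
  if (max(abs(K - t(K))) > 1e-10 * max(1, max(abs(K))))
    stop("'kernel' is not symmetric within tolerance")
  invisible(TRUE)
}

#' @export
print.kernel_lmm <- function(x, digits = 4, ...) {
  cat("Single-kernel REML fit (n =", x$n_used, ")\n")
  cat(sprintf("  sigma_u2 = %.*g   sigma_e2 = %.*g\n",
              digits, x$sigma_u2, digits, x$sigma_e2))
  cat(sprintf("  ratio (h2/m2) = %.*g  (SE %.*g)\n",
              digits, x$ratio, digits, x$ratio_se))
  cat(sprintf("  REML logLik = %.*f   boundary-LRT p = %.3g\n",
              digits, x$loglik_reml, x$p_value))
  if (x$boundary) cat("  note: estimate at the search-box edge\n")
  invisible(x)
}

#' @export
summary.kernel_lmm <- function(object, ...) {
  z <- object$beta / sqrt(diag(as.matrix(object$beta_cov)))
  coefs <- cbind(Estimate = object$beta,
                 `Std. Error` = sqrt(diag(as.matrix(object$beta_cov))),
                 `z value` = z,
                 `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  rownames(coefs) <- colnames(object$X)
  out <- list(fit = object, coefficients = coefs)
  class(out) <- "summary.kernel_lmm"
  out
}

#' @export
print.summary.kernel_lmm <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects:\n")
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' @export
coef.kernel_lmm <- function(object, ...) object$beta

#' @export
logLik.kernel_lmm <- function(object, ...) {
  structure(object$loglik_reml, df = length(object$beta) + 2,
            nobs = object$n_used, class = "logLik")
}

#' Residuals of a kernel mixed-model fit
#'
#' `"marginal"` residuals are `y - X beta`; `"conditional"` residuals also
#' subtract the BLUP of the kernel random effect.
#' @param object a [kernel_lmm()] fit.
#' @param type `"marginal"` or `"conditional"`.
#' @param ... unused.
#' @export
residuals.kernel_lmm <- function(object, type = c("marginal", "conditional"),
                                 ...) {
  type <- match.arg(type)
  r <- object$y - drop(object$X %*% object$beta)
  if (type == "conditional") r <- r - blup_u(object)
  r
}

blup_u <- function(object) {
  w <- object$sigma_u2 * object$d + object$sigma_e2
  rt <- drop(crossprod(object$eigen_K$vectors,
                       object$y - drop(object$X %*% object$beta)))
  drop(object$eigen_K$vectors %*% (object$sigma_u2 * object$d * rt / w))
}

#' Fitted values (optionally including the BLUP random effect)
#' @param object a [kernel_lmm()] fit.
#' @param include_random add the BLUP of the kernel effect to `X beta`.
#' @param ... unused.
#' @export
predict.kernel_lmm <- function(object, include_random = TRUE, ...) {
  f <- drop(object$X %*% object$beta)
  if (include_random) f <- f + blup_u(object)
  f
}

#' Simulate responses from a fitted kernel mixed model
#' @param object a [kernel_lmm()] fit.
#' @param nsim number of response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a data.frame with `nsim` columns, as for [stats::simulate()].
#' @export
simulate.kernel_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_used
  U <- object$eigen_K$vectors
  sd_u <- sqrt(object$sigma_u2 * object$d)
  mu <- drop(object$X %*% object$beta)
  out <- replicate(nsim, mu + drop(U %*% (sd_u * stats::rnorm(n))) +
                     stats::rnorm(n, sd = sqrt(object$sigma_e2)))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Profile REML log-likelihood plot
#' @param x a [kernel_lmm()] fit.
#' @param n_points grid resolution for the curve.
#' @param ... passed to [graphics::plot()].
#' @export
plot.kernel_lmm <- function(x, n_points = 200, ...) {
  hs <- seq(1e-6, 1 - 1e-6, length.out = n_points)
  ll <- vapply(hs, function(h)
    reml_profile(h, x$yt, x$Xt, x$d, x$n_used, ncol(x$X))$loglik, numeric(1))
  graphics::plot(hs, ll, type = "l", xlab = "variance ratio",
                 ylab = "profile REML log-likelihood", ...)
  graphics::abline(v = x$ratio, lty = 2)
  invisible(x)
}

#' One-row data.frame serialization of a fit
#' @param x a [kernel_lmm()] fit.
#' @param ... unused.
#' @export
as.data.frame.kernel_lmm <- function(x, ...) {
  data.frame(sigma_u2 = x$sigma_u2, sigma_e2 = x$sigma_e2,
             ratio = x$ratio, ratio_se = x$ratio_se,
             loglik_reml = x$loglik_reml, p_value = x$p_value,
             converged = x$converged, boundary = x$boundary,
             n_used = x$n_used)
}

#' Adjust a trait for fixed effects by ordinary least squares
#'
#' Regresses `y` on an intercept plus the supplied covariates (factors are
#' expanded to indicators) and returns the residuals — the pre-correction
#' step applied to log abundances before the animal-model fit. Collinear
#' columns are dropped with a warning naming them.
#'
#' @param y numeric trait vector.
#' @param covariates data.frame of covariates aligned with `y` (may be NULL
#'   for intercept-only centering).
#' @return numeric residual vector, orthogonal to the retained design columns.
#' @export
adjust_fixed_effects <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("'y' contains missing values")
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    return(y - mean(y))
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(y))
    stop("covariates and 'y' have different lengths")
  if (anyNA(covariates)) stop("covariates contain missing values")
  X <- stats::model.matrix(~ ., data = covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning("dropping collinear columns: ", paste(drop_cols, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  if (length(y) <= ncol(X))
    stop("design has as many columns as observations after drops: ",
         paste(colnames(X), collapse = ", "))
  unname(drop(qr.resid(qx, y)))
}

#' Classify a variance-component fit as heritable or not
#'
#' A taxon is called heritable when the ratio exceeds twice its standard
#' error and the boundary-LRT p-value is below `alpha`. Heritable taxa are
#' graded `high` (ratio > 0.4), `moderate` (0.2 < ratio <= 0.4) or `low`.
#'
#' @param fit a converged [kernel_lmm()] fit.
#' @param se_ratio_min required ratio/SE multiple (default 2).
#' @param alpha p-value threshold (default 0.05).
#' @return list with `heritable` (logical) and `category`
#'   (`"high"`, `"moderate"`, `"low"` or `"nonheritable"`).
#' @export
classify_heritable <- function(fit, se_ratio_min = 2, alpha = 0.05) {
  if (!isTRUE(fit$converged))
    stop("fit did not converge; refusing to classify")
  heritable <- is.finite(fit$ratio_se) &&
    fit$ratio / fit$ratio_se > se_ratio_min && fit$p_value < alpha
  category <- if (!heritable) "nonheritable"
  else if (fit$ratio > 0.4) "high"
  else if (fit$ratio > 0.2) "moderate"
  else "low"
  list(heritable = heritable, category = category)
}
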
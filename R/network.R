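#' Thresholded Spearman correlation network
#'
#' Computes Spearman rank correlations for all unordered variable pairs
#' (pairwise-complete observations), two-sided p-values from the
#' large-sample t approximation (average ranks for ties), BH adjustment
#' over all tested pairs, and retains edges with `|rho|` strictly above
#' `rho_threshold` and adjusted p below `alpha`.
#'
#' @param variables numeric matrix or data.frame, samples in rows,
#'   variables (taxa, VFAs, milk traits) in columns.
#' @param roles optional named character vector tagging each variable
#'   (e.g. `"taxon"`, `"vfa"`, `"milk"`); carried onto the edges.
#' @param rho_threshold minimum absolute correlation, exclusive
#'   (default 0.2).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_obs minimum complete observations per pair (default 3).
#' @param exact for pairs with fewer than 10 complete observations, compute
#'   the p-value by permutation instead of the t approximation (full
#'   enumeration up to n = 7, otherwise 19999 random permutations with a
#'   fixed seed).
#' @return data.frame (class `correlation_network`) with columns `node_a`,
#'   `node_b`, `role_a`, `role_b`, `rho`, `p`, `p_adj`, `sign`, in a
#'   canonical (column-order) edge ordering; all tested pairs are kept in
#'   `attr(, "all_pairs")`.
#' @export
build_correlation_network <- function(variables, roles = NULL,
                                      rho_threshold = 0.2, alpha = 0.05,
                                      min_obs = 3, exact = FALSE) {
  x <- as.matrix(variables)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("v", seq_len(ncol(x)))
  keep <- apply(x, 2, function(v) stats::var(v, na.rm = TRUE) > 0)
  if (any(!keep | is.na(keep))) {
    drop <- colnames(x)[!keep | is.na(keep)]
    warning("excluding zero-variance variables: ",
            paste(drop, collapse = ", "))
    x <- x[, keep & !is.na(keep), drop = FALSE]
  }
  k <- ncol(x)
  if (k < 2) stop("need at least 2 variables with variation")
  if (is.null(roles)) roles <- stats::setNames(rep(NA_character_, k),
                                               colnames(x))
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(e) {
    i <- pairs[1, e]; j <- pairs[2, e]
    ok <- stats::complete.cases(x[, c(i, j)])
    n <- sum(ok)
    if (n < min_obs) return(NULL)
    xi <- x[ok, i]; xj <- x[ok, j]
    rho <- stats::cor(xi, xj, method = "spearman")
    p <- if (exact && n < 10) spearman_perm_p(xi, xj, rho)
         else spearman_t_p(rho, n)
    data.frame(node_a = colnames(x)[i], node_b = colnames(x)[j],
               role_a = unname(roles[colnames(x)[i]]),
               role_b = unname(roles[colnames(x)[j]]),
               rho = rho, p = p, n = n)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("no pair has enough complete observations")
  rows$p_adj <- bh_adjust(rows$p)
  edges <- rows[abs(rows$rho) > rho_threshold & rows$p_adj < alpha, ,
                drop = FALSE]
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  rownames(edges) <- NULL
  attr(edges, "all_pairs") <- rows
  class(edges) <- c("correlation_network", class(edges))
  edges
}

# two-sided p from t = rho * sqrt((n-2)/(1-rho^2)); exact +/-1 maps to 0
spearman_t_p <- function(rho, n) {
  if (n < 3) return(NA_real_)
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

spearman_perm_p <- function(xi, xj, rho_obs) {
  n <- length(xi)
  ri <- rank(xi); rj <- rank(xj)
  if (n <= 7) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(idx) stats::cor(ri, rj[idx]))
  } else {
    set.seed(20220422L)
    rhos <- replicate(19999, stats::cor(ri, rj[sample.int(n)]))
  }
  (1 + sum(abs(rhos) >= abs(rho_obs) - 1e-12)) / (1 + length(rhos))
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
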
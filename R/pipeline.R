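#' Energy-corrected milk yield
#'
#' `ECM (kg/d) = 0.3246 * MY + 13.86 * MFY + 7.04 * MPY`, all in kg/d.
#'
#' @param my milk yield (kg/d, >= 0).
#' @param mfy milk fat yield (kg/d, >= 0).
#' @param mpy milk protein yield (kg/d, >= 0).
#' @return energy-corrected milk yield (kg/d), vectorized.
#' @export
compute_ecm <- function(my, mfy, mpy) {
  if (any(my < 0) || any(mfy < 0) || any(mpy < 0))
    stop("yields must be non-negative")
  0.3246 * my + 13.86 * mfy + 7.04 * mpy
}

#' Mean microbiability of a subcommunity
#'
#' The average single-taxon contribution: the subcommunity's microbiability
#' divided by its taxon count, \eqn{\beta^2 = m^2 / o}.
#'
#' @param m2 microbiability in `[0, 1]`.
#' @param o number of taxa in the subcommunity (>= 1).
#' @return mean microbiability as a proportion; use [percent_round()] for
#'   the conventional two-decimal percentage presentation.
#' @export
mean_microbiability <- function(m2, o) {
  if (any(o < 1)) stop("'o' must be at least 1")
  if (any(m2 < 0) || any(m2 > 1)) stop("'m2' must lie in [0, 1]")
  m2 / o
}

#' Round a proportion to a percentage, half away from zero
#'
#' Converts a proportion to a percentage and rounds half-away-from-zero to
#' `digits` decimals (the usual presentation convention; base [round()]
#' rounds half to even, which differs on exact ties such as 0.90625).
#'
#' @param x proportion(s).
#' @param digits decimal places (default 2).
#' @return percentage(s).
#' @export
percent_round <- function(x, digits = 2) {
  scaled <- 100 * x * 10^digits
  sign(scaled) * floor(abs(scaled) + 0.5) / 10^digits
}

#' Per-taxon heritability from a genomic kernel
#'
#' For each detected taxon: abundances are `log10(proportion + delta)` with
#' `delta` half the smallest nonzero proportion in the whole table, adjusted
#' for fixed effects (subcohort, parity, age, days-in-milk, pH) by OLS
#' ([adjust_fixed_effects()]), then fitted against `G` with an
#' intercept-only animal model ([kernel_lmm()]) and classified by
#' [classify_heritable()].
#'
#' @param taxa abundance matrix restricted to detected taxa (samples in the
#'   same order as `G`).
#' @param G genomic relationship matrix from [compute_grm()].
#' @param covariates data.frame of fixed effects aligned with the samples
#'   (may be NULL for intercept-only adjustment).
#' @param eigen_G optional precomputed eigendecomposition of `G`.
#' @return data.frame (class `heritability_result`) with one row per taxon:
#'   `taxon_id`, `h2`, `se`, `p_value`, `loglik`, `converged`, `boundary`,
#'   `heritable`, `category`; the pseudocount is attached as
#'   `attr(, "delta")` and the id partition as `attr(, "partition")`.
#' @export
estimate_taxon_heritability <- function(taxa, G, covariates = NULL,
                                        eigen_G = NULL) {
  x <- unclass(as.matrix(taxa))
  if (!identical(rownames(x), rownames(G)))
    stop("sample ids of taxa table and G do not match: ",
         paste(utils::head(setdiff(rownames(x), rownames(G)), 5),
               collapse = ", "))
  if (is.null(eigen_G)) eigen_G <- eigen(G, symmetric = TRUE)
  nz <- x[x > 0]
  if (!length(nz)) stop("taxa table is all zero")
  delta <- min(nz) / 2
  res <- lapply(colnames(x), function(id) {
    ylog <- log10(x[, id] + delta)
    yadj <- adjust_fixed_effects(ylog, covariates)
    fit <- kernel_lmm(yadj, G, eigen_K = eigen_G)
    cls <- classify_heritable(fit)
    data.frame(taxon_id = id, h2 = fit$ratio, se = fit$ratio_se,
               p_value = fit$p_value, loglik = fit$loglik_reml,
               converged = fit$converged, boundary = fit$boundary,
               heritable = cls$heritable, category = cls$category)
  })
  out <- do.call(rbind, res)
  attr(out, "delta") <- delta
  attr(out, "partition") <- list(
    heritable = out$taxon_id[out$heritable],
    nonheritable = out$taxon_id[!out$heritable])
  class(out) <- c("heritability_result", class(out))
  out
}

#' Subcommunity microbiability for host traits
#'
#' For each trait and each subcommunity (the heritable subset and its
#' complement among the table's taxa): builds the microbiota relationship
#' matrix on that subset ([build_mrm()]), fits the mixed model with fixed
#' effects subcohort, parity, age and days-in-milk carried inside the model
#' ([kernel_lmm()]), and reports the microbiability `m2` and the mean
#' microbiability `beta2 = m2 / o` with `o` the subset size.
#'
#' A subcommunity with fewer than 2 taxa is skipped with a message; an
#' absent or constant trait yields a per-trait skip, other traits proceed.
#'
#' @param phenos data.frame with trait columns and covariates `subcohort`,
#'   `parity`, `age`, `days_in_milk`, rownames or `sample_id` matching the
#'   taxa table rows.
#' @param taxa abundance matrix restricted to detected taxa.
#' @param heritable_ids taxon ids of the heritable subcommunity.
#' @param traits character vector of trait column names to analyze.
#' @return data.frame (class `microbiability_result`) with columns `trait`,
#'   `group`, `m2`, `m2_se`, `p_value`, `o`, `beta2`.
#' @export
estimate_microbiability <- function(phenos, taxa, heritable_ids, traits) {
  x <- unclass(as.matrix(taxa))
  phenos <- as.data.frame(phenos)
  ids <- if ("sample_id" %in% names(phenos)) as.character(phenos$sample_id)
         else rownames(phenos)
  if (!identical(ids, rownames(x)))
    stop("sample ids of phenotypes and taxa table do not match")
  bad <- setdiff(heritable_ids, colnames(x))
  if (length(bad))
    stop("heritable ids not in table: ", paste(bad, collapse = ", "))
  need <- c("subcohort", "parity", "age", "days_in_milk")
  if (!all(need %in% names(phenos)))
    stop("missing covariates: ",
         paste(setdiff(need, names(phenos)), collapse = ", "))
  X <- stats::model.matrix(~ subcohort + parity + age + days_in_milk,
                           data = phenos)
  groups <- list(heritable = intersect(colnames(x), heritable_ids),
                 nonheritable = setdiff(colnames(x), heritable_ids))
  rows <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    if (length(sub) < 2) {
      message("skipping group '", g, "': fewer than 2 taxa")
      next
    }
    M <- build_mrm(x, sub)
    eM <- eigen(M, symmetric = TRUE)
    o <- length(sub)
    for (tr in traits) {
      if (!tr %in% names(phenos) ||
          !is.numeric(phenos[[tr]]) || stats::var(phenos[[tr]]) == 0) {
        message("skipping trait '", tr, "' (absent or constant)")
        next
      }
      fit <- kernel_lmm(phenos[[tr]], M, X = X, eigen_K = eM)
      rows[[paste(g, tr)]] <- data.frame(
        trait = tr, group = g, m2 = fit$ratio, m2_se = fit$ratio_se,
        p_value = fit$p_value, o = o,
        beta2 = mean_microbiability(fit$ratio, o))
    }
  }
  if (!length(rows)) stop("no trait-group combination could be fitted")
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("microbiability_result", class(out))
  out
}
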
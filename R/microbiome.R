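#' Taxa relative-abundance table
#'
#' Validates an individuals-by-taxa matrix of proportions: entries in
#' `[0, 1]`, rows summing to 1 within `tol` (rows are renormalized to sum
#' exactly to 1 when within tolerance).
#'
#' @param abundance numeric matrix, samples in rows, taxa in columns.
#' @param tol row-sum tolerance (default 1e-8).
#' @return matrix of class `taxa_table` with unique dimnames.
#' @export
taxa_table <- function(abundance, tol = 1e-8) {
  x <- as.matrix(abundance)
  if (ncol(x) < 1 || nrow(x) < 1) stop("empty taxa table")
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("ind_%04d", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("taxon_%04d", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop("sample and taxon ids must be unique")
  if (anyNA(x) || any(x < 0) || any(x > 1))
    stop("abundances must be proportions in [0, 1]")
  rs <- rowSums(x)
  if (any(abs(rs - 1) > tol))
    stop("rows must sum to 1 within ", tol)
  x <- x / rs
  class(x) <- c("taxa_table", class(x))
  x
}

#' Per-taxon prevalence
#'
#' Fraction of samples in which each taxon has abundance strictly above zero.
#' @param table a [taxa_table()] (or plain abundance matrix).
#' @return named numeric vector in `[0, 1]`.
#' @export
taxon_prevalence <- function(table) colMeans(unclass(as.matrix(table)) > 0)

#' Detection filtering and core/noncore classification
#'
#' Taxa present in at least `detect_min` of samples are *detected*; detected
#' taxa present in at least `core_min` are *core*, the rest *noncore* (both
#' boundaries inclusive on the lower side, matching "at least").
#' Undetected taxa are removed from the returned table.
#'
#' @param table a [taxa_table()].
#' @param detect_min detection prevalence threshold (default 0.20).
#' @param core_min core prevalence threshold (default 0.50).
#' @return list with `table` (detected taxa only, *not* re-closed: rows keep
#'   their original proportions) and `classification`, a data.frame with
#'   `taxon_id`, `prevalence`, `detected`, `core_status`
#'   (`core` / `noncore` / `undetected`).
#' @export
filter_and_classify_taxa <- function(table, detect_min = 0.20,
                                     core_min = 0.50) {
  x <- unclass(as.matrix(table))
  if (ncol(x) == 0 || nrow(x) == 0) stop("empty taxa table")
  prev <- colMeans(x > 0)
  detected <- prev >= detect_min
  core_status <- ifelse(!detected, "undetected",
                        ifelse(prev >= core_min, "core", "noncore"))
  cls <- data.frame(taxon_id = colnames(x), prevalence = prev,
                    detected = detected, core_status = core_status,
                    row.names = NULL)
  list(table = x[, detected, drop = FALSE], classification = cls)
}

#' Microbiota relationship matrix
#'
#' Builds the kernel \eqn{M = (1/q) O O'} where `O` column-standardizes the
#' log of (proportion + 1) for the chosen taxa:
#' \deqn{O_{ij} = \frac{\log S_{ij} - \overline{\log S_{\cdot j}}}
#'                     {\mathrm{sd}(\log S_{\cdot j})}, \qquad
#'       S_{ij} = \text{proportion}_{ij} + 1.}
#' The sample standard deviation uses the `n - 1` denominator, so
#' `trace(M) = n - 1`. The log base is irrelevant (it cancels in the
#' standardization). Zero-variance columns are dropped with a warning and
#' `q` reduced accordingly.
#'
#' @param table a [taxa_table()] or abundance matrix of proportions.
#' @param taxa_subset taxon ids (column names) to include; defaults to all.
#' @return symmetric PSD n x n matrix with `attr(, "kind") == "microbial"`
#'   and `attr(, "q")` the number of taxa used.
#' @export
build_mrm <- function(table, taxa_subset = NULL) {
  x <- unclass(as.matrix(table))
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("taxon_%04d", seq_len(ncol(x)))
  if (is.null(taxa_subset)) taxa_subset <- colnames(x)
  missing_ids <- setdiff(taxa_subset, colnames(x))
  if (length(missing_ids))
    stop("taxa not in table: ", paste(missing_ids, collapse = ", "))
  x <- x[, taxa_subset, drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 samples")
  L <- log(x + 1)
  sds <- apply(L, 2, stats::sd)
  zero_sd <- sds == 0
  if (any(zero_sd)) {
    warning("dropping ", sum(zero_sd), " zero-variance taxa: ",
            paste(colnames(x)[zero_sd], collapse = ", "))
    L <- L[, !zero_sd, drop = FALSE]
    sds <- sds[!zero_sd]
  }
  q <- ncol(L)
  if (q < 2) stop("fewer than 2 taxa with variation; kernel degenerate")
  O <- sweep(sweep(L, 2, colMeans(L)), 2, sds, "/")
  M <- tcrossprod(O) / q
  M <- (M + t(M)) / 2
  dimnames(M) <- list(rownames(x), rownames(x))
  attr(M, "kind") <- "microbial"
  attr(M, "q") <- q
  M
}

#' Prevalence and abundance summaries for taxon subcommunities
#'
#' Splits the detected taxa into a named group (e.g. heritable) and its
#' complement, and reports, per group, the mean per-taxon prevalence (as a
#' percentage) and the mean per-animal summed relative abundance (as a
#' percentage).
#'
#' @param table abundance matrix restricted to detected taxa.
#' @param heritable_ids taxon ids forming the first group; must be columns
#'   of `table`.
#' @return data.frame with one row per group (`heritable`, `nonheritable`)
#'   and columns `n_taxa`, `mean_presence_pct`, `mean_abundance_pct`.
#' @export
summarize_subcommunities <- function(table, heritable_ids) {
  x <- unclass(as.matrix(table))
  bad <- setdiff(heritable_ids, colnames(x))
  if (length(bad))
    stop("ids not in table: ", paste(bad, collapse = ", "))
  groups <- list(heritable = heritable_ids,
                 nonheritable = setdiff(colnames(x), heritable_ids))
  out <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    if (!length(ids))
      return(data.frame(group = g, n_taxa = 0L,
                        mean_presence_pct = NA_real_,
                        mean_abundance_pct = NA_real_))
    sub <- x[, ids, drop = FALSE]
    data.frame(group = g, n_taxa = length(ids),
               mean_presence_pct = 100 * mean(colMeans(sub > 0)),
               mean_abundance_pct = 100 * mean(rowSums(sub)))
  })
  do.call(rbind, out)
}
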
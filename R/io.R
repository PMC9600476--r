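# All tables are TSV with a header row, ids as strings in column 1 and
# missing values as empty fields.

#' Write a matrix or data.frame as TSV
#' @param x matrix (row ids become column `id`) or data.frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  if (is.matrix(x)) {
    x <- data.frame(id = rownames(x), as.data.frame(unclass(x)),
                    check.names = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input file.
#' @param as_matrix restore an `id`-column file as a rownamed numeric matrix.
#' @export
read_tsv <- function(path, as_matrix = FALSE) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, na.strings = "",
                         colClasses = NA, stringsAsFactors = FALSE)
  if (as_matrix) {
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- as.character(d[[1]])
    storage.mode(m) <- "double"
    return(m)
  }
  d
}

#' Read a genotype dosage TSV
#'
#' Expects samples in rows (ids in column 1), SNPs in columns, additive
#' dosages 0/1/2 with empty fields for missing calls; an optional variant
#' map TSV supplies `snp_id`, `chrom`, `bp`.
#' @param path genotype TSV.
#' @param map_path optional variant map TSV.
#' @return a [genotypes()] object.
#' @export
read_genotypes <- function(path, map_path = NULL) {
  m <- read_tsv(path, as_matrix = TRUE)
  map <- if (!is.null(map_path)) read_tsv(map_path) else NULL
  genotypes(m, map)
}

#' Read a PLINK-dialect additive export (.raw)
#'
#' Whitespace-separated file with columns FID IID PAT MAT SEX PHENOTYPE
#' followed by one 0/1/2 dosage column per SNP (`NA` for missing). Sample
#' ids are taken from IID; SNP ids from the headers (a trailing
#' `_<allele>` counting suffix is stripped).
#' @param path `.raw` file.
#' @return a [genotypes()] object.
#' @export
read_plink_raw <- function(path) {
  d <- utils::read.table(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(d)))
    stop("not a PLINK additive export: missing ",
         paste(setdiff(meta, names(d)), collapse = ", "))
  snp_cols <- setdiff(names(d), meta)
  m <- as.matrix(d[, snp_cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d$IID)
  colnames(m) <- sub("_[ACGT0-9]+$", "", snp_cols)
  genotypes(m)
}

#' Default analysis thresholds
#'
#' The conventional thresholds used throughout: detection prevalence 0.20,
#' core prevalence 0.50, MAF 0.05, call rate 0.90, heritable-SE multiple 2,
#' heritable p 0.05, FDR tiers 0.01/0.05, network `|rho|` 0.2 and adjusted
#' p 0.05, Mantel permutations 9999.
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(detect_min = 0.20, core_min = 0.50, maf_min = 0.05,
       call_rate_min = 0.90, se_ratio_min = 2, h2_alpha = 0.05,
       fdr_significant = 0.01, fdr_suggestive = 0.05,
       edge_rho = 0.2, edge_alpha = 0.05, mantel_n_perm = 9999)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: genotype QC, GRM, taxa detection/classification,
#' per-taxon heritability, heritable/nonheritable partition, subcommunity
#' microbiability and mean microbiability for the requested traits,
#' mixed-model GWAS on the heritable taxa, the G-vs-M Mantel test, and the
#' heritable-taxa/trait correlation network. Inputs are either file paths or
#' a simulation block. Every stage writes a TSV into `out_dir`; a manifest
#' with MD5 hashes, the resolved configuration and a human-readable summary
#' are written alongside. Re-running with the same configuration and seed
#' reproduces every file bit-identically.
#'
#' @param config named list, or path to a YAML file with the same structure.
#'   Recognized fields: `simulate` (list passed to [sim_config()]), or
#'   `genotype_file` / `map_file` / `taxa_file` / `phenotype_file`;
#'   `traits` (default: all trait columns present); `thresholds`
#'   (overrides of [default_thresholds()]); `seed`; `out_dir`.
#' @param out_dir output directory (overrides the config entry).
#' @param seed seed (overrides the config entry).
#' @return invisibly, a list with the stage results and the manifest
#'   data.frame.
#' @export
run_full_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$out_dir)) stop("'out_dir' is required")
  if (is.null(config$seed)) config$seed <- 1L
  th <- utils::modifyList(default_thresholds(),
                          config$thresholds %||% list())
  config$thresholds <- th
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  log_counts <- list()
  if (!is.null(config$simulate)) {
    sc <- do.call(sim_config, c(config$simulate, list(seed = config$seed)))
    geno_raw <- simulate_genotypes(sc)
    taxa_sim <- simulate_taxa_abundances(geno_raw, sc)
    ph_sim <- simulate_phenotypes(taxa_sim$table, sc,
                                  detect_min = th$detect_min)
    taxa_full <- taxa_sim$table
    phenos <- ph_sim$phenotypes
    write_tsv(unclass(taxa_full), file.path(config$out_dir, "taxa.tsv"))
    write_tsv(phenos, file.path(config$out_dir, "phenotypes.tsv"))
    truth <- data.frame(taxon_id = names(taxa_sim$truth$h2),
                        true_h2 = taxa_sim$truth$h2, row.names = NULL)
    write_tsv(truth, file.path(config$out_dir, "truth_taxa.tsv"))
    write_tsv(data.frame(trait = names(ph_sim$truth$m2),
                         true_m2 = ph_sim$truth$m2, row.names = NULL),
              file.path(config$out_dir, "truth_traits.tsv"))
  } else {
    geno_raw <- read_genotypes(config$genotype_file, config$map_file)
    taxa_full <- taxa_table(read_tsv(config$taxa_file, as_matrix = TRUE))
    phenos <- read_tsv(config$phenotype_file)
  }

  geno <- qc_genotypes(geno_raw, th$maf_min, th$call_rate_min)
  log_counts$snps_dropped <-
    attr(geno, "qc_report")$n_input - attr(geno, "qc_report")$n_kept
  G <- compute_grm(geno)
  write_tsv(G, file.path(config$out_dir, "grm.tsv"))

  fc <- filter_and_classify_taxa(taxa_full, th$detect_min, th$core_min)
  log_counts$taxa_dropped <- sum(!fc$classification$detected)
  write_tsv(fc$classification,
            file.path(config$out_dir, "taxa_classification.tsv"))

  covars <- phenos[, intersect(c("subcohort", "parity", "age",
                                 "days_in_milk", "pH"), names(phenos)),
                   drop = FALSE]
  h2 <- estimate_taxon_heritability(fc$table, G, covariates = covars)
  log_counts$fits_nonconverged <- sum(!h2$converged)
  write_tsv(as.data.frame(h2), file.path(config$out_dir, "heritability.tsv"))
  part <- attr(h2, "partition")
  write_tsv(data.frame(taxon_id = c(part$heritable, part$nonheritable),
                       group = rep(c("heritable", "nonheritable"),
                                   c(length(part$heritable),
                                     length(part$nonheritable)))),
            file.path(config$out_dir, "partition.tsv"))

  traits <- config$traits %||%
    setdiff(names(phenos)[vapply(phenos, is.numeric, logical(1))],
            c("parity", "age", "days_in_milk", "pH"))
  m2 <- NULL
  if (length(part$heritable) >= 2 || length(part$nonheritable) >= 2) {
    m2 <- estimate_microbiability(phenos, fc$table, part$heritable, traits)
    m2out <- as.data.frame(m2)
    m2out$beta2_pct <- percent_round(m2out$beta2)
    write_tsv(m2out, file.path(config$out_dir, "microbiability.tsv"))
  }

  M <- build_mrm(fc$table)
  mant <- mantel_test(G, M, n_perm = th$mantel_n_perm, seed = config$seed)
  write_tsv(data.frame(r = mant$r, p = mant$p, n_perm = mant$n_perm),
            file.path(config$out_dir, "mantel.tsv"))

  gwas <- NULL
  if (length(part$heritable) >= 1) {
    delta <- attr(h2, "delta")
    vals <- lapply(part$heritable, function(id)
      adjust_fixed_effects(log10(fc$table[, id] + delta), covars))
    names(vals) <- part$heritable
    gwas <- run_mm_gwas(vals, geno, G)
    write_tsv(as.data.frame(gwas), file.path(config$out_dir, "gwas.tsv"))
  }

  net <- NULL
  trait_cols <- intersect(traits, names(phenos))
  if (length(part$heritable) >= 1 && length(trait_cols) >= 1) {
    vars <- cbind(fc$table[, part$heritable, drop = FALSE],
                  as.matrix(phenos[, trait_cols, drop = FALSE]))
    roles <- stats::setNames(
      c(rep("taxon", length(part$heritable)),
        rep("trait", length(trait_cols))),
      c(part$heritable, trait_cols))
    net <- tryCatch(
      build_correlation_network(vars, roles, th$edge_rho, th$edge_alpha),
      error = function(e) NULL)
    if (!is.null(net))
      write_tsv(as.data.frame(net), file.path(config$out_dir, "network.tsv"))
  }

  echo <- config
  echo$out_dir <- NULL  # keep the echoed config location independent
  yaml::write_yaml(echo, file.path(config$out_dir, "resolved_config.yaml"))
  files <- sort(setdiff(list.files(config$out_dir),
                        c("manifest.tsv", "summary.txt")))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files))),
    row.names = NULL)
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))

  summary_lines <- c(
    "microherit pipeline summary",
    sprintf("seed: %s", config$seed),
    sprintf("samples: %d  SNPs kept: %d  SNPs dropped: %d",
            nrow(geno$dosage), ncol(geno$dosage), log_counts$snps_dropped),
    sprintf("taxa detected: %d  undetected dropped: %d",
            ncol(fc$table), log_counts$taxa_dropped),
    sprintf("heritable taxa: %d  nonheritable: %d",
            length(part$heritable), length(part$nonheritable)),
    sprintf("non-converged fits: %d", log_counts$fits_nonconverged),
    sprintf("Mantel G vs M: r = %.4f, p = %.4g", mant$r, mant$p))
  writeLines(summary_lines, file.path(config$out_dir, "summary.txt"))

  invisible(list(genotypes = geno, G = G, classification = fc$classification,
                 heritability = h2, partition = part, microbiability = m2,
                 mantel = mant, gwas = gwas, network = net,
                 manifest = manifest, log_counts = log_counts,
                 config = config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
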
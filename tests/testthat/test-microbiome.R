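make_table <- function(x) {
  x <- cbind(x, filler = pmax(1 - rowSums(x), 0))
  taxa_table(x / rowSums(x))
}

test_that("prevalence classification applies the 20%/50% boundaries inclusively", {
  x <- matrix(0, 5, 3, dimnames = list(NULL, c("t_core", "t_edge", "t_out")))
  x[1:3, 1] <- 0.1          # prevalence 0.6 -> core
  x[1, 2] <- 0.1            # prevalence 0.2 -> detected, noncore
  # column 3 stays absent      prevalence 0.0 -> undetected
  tab <- make_table(x)
  fc <- filter_and_classify_taxa(tab)
  cls <- fc$classification
  expect_equal(cls$core_status[cls$taxon_id == "t_core"], "core")
  expect_equal(cls$core_status[cls$taxon_id == "t_edge"], "noncore")
  expect_equal(cls$core_status[cls$taxon_id == "t_out"], "undetected")
  expect_false("t_out" %in% colnames(fc$table))
  # exactly 50% prevalence is core
  y <- matrix(0, 4, 1, dimnames = list(NULL, "t_half"))
  y[1:2, 1] <- 0.2
  fc2 <- filter_and_classify_taxa(make_table(y))
  expect_equal(fc2$classification$core_status[1], "core")
})

test_that("classification matches the brute-force prevalence rule on a random table", {
  set.seed(33)
  x <- matrix(rexp(50 * 30), 50, 30) * rbinom(50 * 30, 1, 0.5)
  colnames(x) <- sprintf("t%02d", 1:30)
  tab <- taxa_table(x / rowSums(x))
  fc <- filter_and_classify_taxa(tab)
  prev <- colMeans(x > 0)
  expect_equal(fc$classification$prevalence, unname(prev))
  expect_identical(fc$classification$detected, unname(prev >= 0.2))
  expect_identical(
    fc$classification$core_status,
    unname(ifelse(prev < 0.2, "undetected",
                  ifelse(prev >= 0.5, "core", "noncore"))))
  cls <- fc$classification
  expect_equal(sum(cls$core_status == "core") +
                 sum(cls$core_status == "noncore"), sum(cls$detected))
})

test_that("M = (1/q) O O' has trace n - 1 and is log-base invariant", {
  set.seed(8)
  x <- matrix(rexp(20 * 6), 20, 6)
  tab <- taxa_table(x / rowSums(x))
  M <- build_mrm(tab)
  n <- nrow(tab)
  expect_equal(sum(diag(M)), n - 1, tolerance = 1e-8)
  expect_true(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) >
                -1e-8)

  # base-10 standardization gives the identical kernel
  S <- unclass(tab) + 1
  L10 <- log10(S)
  O10 <- scale(L10)
  M10 <- tcrossprod(O10) / ncol(O10)
  expect_equal(unclass(M), unclass(M10), ignore_attr = TRUE,
               tolerance = 1e-12)

  # invariant to sample order up to the same permutation
  perm <- sample(n)
  M2 <- build_mrm(unclass(tab)[perm, ])
  expect_equal(unclass(M2), unclass(M)[perm, perm], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("zero-variance taxa are dropped from the kernel with q reduced", {
  set.seed(4)
  a <- runif(12, 0.1, 0.3); b <- runif(12, 0.1, 0.3)
  tab <- cbind(a = a, b = b, flat = 0.2, filler = 1 - a - b - 0.2)
  expect_warning(M <- build_mrm(tab, c("a", "b", "flat")), "flat")
  expect_equal(attr(M, "q"), 2)
  expect_equal(sum(diag(M)), nrow(tab) - 1, tolerance = 1e-8)
  expect_error(suppressWarnings(build_mrm(tab, c("a", "flat"))),
               "degenerate")
})

test_that("subcommunity summaries match brute-force recomputation and partition", {
  set.seed(12)
  x <- matrix(rexp(40 * 10), 40, 10) * rbinom(40 * 10, 1, 0.8)
  colnames(x) <- sprintf("t%02d", 1:10)
  tab <- taxa_table(x / pmax(rowSums(x), 1e-300))
  her <- c("t01", "t04", "t07")
  s <- summarize_subcommunities(tab, her)
  sub <- unclass(tab)[, her]
  expect_equal(s$mean_presence_pct[s$group == "heritable"],
               100 * mean(colMeans(sub > 0)))
  expect_equal(s$mean_abundance_pct[s$group == "heritable"],
               100 * mean(rowSums(sub)))
  # the two groups' abundances add to the total per animal
  other <- setdiff(colnames(tab), her)
  expect_equal(rowSums(unclass(tab)[, her]) + rowSums(unclass(tab)[, other]),
               rowSums(unclass(tab)), tolerance = 1e-10)
  expect_equal(sum(s$mean_abundance_pct), 100, tolerance = 1e-8)
  # two-taxon arithmetic check
  y <- matrix(0, 5, 2, dimnames = list(NULL, c("p4", "p6")))
  y[1:2, 1] <- 0.1; y[1:3, 2] <- 0.1
  s2 <- summarize_subcommunities(make_table(y), c("p4", "p6"))
  expect_equal(s2$mean_presence_pct[s2$group == "heritable"], 50)
  expect_error(summarize_subcommunities(tab, "nope"), "not in table")
})
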
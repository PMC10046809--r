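test_that("per-age aggregation averages genes over valid samples, then over the set", {
  ds <- toy_dataset()
  # single constant gene: mean 7-like value, degenerate CI equal to the mean
  single <- group_age_series(ds, NULL, "gA")
  expect_equal(single$mean, rep(10, 3))
  expect_equal(single$ci_low, single$mean)
  expect_equal(single$ci_high, single$mean)
  expect_equal(single$n_genes, rep(1L, 3))

  # two genes with per-age means 10 and 20 -> set mean 15
  pair <- group_age_series(ds, NULL, c("gA", "gB"))
  expect_equal(pair$mean, rep(15, 3))
  expect_true(all(pair$ci_low <= pair$mean & pair$mean <= pair$ci_high))
})

test_that("confidence interval follows mean +/- 1.96 sd / sqrt(n) across gene means", {
  ds <- toy_dataset()
  all4 <- group_age_series(ds, NULL, c("gA", "gB", "gC", "gD"))
  gene_means <- c(10, 20, 5, 1)
  half <- 1.96 * sd(gene_means) / sqrt(4)
  expect_equal(all4$mean, rep(mean(gene_means), 3))
  expect_equal(all4$ci_high - all4$mean, rep(half, 3))
})

test_that("invalid cells are excluded complete-case within age", {
  ds <- toy_dataset()
  ds$mask["gA", "liver@1"] <- FALSE # gA at age 1 now only from brain
  out <- group_age_series(ds, NULL, c("gA", "gB"))
  expect_equal(out$mean[out$age == 1], 15) # gA constant, so unchanged
  ds$mask["gA", ] <- FALSE # gA fully invalid: drops from the set
  out2 <- group_age_series(ds, NULL, c("gA", "gB"))
  expect_equal(out2$mean, rep(20, 3))
  expect_equal(out2$n_genes, rep(1L, 3))
  ds$mask[, ] <- FALSE
  expect_error(group_age_series(ds, NULL, c("gA", "gB")), "no valid cell at age")
})

test_that("aggregation is linear: scaling the matrix scales means and CI bounds", {
  sim <- simulate_dataset(small_config(seed = 21))
  ctl <- truth_catalog(sim$truth)
  base <- group_age_series(sim$dataset, ctl, "HG")
  scaled_ds <- sim$dataset
  scaled_ds$values <- scaled_ds$values * 3.7
  scaled <- group_age_series(scaled_ds, ctl, "HG")
  expect_equal(scaled$mean, base$mean * 3.7)
  expect_equal(scaled$ci_low, base$ci_low * 3.7)
  expect_equal(scaled$ci_high, base$ci_high * 3.7)
})

test_that("HG and IntG series use disjoint gene sets covering the universe", {
  sim <- simulate_dataset(small_config(seed = 22))
  ctl <- truth_catalog(sim$truth)
  hg_genes <- ctl$gene[ctl$group == "HG"]
  intg_genes <- ctl$gene[ctl$group == "IntG"]
  expect_length(intersect(hg_genes, intg_genes), 0)
  expect_setequal(
    c(hg_genes, intg_genes, attr(ctl, "removed")),
    rownames(sim$dataset$values)
  )
})

test_that("tissue restriction uses only the requested tissues", {
  sim <- simulate_dataset(noiseless_config(seed = 23))
  ctl <- truth_catalog(sim$truth)
  one_tissue <- group_age_series(
    sim$dataset, ctl, "HG",
    tissues = sim$dataset$samples$tissue[1]
  )
  truth_hg <- sim$truth$group_means[sim$truth$group_means$group == "HG", ]
  expect_equal(one_tissue$mean, truth_hg$mean, tolerance = 1e-9)
  expect_error(
    group_age_series(sim$dataset, ctl, "HG", tissues = "nonexistent"),
    "no sample left"
  )
})

test_that("coverage matches a brute-force scan over sorted prefixes", {
  ages <- c(1, 2, 3)
  meta <- data.frame(
    sample = sprintf("s%d", 1:3), tissue = "t",
    age_months = ages, sex = "M"
  )
  vals <- matrix(
    c(50, 30, 15, 5) / 3, 4, 3,
    dimnames = list(c("A", "B", "C", "D"), meta$sample)
  )
  ds <- expression_dataset(vals, meta)
  ctl <- partition_genes(c("A", "B", "C", "D"), c("A", "C"))

  cov <- production_coverage(ds, ctl, fraction = 0.8)
  expect_identical(cov$n_genes_covering, 2L)
  expect_equal(cov$share_of_genome, 0.5)
  expect_identical(cov$n_hg_among_them, 1L) # A is HG, B is not

  # independent brute force: smallest prefix of the sorted totals
  totals <- sort(rowSums(vals), decreasing = TRUE)
  brute <- min(which(cumsum(totals) / sum(totals) >= 0.8))
  expect_identical(cov$n_genes_covering, as.integer(brute))

  # fraction -> 1 limit: all genes with nonzero production
  vals2 <- vals
  vals2["D", ] <- 0
  ds2 <- expression_dataset(vals2, meta)
  cov2 <- production_coverage(ds2, ctl, fraction = 1 - 1e-12)
  expect_identical(cov2$n_genes_covering, 3L)

  expect_error(production_coverage(ds, ctl, fraction = 0), "strictly between")
  expect_error(production_coverage(ds, ctl, fraction = 1), "strictly between")
  vals3 <- vals
  vals3[, ] <- 0
  expect_error(
    production_coverage(expression_dataset(vals3, meta), ctl),
    "all-zero"
  )
})

test_that("coverage prefix size is monotone in the requested fraction", {
  sim <- simulate_dataset(small_config(seed = 24))
  ctl <- truth_catalog(sim$truth)
  fractions <- c(0.2, 0.4, 0.6, 0.8, 0.95)
  sizes <- vapply(
    fractions,
    function(f) production_coverage(sim$dataset, ctl, f)$n_genes_covering,
    integer(1)
  )
  expect_true(all(diff(sizes) >= 0))
})

test_that("coverage ties break by production then gene name, deterministically", {
  meta <- data.frame(sample = "s1", tissue = "t", age_months = 1, sex = "M")
  vals <- matrix(c(4, 4, 2), 3, 1, dimnames = list(c("zz", "aa", "mm"), "s1"))
  ds <- expression_dataset(vals, meta)
  # 0.4 of total (10) needs one gene; the tie at 4 resolves to "aa"
  cov <- production_coverage(ds, NULL, fraction = 0.4)
  expect_identical(cov$n_genes_covering, 1L)
  expect_true(is.na(cov$n_hg_among_them))
})
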
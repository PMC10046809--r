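test_that("generation is deterministic under a fixed config and leaves the RNG alone", {
  cfg <- small_config(seed = 51)
  a <- simulate_dataset(cfg)
  set.seed(999)
  before <- stats::runif(1)
  b <- simulate_dataset(cfg)
  set.seed(999)
  expect_identical(stats::runif(1), before) # caller RNG untouched
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(
    as.data.frame(a$dataset$samples), as.data.frame(b$dataset$samples)
  )
  expect_identical(a$truth$genes, b$truth$genes)
})

test_that("the noiseless limit reproduces configured group means and slopes exactly", {
  cfg <- noiseless_config(seed = 52)
  sim <- simulate_dataset(cfg)
  ctl <- truth_catalog(sim$truth)
  for (g in c("HG", "IntG")) {
    series <- group_age_series(sim$dataset, ctl, g)
    truth <- sim$truth$group_means[sim$truth$group_means$group == g, ]
    expect_equal(series$mean, truth$mean, tolerance = 1e-9)
    fits <- segment_fits(series, cfg$breakpoint)
    slope <- if (g == "HG") cfg$hg_slope else cfg$intg_slope
    factor <- cfg$late_slope_factor[[g]]
    expect_equal(fits$early$slope, slope, tolerance = 1e-9)
    expect_equal(fits$late$slope, slope * factor, tolerance = 1e-9)
  }
})

test_that("study-shaped defaults: grid, tissues, replicate structure, sex mix", {
  cfg <- sim_config(n_genes = 20, seed = 53)
  expect_identical(cfg$ages, c(1, 3, 6, 9, 12, 15, 18, 21, 24, 27))
  expect_identical(cfg$n_tissues, 17L)
  sim <- simulate_dataset(cfg)
  smp <- sim$dataset$samples
  expect_identical(dplyr::n_distinct(smp$tissue), 17L)
  per_cell <- dplyr::count(smp, tissue, age_months)
  expect_true(all(per_cell$n %in% c(5L, 6L)))
  sex_mix <- smp |>
    dplyr::count(tissue, age_months, sex) |>
    tidyr::pivot_wider(names_from = "sex", values_from = "n")
  expect_true(all(sex_mix$M == 3L))
  expect_true(all(sex_mix$F %in% c(2L, 3L)))
})

test_that("a trend driving the expected mean non-positive is rejected", {
  expect_error(
    expected_group_means(
      sim_config(hg_level = 20, hg_slope = -3, seed = 1)
    ),
    "trend underflow"
  )
  expect_error(
    simulate_dataset(sim_config(intg_level = 5, intg_slope = -1, seed = 1)),
    "trend underflow"
  )
})

test_that("replicate noise is calibrated: empirical CV tracks the configured CV", {
  cfg <- small_config(
    n_genes = 1200, n_tissues = 2, replicates = 6,
    replicate_cv = 0.3, high_var_fraction = 0, seed = 54
  )
  sim <- simulate_dataset(cfg)
  keys <- paste(
    sim$dataset$samples$tissue, sim$dataset$samples$age_months,
    sep = "@"
  )
  one_cell <- sim$dataset$values[, keys == keys[1], drop = FALSE]
  cvs <- apply(one_cell, 1, sd) / rowMeans(one_cell)
  # mean sample CV across 1200 genes within 10% relative error of target
  expect_lt(abs(mean(cvs) - 0.3) / 0.3, 0.10)
})

test_that("the CV filter removes the high-variance subset far more often than the rest", {
  removed_rate <- function(seed) {
    cfg <- small_config(
      n_genes = 400, n_tissues = 3, replicates = 6,
      replicate_cv = 0.3, high_var_fraction = 0.25, high_var_cv = 1.5,
      seed = seed
    )
    sim <- simulate_dataset(cfg)
    ds <- cv_filter(sim$dataset, threshold = 1)
    high <- sim$truth$genes$high_var
    c(
      high = mean(!ds$mask[high, ]),
      low = mean(!ds$mask[!high, ])
    )
  }
  rates <- vapply(55:57, removed_rate, numeric(2))
  # the sample CV of 6 log-normal replicates is biased well below the
  # population CV, so a pop-CV-1.5 gene loses a cell roughly 40% of the
  # time; the contrast with calibrated genes is what the filter delivers
  expect_gt(mean(rates["high", ]), 0.25)
  expect_lt(mean(rates["low", ]), 0.01)
})

test_that("calibration harness validates its preconditions", {
  cfg <- small_config(seed = 58)
  expect_error(calibration_run(cfg, n_reps = 10), "n_reps >= 100")
  expect_error(
    calibration_run(noiseless_config(), n_reps = 100),
    "degenerate config"
  )
})

test_that("alpha = 1 rejects everything and a huge slope gap gives full power", {
  cfg <- small_config(
    n_genes = 80, n_tissues = 2, hg_fraction = 0.5,
    hg_level = 400, intg_level = 400,
    hg_slope = -12, intg_slope = -0.05, late_slope_factor = 1,
    replicate_cv = 0.2, tissue_effect_sd = 0, seed = 59
  )
  out <- calibration_run(cfg, n_reps = 100, alpha = 1)
  expect_identical(out$mode, "power")
  expect_equal(out$rate, 1)
  strong <- calibration_run(cfg, n_reps = 100, alpha = 0.05)
  expect_gt(strong$rate, 0.95)
})

test_that("written simulations carry matrix, metadata, housekeeping list and truth", {
  sim <- simulate_dataset(small_config(n_genes = 30, n_tissues = 2, seed = 60))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_setequal(
    list.files(dir),
    c("matrix.tsv", "metadata.tsv", "hk_list.tsv", "truth.json", "config.yaml")
  )
  hk <- readr::read_tsv(file.path(dir, "hk_list.tsv"), show_col_types = FALSE)
  expect_identical(
    sort(hk$gene),
    sort(sim$truth$genes$gene[sim$truth$genes$group == "HG"])
  )
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$genes$baseline, sim$truth$genes$baseline, tolerance = 1e-12)
})
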
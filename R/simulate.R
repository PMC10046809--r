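study_tissues <- c(
  "Brain", "BAT", "Bone", "GAT", "Heart", "Kidney", "Lung", "Marrow", "MAT",
  "Pancreas", "SCAT", "Skin", "Small_Intestine", "Spleen", "WBC",
  "Limb_Muscle", "Liver"
)

#' Configuration of the synthetic expression-matrix generator
#'
#' Defaults emulate the structure of the mouse multi-tissue aging series the
#' pipeline was built for: 17 tissues, the 10-age grid 1--27 months, 5 or 6
#' replicate animals per tissue-age cell (3M+3F or 3M+2F), two gene
#' compartments whose mean production follows piecewise-linear age trends
#' with a 9-month breakpoint at the published group magnitudes (HG starting
#' near 496 units falling 3.04 units/month early; IntG near 135 falling 0.92
#' units/month early; late slopes attenuated to the published late/early
#' ratios), log-normal between-gene baselines, multiplicative log-normal
#' tissue effects and replicate noise, and a configurable fraction of
#' high-variance genes the CV filter should catch.
#'
#' @param n_genes Number of genes (default 2000; the study's full 35,630
#'   scale is configurable, not the default).
#' @param hg_fraction Proportion of genes labelled HG (default 0.143, the
#'   study's 5101/35630).
#' @param n_tissues Number of tissues (default 17).
#' @param ages Age grid in months.
#' @param replicates Allowed replicate counts per tissue-age cell; a cell
#'   draws uniformly among them (default `c(5, 6)`).
#' @param hg_level,intg_level Group mean production at the first age
#'   (expression units).
#' @param hg_slope,intg_slope Early-interval slope, units per month
#'   (negative = decline).
#' @param breakpoint Age (months) at which the trend slope changes.
#' @param late_slope_factor Multiplier applied to each group's slope after
#'   the breakpoint; scalar or named vector `c(HG = , IntG = )`.
#' @param baseline_sdlog Log-sd of the between-gene baseline spread.
#' @param tissue_effect_sd Log-sd of the multiplicative tissue effect.
#' @param replicate_cv Target coefficient of variation across replicate
#'   animals (population CV of the log-normal noise); 0 switches noise off.
#' @param high_var_fraction Proportion of genes given `high_var_cv` instead
#'   of `replicate_cv`.
#' @param high_var_cv Replicate CV of the high-variance subset (>= 1 so the
#'   CV filter targets it).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       hg_fraction = 5101 / 35630,
                       n_tissues = 17,
                       ages = c(1, 3, 6, 9, 12, 15, 18, 21, 24, 27),
                       replicates = c(5, 6),
                       hg_level = 496,
                       intg_level = 135,
                       hg_slope = -3.0446,
                       intg_slope = -0.9222,
                       breakpoint = 9,
                       late_slope_factor = c(HG = 0.429, IntG = 0.255),
                       baseline_sdlog = 1,
                       tissue_effect_sd = 0.5,
                       replicate_cv = 0.3,
                       high_var_fraction = 0.1,
                       high_var_cv = 1.5,
                       seed = 1) {
  if (n_genes < 2) abort("n_genes must be >= 2")
  if (hg_fraction < 0 || hg_fraction > 1) abort("hg_fraction must lie in [0, 1]")
  if (high_var_fraction < 0 || high_var_fraction > 1) {
    abort("high_var_fraction must lie in [0, 1]")
  }
  if (is.unsorted(ages, strictly = TRUE)) abort("ages must be strictly increasing")
  if (any(ages <= 0)) abort("ages must be positive")
  if (replicate_cv < 0) abort("replicate_cv must be >= 0")
  if (length(late_slope_factor) == 1) {
    late_slope_factor <- c(HG = unname(late_slope_factor),
                           IntG = unname(late_slope_factor))
  }
  structure(
    list(
      n_genes = as.integer(n_genes), hg_fraction = hg_fraction,
      n_tissues = as.integer(n_tissues), ages = ages,
      replicates = as.integer(replicates),
      hg_level = hg_level, intg_level = intg_level,
      hg_slope = hg_slope, intg_slope = intg_slope,
      breakpoint = breakpoint, late_slope_factor = late_slope_factor,
      baseline_sdlog = baseline_sdlog, tissue_effect_sd = tissue_effect_sd,
      replicate_cv = replicate_cv, high_var_fraction = high_var_fraction,
      high_var_cv = high_var_cv, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Expected group mean path of a simulation config
#'
#' Piecewise-linear mean production per age implied by the config: the group
#' level at the first age, the early slope up to the breakpoint, and the
#' attenuated slope after it.
#'
#' @param config A `sim_config`.
#' @return A tibble: `group`, `age`, `mean`.
#' @export
expected_group_means <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  path <- function(level, slope, factor) {
    a <- config$ages
    a1 <- a[1]
    bp <- config$breakpoint
    level + slope * (pmin(a, bp) - a1) + slope * factor * (pmax(a, bp) - bp)
  }
  out <- dplyr::bind_rows(
    tibble::tibble(
      group = "HG", age = config$ages,
      mean = path(config$hg_level, config$hg_slope,
                  config$late_slope_factor[["HG"]])
    ),
    tibble::tibble(
      group = "IntG", age = config$ages,
      mean = path(config$intg_level, config$intg_slope,
                  config$late_slope_factor[["IntG"]])
    )
  )
  if (any(out$mean <= 0)) {
    abort("trend underflow: configured trend drives an expected mean <= 0")
  }
  out
}

lnorm_params <- function(cv) {
  # meanlog/sdlog of a unit-mean log-normal with the given population CV
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic age-resolved expression dataset
#'
#' Each value is baseline_g x tissue_factor_t x trend_g(age) x noise:
#' per-gene log-normal baselines normalized to mean 1 within each group,
#' log-normal tissue factors normalized to mean 1, the group's
#' piecewise-linear mean path (see [expected_group_means()]), and unit-mean
#' log-normal replicate noise whose population CV is the gene's configured
#' replicate CV. In the noiseless limit (`replicate_cv = 0`,
#' `tissue_effect_sd = 0`) every replicate equals its expected value and the
#' aggregation pipeline recovers the configured group means exactly.
#' Generation is deterministic under a fixed config (the caller's RNG state
#' is untouched).
#'
#' @param config A [sim_config()].
#' @return A list with `dataset` (an [expression_dataset()]), `truth` (list:
#'   `genes` tibble with per-gene group/baseline/replicate CV, `group_means`
#'   tibble, `tissue_factors`, `config`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  paths <- expected_group_means(config)

  withr::with_seed(config$seed, {
    n <- config$n_genes
    n_hg <- round(n * config$hg_fraction)
    genes <- sprintf("g%05d", seq_len(n))
    group <- rep(c("HG", "IntG"), c(n_hg, n - n_hg))

    baseline <- stats::rlnorm(n, 0, config$baseline_sdlog)
    for (g in unique(group)) {
      sel <- group == g
      baseline[sel] <- baseline[sel] / mean(baseline[sel])
    }

    gene_cv <- rep(config$replicate_cv, n)
    n_high <- round(config$high_var_fraction * n)
    high_var <- rep(FALSE, n)
    if (n_high > 0) {
      high_var[sample.int(n, n_high)] <- TRUE
      gene_cv[high_var] <- config$high_var_cv
    }

    tissues <- if (config$n_tissues <= length(study_tissues)) {
      study_tissues[seq_len(config$n_tissues)]
    } else {
      sprintf("T%02d", seq_len(config$n_tissues))
    }
    tissue_factor <- stats::rlnorm(length(tissues), 0, config$tissue_effect_sd)
    tissue_factor <- tissue_factor / mean(tissue_factor)

    mean_path <- matrix(NA_real_, n, length(config$ages))
    for (g in unique(group)) {
      pg <- paths$mean[paths$group == g]
      mean_path[group == g, ] <- matrix(pg, sum(group == g), length(pg),
        byrow = TRUE
      )
    }

    noise_par <- lnorm_params(gene_cv)
    cols <- list()
    meta <- list()
    k <- 0
    for (ti in seq_along(tissues)) {
      for (ai in seq_along(config$ages)) {
        n_rep <- if (length(config$replicates) == 1) {
          config$replicates
        } else {
          sample(config$replicates, 1)
        }
        expected <- baseline * tissue_factor[ti] * mean_path[, ai]
        noise <- if (all(gene_cv == 0)) {
          matrix(1, n, n_rep)
        } else {
          matrix(
            stats::rlnorm(n * n_rep, noise_par$meanlog, noise_par$sdlog),
            n, n_rep
          )
        }
        block <- expected * noise
        sex <- c(rep("M", 3), rep("F", n_rep - 3))
        if (n_rep < 3) sex <- rep(c("M", "F"), length.out = n_rep)
        ids <- sprintf("%s_m%02d_r%d", tissues[ti], config$ages[ai], seq_len(n_rep))
        k <- k + 1
        colnames(block) <- ids
        cols[[k]] <- block
        meta[[k]] <- tibble::tibble(
          sample = ids, tissue = tissues[ti],
          age_months = config$ages[ai], sex = sex
        )
      }
    }
    values <- do.call(cbind, cols)
    rownames(values) <- genes
    samples <- dplyr::bind_rows(meta)

    dataset <- expression_dataset(values, samples)
    truth <- list(
      genes = tibble::tibble(
        gene = genes, group = group, baseline = baseline,
        replicate_cv = gene_cv, high_var = high_var
      ),
      group_means = paths,
      tissue_factors = setNames(tissue_factor, tissues),
      config = config
    )
    list(dataset = dataset, truth = truth)
  })
}

#' Catalogue of a simulated dataset from its truth record
#'
#' @param truth The `truth` element of [simulate_dataset()].
#' @return A `gene_catalog` built from the generator's group labels.
#' @export
truth_catalog <- function(truth) {
  partition_genes(truth$genes$gene, truth$genes$gene[truth$genes$group == "HG"])
}

#' Write a simulated dataset to a directory
#'
#' Emits the generator's output in the pipeline's on-disk formats:
#' `matrix.tsv`, `metadata.tsv`, `hk_list.tsv` (the simulated HG labels),
#' `truth.json` and `config.yaml`.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(
    sim$dataset,
    file.path(dir, "matrix.tsv"), file.path(dir, "metadata.tsv")
  )
  readr::write_tsv(
    tibble::tibble(gene = sim$truth$genes$gene[sim$truth$genes$group == "HG"]),
    file.path(dir, "hk_list.tsv")
  )
  jsonlite::write_json(
    list(
      genes = sim$truth$genes,
      group_means = sim$truth$group_means,
      tissue_factors = as.list(sim$truth$tissue_factors)
    ),
    file.path(dir, "truth.json"),
    dataframe = "columns", digits = NA
  )
  yaml::write_yaml(
    unclass(sim$truth$config)[
      setdiff(names(sim$truth$config), character(0))
    ],
    file.path(dir, "config.yaml")
  )
  invisible(dir)
}

#' Monte-Carlo calibration of the slope-equality test
#'
#' Repeatedly simulates a dataset, runs the aggregation pipeline (optional
#' CV filter, per-age HG and IntG series), fits both group trends and
#' applies [compare_slopes()]. With equal configured slopes the rejection
#' fraction at level `alpha` estimates the type-I error rate; with unequal
#' slopes it estimates power. A 95% Clopper-Pearson binomial interval is
#' attached.
#'
#' @param config A [sim_config()]; rep r uses seed `config$seed + r`.
#' @param n_reps Number of simulations (>= 100 for a stable rate estimate).
#' @param alpha Nominal level (default 0.05).
#' @param filter Apply [cv_filter()] before aggregation? Default `TRUE`.
#' @param cv_threshold Threshold passed to [cv_filter()].
#' @return A one-row tibble: `mode` (`"type_i"` or `"power"`), `rate`,
#'   `n_reps`, `ci_low`, `ci_high`, `alpha`.
#' @export
calibration_run <- function(config, n_reps, alpha = 0.05,
                            filter = TRUE, cv_threshold = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (n_reps < 100) abort("calibration needs n_reps >= 100")
  if (config$replicate_cv == 0 && config$tissue_effect_sd == 0) {
    abort("degenerate config: rejection rates are undefined without noise")
  }
  equal <- isTRUE(all.equal(config$hg_slope, config$intg_slope)) &&
    isTRUE(all.equal(
      config$late_slope_factor[["HG"]], config$late_slope_factor[["IntG"]]
    ))
  reject <- vapply(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_dataset(cfg)
    ds <- sim$dataset
    if (filter) ds <- cv_filter(ds, threshold = cv_threshold)
    catalog <- truth_catalog(sim$truth)
    hg <- group_age_series(ds, catalog, "HG")
    intg <- group_age_series(ds, catalog, "IntG")
    cmp <- compare_slopes(fit_trend(hg), fit_trend(intg))
    cmp$p < alpha
  }, logical(1))
  ci <- stats::binom.test(sum(reject), n_reps)$conf.int
  tibble::tibble(
    mode = if (equal) "type_i" else "power",
    rate = mean(reject), n_reps = n_reps,
    ci_low = ci[1], ci_high = ci[2], alpha = alpha
  )
}
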
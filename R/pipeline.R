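#' Run the end-to-end analysis pipeline
#'
#' Executes the full analysis: input (files or simulation) -> HG/IntG
#' partition -> CV filter -> per-age group series -> overall and segmented
#' trends with the slope-equality F test -> HG/IntG ratio, interval slopes
#' and stage summary -> gene-block reports -> production coverage. With
#' `out_dir` set, a machine-readable report bundle is written (TSV tables,
#' JSON reports, a JSON index and a plain-text run log recording the seed
#' and a config hash); a rerun with the same config is byte-identical.
#'
#' @param config A named list or the path of a YAML file. Recognized fields:
#'   `input` (list with `matrix`, `metadata`, `hk_list` paths) or
#'   `simulation` (arguments for [sim_config()]); `cv_threshold` (default 1;
#'   `NULL`/`false` disables the filter), `breakpoint` (default 9),
#'   `coverage_fraction` (default 0.8), `ratio_intervals` (list of
#'   two-element month vectors; default the early interval and the 9--18
#'   month window), `blocks` (named list: each a file path or a character
#'   vector of symbols), `case_insensitive`, `expand_variants`.
#' @param out_dir Optional report directory.
#' @return A `pipeline_report` list: `catalog`, `hg`, `intg`, `fits`
#'   (overall `trend_fit`s and `comparison`), `segmented`, `ratio`,
#'   `ratio_interval_fits`, `stages`, `blocks`, `coverage`,
#'   `filter_report`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cv_threshold <- config$cv_threshold %||% 1
  breakpoint <- config$breakpoint %||% 9
  coverage_fraction <- config$coverage_fraction %||% 0.8
  ratio_intervals <- config$ratio_intervals %||% list(c(1, 9), c(9, 18))

  # --- input stage -----------------------------------------------------
  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_dataset(cfg)
    dataset <- sim$dataset
    catalog <- truth_catalog(sim$truth)
    seed <- cfg$seed
  } else if (!is.null(config$input)) {
    inp <- config$input
    if (is.null(inp$matrix) || is.null(inp$metadata)) {
      abort("input stage: config$input needs matrix and metadata paths")
    }
    dataset <- read_expression(inp$matrix, inp$metadata)
    if (is.null(inp$hk_list)) abort("input stage: config$input needs hk_list")
    hk <- suppressWarnings(read_gene_list(inp$hk_list))
    catalog <- partition_genes(
      rownames(dataset$values), hk,
      case_insensitive = isTRUE(config$case_insensitive),
      expand_variants = isTRUE(config$expand_variants)
    )
    seed <- config$seed %||% NA_integer_
  } else {
    abort("no input source: config needs an 'input' or 'simulation' block")
  }

  # --- filter + aggregation -------------------------------------------
  if (!is.null(cv_threshold) && !isFALSE(cv_threshold)) {
    dataset <- cv_filter(dataset, threshold = cv_threshold)
  }
  hg <- group_age_series(dataset, catalog, "HG")
  intg <- group_age_series(dataset, catalog, "IntG")

  # --- trends ----------------------------------------------------------
  fit_hg <- fit_trend(hg)
  fit_intg <- fit_trend(intg)
  comparison <- compare_slopes(fit_hg, fit_intg)
  segmented <- segmented_trends(hg, intg, breakpoint = breakpoint)

  # --- ratio -----------------------------------------------------------
  ratio <- ratio_series(hg, intg)
  ratio_fits <- purrr::map(ratio_intervals, function(iv) {
    interval_ratio_slope(ratio, iv[1], iv[2])
  })
  names(ratio_fits) <- purrr::map_chr(
    ratio_intervals, ~ sprintf("%g-%g", .x[1], .x[2])
  )
  stages <- stage_summary(ratio)

  # --- blocks ----------------------------------------------------------
  blocks <- purrr::imap(config$blocks %||% list(), function(def, nm) {
    blk <- if (is.character(def) && length(def) == 1 && file.exists(def)) {
      read_gene_block(def, catalog, name = nm,
        case_insensitive = isTRUE(config$case_insensitive))
    } else {
      gene_block(def, catalog, name = nm,
        case_insensitive = isTRUE(config$case_insensitive))
    }
    block_report(dataset, blk, breakpoint = breakpoint)
  })

  coverage <- production_coverage(dataset, catalog, fraction = coverage_fraction)

  report <- structure(
    list(
      catalog = catalog, hg = hg, intg = intg,
      fits = list(hg = fit_hg, intg = fit_intg, comparison = comparison),
      segmented = segmented,
      ratio = ratio, ratio_interval_fits = ratio_fits, stages = stages,
      blocks = blocks, coverage = coverage,
      filter_report = dataset$filter_report,
      config = config, seed = seed
    ),
    class = "pipeline_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(glance(x$catalog))
  cat(sprintf(
    "overall slopes: HG %.4f, IntG %.4f; F = %.3f on (1, %d) df, p = %.4g\n",
    x$fits$hg$slope, x$fits$intg$slope,
    x$fits$comparison$f, x$fits$comparison$df2, x$fits$comparison$p
  ))
  print(x$segmented)
  invisible(x)
}

#' Flat tibble of every fitted trend in a pipeline report
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @return A tibble with one row per (group, interval) fit:
#'   `group`, `interval`, `n`, `slope`, `slope_se`, `t`, `p`, `r`, `r_p`.
#' @export
tidy.pipeline_report <- function(x, ...) {
  labels <- attr(x$segmented, "labels")
  one <- function(fit, group, interval) {
    tibble::tibble(
      group = group, interval = interval, n = fit$n,
      slope = fit$slope, slope_se = fit$slope_se, t = fit$t, p = fit$p,
      r = fit$r, r_p = fit$r_p
    )
  }
  overall <- sprintf("%g-%g", min(x$hg$age), max(x$hg$age))
  dplyr::bind_rows(
    one(x$fits$hg, "HG", overall),
    one(x$fits$intg, "IntG", overall),
    one(x$segmented$early$fit_a, "HG", labels[["early"]]),
    one(x$segmented$early$fit_b, "IntG", labels[["early"]]),
    one(x$segmented$late$fit_a, "HG", labels[["late"]]),
    one(x$segmented$late$fit_b, "IntG", labels[["late"]])
  )
}

#' Write a pipeline report bundle
#'
#' @param report A `pipeline_report`.
#' @param out_dir Directory to create/fill.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)

  write_catalog(report$catalog, p("catalog.tsv"))
  jsonlite::write_json(catalog_report(report$catalog), p("catalog_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_age_series(report$hg, p("hg_series.tsv"))
  write_age_series(report$intg, p("intg_series.tsv"))
  readr::write_tsv(tidy(report), p("trend_fits.tsv"))

  comparisons <- dplyr::bind_rows(
    dplyr::mutate(glance(report$fits$comparison), interval = "overall"),
    dplyr::mutate(
      glance(report$segmented$early$comparison),
      interval = attr(report$segmented, "labels")[["early"]]
    ),
    dplyr::mutate(
      glance(report$segmented$late$comparison),
      interval = attr(report$segmented, "labels")[["late"]]
    )
  )
  readr::write_tsv(comparisons, p("slope_comparisons.tsv"))

  readr::write_tsv(tibble::as_tibble(report$ratio), p("ratio_series.tsv"))
  ratio_tbl <- purrr::imap_dfr(report$ratio_interval_fits, function(fit, nm) {
    dplyr::mutate(glance(fit), interval = nm)
  })
  readr::write_tsv(ratio_tbl, p("ratio_interval_fits.tsv"))
  readr::write_tsv(report$stages, p("stage_summary.tsv"))
  readr::write_tsv(report$coverage, p("coverage.tsv"))
  if (!is.null(report$filter_report)) {
    readr::write_tsv(report$filter_report, p("cv_filter_report.tsv"))
  }

  if (length(report$blocks) > 0) {
    jsonlite::write_json(report$blocks, p("blocks.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns"
    )
  }

  index <- list(
    tool = "ontotrend",
    version = as.character(utils::packageVersion("ontotrend")),
    seed = report$seed,
    config_hash = rlang::hash(report$config),
    files = list.files(out_dir)
  )
  jsonlite::write_json(index, p("report_index.json"), auto_unbox = TRUE)
  writeLines(
    c(
      "ontotrend run log",
      sprintf("version: %s", index$version),
      sprintf("seed: %s", index$seed),
      sprintf("config_hash: %s", index$config_hash),
      sprintf("n_genes: %d", attr(report$catalog, "counts")[["total"]]),
      sprintf("outputs: %s", paste(sort(index$files), collapse = ", "))
    ),
    p("run.log")
  )
  invisible(out_dir)
}
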
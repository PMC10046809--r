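new_age_series <- function(tbl) {
  structure(tbl, class = c("age_series", class(tbl)))
}

#' @export
print.age_series <- function(x, ...) {
  cat(sprintf("<age_series> %d age point(s)\n", nrow(x)))
  NextMethod()
}

resolve_gene_set <- function(dataset, catalog, group) {
  if (inherits(group, "gene_block")) {
    genes <- group$gene
  } else if (is.character(group) && length(group) == 1 &&
    group %in% c("HG", "IntG")) {
    if (is.null(catalog)) abort("a gene_catalog is required to select by group label")
    genes <- catalog_group(catalog, group)
  } else {
    genes <- gene_column(group)
  }
  genes <- intersect(genes, rownames(dataset$values))
  if (length(genes) == 0) abort("no member of the requested gene set is in the dataset")
  genes
}

#' Per-age aggregated production of a gene set
#'
#' The central aggregation: for each age, every gene's production is the mean
#' of its values over all valid (tissue, replicate) samples at that age —
#' pooling tissues and sexes — and the series mean is the mean of those
#' per-gene means over the set's genes. The 95% confidence interval is
#' mean +/- 1.96 x sd / sqrt(n_genes), with the sd taken across the per-gene
#' means (sample sd). Cells invalidated by [cv_filter()] are excluded
#' (complete-case within age); a gene with no valid sample at an age drops
#' out of that age's mean and `n_genes`.
#'
#' @param dataset An `expression_dataset`.
#' @param catalog A `gene_catalog` (may be `NULL` when `group` is a
#'   `gene_block` or an explicit gene vector).
#' @param group `"HG"`, `"IntG"`, a `gene_block`, or a character vector of
#'   gene names.
#' @param tissues Optional character vector restricting to a tissue subset.
#' @param pool `"gene_means"` (default, as described above) or `"samples"`:
#'   pool all valid gene-by-sample values of the age directly, with the CI
#'   computed across those values.
#' @return An `age_series` tibble: `age`, `mean`, `ci_low`, `ci_high`,
#'   `n_genes`.
#' @export
group_age_series <- function(dataset, catalog, group, tissues = NULL,
                             pool = c("gene_means", "samples")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  pool <- match.arg(pool)
  genes <- resolve_gene_set(dataset, catalog, group)

  samples <- dataset$samples
  keep <- rep(TRUE, nrow(samples))
  if (!is.null(tissues)) keep <- samples$tissue %in% tissues
  if (!any(keep)) abort("no sample left after tissue restriction")

  keys <- sample_cell_keys(dataset)
  cell_idx <- match(keys, dataset$cells$cell)
  gi <- match(genes, rownames(dataset$values))
  ages <- sort(unique(samples$age_months[keep]))

  rows <- purrr::map(ages, function(a) {
    cols <- which(keep & samples$age_months == a)
    vals <- dataset$values[gi, cols, drop = FALSE]
    valid <- dataset$mask[gi, cell_idx[cols], drop = FALSE] & !is.na(vals)
    vals[!valid] <- NA_real_
    if (pool == "gene_means") {
      n_obs <- rowSums(valid)
      gene_means <- rowSums(vals, na.rm = TRUE) / n_obs
      gene_means <- gene_means[n_obs > 0]
      n <- length(gene_means)
      if (n == 0) {
        abort(sprintf("no valid cell at age %s for the requested gene set", a))
      }
      m <- mean(gene_means)
      half <- if (n >= 2) 1.96 * sd(gene_means) / sqrt(n) else 0
      if (!is.finite(half)) half <- 0
    } else {
      pooled <- vals[valid]
      if (length(pooled) == 0) {
        abort(sprintf("no valid cell at age %s for the requested gene set", a))
      }
      n <- sum(rowSums(valid) > 0)
      m <- mean(pooled)
      half <- if (length(pooled) >= 2) 1.96 * sd(pooled) / sqrt(length(pooled)) else 0
      if (!is.finite(half)) half <- 0
    }
    tibble::tibble(
      age = a, mean = m, ci_low = m - half, ci_high = m + half, n_genes = n
    )
  })
  new_age_series(dplyr::bind_rows(rows))
}

#' Cumulative production coverage of the most productive genes
#'
#' Sorts genes by total production (summed over all samples) in descending
#' order — ties broken by gene name — and finds the smallest prefix whose
#' cumulative share of total production reaches `fraction`. Reports the
#' prefix size, its share of the gene count, and how many of its genes carry
#' the HG label.
#'
#' @param dataset An `expression_dataset`.
#' @param catalog A `gene_catalog` (or `NULL`: HG count reported as `NA`).
#' @param fraction Target cumulative production share, strictly between
#'   0 and 1 (default 0.8).
#' @return A one-row tibble: `fraction`, `n_genes_covering`,
#'   `share_of_genome`, `n_hg_among_them`, `total_genes`.
#' @export
production_coverage <- function(dataset, catalog = NULL, fraction = 0.8) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort("fraction must lie strictly between 0 and 1")
  }
  totals <- rowSums(dataset$values, na.rm = TRUE)
  grand <- sum(totals)
  if (grand == 0) abort("all-zero expression matrix")
  ord <- order(-totals, rownames(dataset$values))
  cum <- cumsum(totals[ord]) / grand
  n_cover <- unname(which(cum >= fraction)[1])
  top <- rownames(dataset$values)[ord[seq_len(n_cover)]]
  n_hg <- if (is.null(catalog)) {
    NA_integer_
  } else {
    sum(top %in% catalog_group(catalog, "HG"))
  }
  tibble::tibble(
    fraction = fraction,
    n_genes_covering = n_cover,
    share_of_genome = n_cover / nrow(dataset$values),
    n_hg_among_them = n_hg,
    total_genes = nrow(dataset$values)
  )
}

#' Write an age series as TSV
#'
#' @param series An `age_series`.
#' @param path Output path (columns `age`, `mean`, `ci_low`, `ci_high`,
#'   `n_genes`).
#' @return `path`, invisibly.
#' @export
write_age_series <- function(series, path) {
  readr::write_tsv(tibble::as_tibble(series), path)
  invisible(path)
}

#' @export
autoplot.age_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Age (months)", y = "Mean RNA production",
      title = "Per-age aggregated production (95% CI)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot HG and IntG series together
#'
#' @param hg,intg `age_series` tibbles for the two groups.
#' @return A ggplot object.
#' @export
plot_group_series <- function(hg, intg) {
  both <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(hg), group = "HG"),
    dplyr::mutate(tibble::as_tibble(intg), group = "IntG")
  )
  ggplot2::ggplot(both, ggplot2::aes(
    x = .data$age, y = .data$mean,
    colour = .data$group, fill = .data$group
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      alpha = 0.25, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Age (months)", y = "Mean RNA production") +
    ggplot2::theme_minimal()
}
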
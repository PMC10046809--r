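#' Construct an expression dataset from a matrix and sample metadata
#'
#' The core container of the package: a genes-by-samples matrix of
#' non-negative normalized expression values joined to per-sample metadata
#' (tissue, age in months, sex), plus a per-(gene, tissue, age) validity mask
#' that the coefficient-of-variation filter updates.
#'
#' @param values Numeric matrix, rows = genes (rownames required),
#'   columns = samples (colnames required). Missing values must be `NA`,
#'   never zero placeholders; negative values are rejected.
#' @param samples Data frame with columns `sample`, `tissue`, `age_months`,
#'   `sex`; `sample` must exactly cover the matrix columns.
#' @return An `expression_dataset`: a list with elements `values`, `samples`
#'   (tibble, ordered as the matrix columns), `cells` (tibble of distinct
#'   tissue-by-age cells with a `cell` key), `mask` (logical genes-by-cells
#'   matrix, `TRUE` = valid, initialized all-valid) and `filter_report`
#'   (`NULL` until [cv_filter()] runs).
#' @export
expression_dataset <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("values must have gene rownames and sample colnames")
  }
  if (any(values < 0, na.rm = TRUE)) abort("expression values must be non-negative")
  samples <- tibble::as_tibble(samples)
  required <- c("sample", "tissue", "age_months", "sex")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(sprintf("metadata lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample)) {
    abort(sprintf(
      "duplicated sample id in metadata: %s",
      samples$sample[duplicated(samples$sample)][1]
    ))
  }
  bad_age <- which(!is.finite(samples$age_months) | samples$age_months <= 0)
  if (length(bad_age) > 0) {
    abort(sprintf(
      "age_months must be a positive number (metadata row %d, sample '%s')",
      bad_age[1], samples$sample[bad_age[1]]
    ))
  }
  only_meta <- setdiff(samples$sample, colnames(values))
  if (length(only_meta) > 0) {
    abort(sprintf(
      "metadata sample(s) absent from matrix: %s",
      paste(head(only_meta, 5), collapse = ", ")
    ))
  }
  only_mat <- setdiff(colnames(values), samples$sample)
  if (length(only_mat) > 0) {
    abort(sprintf(
      "matrix column(s) absent from metadata: %s",
      paste(head(only_mat, 5), collapse = ", ")
    ))
  }
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]

  cells <- samples |>
    dplyr::distinct(.data$tissue, age_months = .data$age_months) |>
    dplyr::arrange(.data$tissue, .data$age_months) |>
    dplyr::mutate(cell = paste(.data$tissue, .data$age_months, sep = "@")) |>
    dplyr::relocate("cell")
  mask <- matrix(TRUE, nrow(values), nrow(cells),
    dimnames = list(rownames(values), cells$cell)
  )
  structure(
    list(
      values = values, samples = samples, cells = cells,
      mask = mask, filter_report = NULL
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %d genes x %d samples (%d tissues, ages %s)\n",
    nrow(x$values), ncol(x$values),
    dplyr::n_distinct(x$samples$tissue),
    paste(dataset_ages(x), collapse = ",")
  ))
  if (!is.null(x$filter_report)) {
    cat(sprintf(
      "  CV filter applied (threshold %.3g): %d of %d cells invalid\n",
      attr(x$filter_report, "threshold"),
      sum(!x$mask), length(x$mask)
    ))
  }
  invisible(x)
}

dataset_ages <- function(dataset) sort(unique(dataset$samples$age_months))

sample_cell_keys <- function(dataset) {
  paste(dataset$samples$tissue, dataset$samples$age_months, sep = "@")
}

#' Read an expression matrix and sample metadata from disk
#'
#' @param matrix_path TSV/CSV expression matrix: first column gene symbols,
#'   remaining columns one per sample.
#' @param metadata_path TSV/CSV table with columns `sample`, `tissue`,
#'   `age_months`, `sex`.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  read_delim_auto <- function(path) {
    if (grepl("\\.csv$", path, ignore.case = TRUE)) {
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    } else {
      readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    }
  }
  mat_tbl <- read_delim_auto(matrix_path)
  if (ncol(mat_tbl) < 2) abort("expression matrix needs a gene column plus samples")
  genes <- as.character(mat_tbl[[1]])
  if (anyDuplicated(genes)) {
    abort(sprintf(
      "duplicated gene name in matrix: %s", genes[duplicated(genes)][1]
    ))
  }
  values <- as.matrix(mat_tbl[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes

  meta <- read_delim_auto(metadata_path)
  if (!"age_months" %in% names(meta)) {
    abort("metadata lacks column(s): age_months")
  }
  age_num <- suppressWarnings(as.numeric(meta$age_months))
  bad <- which(is.na(age_num) | age_num <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "age_months must be a positive number (metadata row %d, value '%s')",
      bad[1], as.character(meta$age_months[bad[1]])
    ))
  }
  meta$age_months <- age_num
  expression_dataset(values, meta)
}

#' Write an expression dataset to disk
#'
#' Inverse of [read_expression()]; the mask and filter report are not
#' serialized (re-run [cv_filter()] after reloading).
#'
#' @param dataset An `expression_dataset`.
#' @param matrix_path,metadata_path Output TSV/CSV paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(dataset, matrix_path, metadata_path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  write_delim_auto <- function(tbl, path) {
    if (grepl("\\.csv$", path, ignore.case = TRUE)) {
      readr::write_csv(tbl, path, progress = FALSE)
    } else {
      readr::write_tsv(tbl, path, progress = FALSE)
    }
  }
  mat_tbl <- dplyr::bind_cols(
    tibble::tibble(gene = rownames(dataset$values)),
    tibble::as_tibble(dataset$values)
  )
  write_delim_auto(mat_tbl, matrix_path)
  write_delim_auto(dataset$samples, metadata_path)
  invisible(matrix_path)
}

#' Expression values as a long tibble
#'
#' @param dataset An `expression_dataset`.
#' @return A tibble with one row per (gene, sample): columns `gene`,
#'   `sample`, `tissue`, `age_months`, `sex`, `value`.
#' @export
expression_tbl <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  long <- tibble::as_tibble(dataset$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value")
  dplyr::left_join(long, dataset$samples, by = "sample") |>
    dplyr::relocate("gene", "sample", "tissue", "age_months", "sex", "value")
}

#' Counts-per-million transform
#'
#' Optional helper for raw-count inputs: scales every sample (column) to one
#' million total counts. The analysis itself assumes already-normalized
#' values and applies no transform by default.
#'
#' @param dataset An `expression_dataset`.
#' @return The dataset with rescaled values.
#' @export
cpm_transform <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  totals <- colSums(dataset$values, na.rm = TRUE)
  if (any(totals == 0)) abort("cannot CPM-scale a sample with zero total")
  dataset$values <- sweep(dataset$values, 2, totals / 1e6, "/")
  dataset
}

#' Coefficient-of-variation filter over replicate animals
#'
#' For every (gene, tissue, age) cell the coefficient of variation
#' CV = sd / mean is computed across the replicate animals (sample sd,
#' n − 1 denominator). A cell is marked invalid when CV >= `threshold` or
#' its replicate mean is zero; invalid cells are excluded from all
#' downstream per-age aggregation. An optional genome-wide per-gene variant
#' (`scope = "gene"`) pools all samples of a gene instead.
#'
#' @param dataset An `expression_dataset`.
#' @param threshold Positive CV cutoff; the published rule is `CV < 1`
#'   (default).
#' @param scope `"cell"` (default): CV within each tissue-by-age cell;
#'   `"gene"`: a single genome-wide CV per gene across all samples,
#'   invalidating all of the gene's cells at once.
#' @return The dataset with an updated `mask` and a `filter_report` tibble
#'   (per-age counts of invalidated cells; threshold stored as attribute).
#' @export
cv_filter <- function(dataset, threshold = 1, scope = c("cell", "gene")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  scope <- match.arg(scope)
  if (!is.finite(threshold) && !is.infinite(threshold)) abort("threshold must be numeric")
  if (threshold <= 0) abort("cv threshold must be > 0")

  keys <- sample_cell_keys(dataset)
  mask <- matrix(TRUE, nrow(dataset$values), nrow(dataset$cells),
    dimnames = dimnames(dataset$mask)
  )
  if (scope == "cell") {
    for (j in seq_len(nrow(dataset$cells))) {
      cols <- which(keys == dataset$cells$cell[j])
      sub <- dataset$values[, cols, drop = FALSE]
      n_obs <- rowSums(!is.na(sub))
      m <- rowMeans(sub, na.rm = TRUE)
      s <- apply(sub, 1, sd, na.rm = TRUE)
      cv <- s / m
      invalid <- (n_obs >= 2 & is.finite(cv) & cv >= threshold) |
        (n_obs >= 1 & m == 0)
      mask[, j] <- !invalid
    }
  } else {
    m <- rowMeans(dataset$values, na.rm = TRUE)
    s <- apply(dataset$values, 1, sd, na.rm = TRUE)
    cv <- s / m
    invalid <- (is.finite(cv) & cv >= threshold) | m == 0
    mask[invalid, ] <- FALSE
  }
  dataset$mask <- mask

  inv_by_cell <- colSums(!mask)
  report <- dataset$cells |>
    dplyr::mutate(n_invalid = inv_by_cell[.data$cell]) |>
    dplyr::group_by(age_months = .data$age_months) |>
    dplyr::summarise(n_invalid = sum(.data$n_invalid), .groups = "drop")
  attr(report, "threshold") <- threshold
  attr(report, "scope") <- scope
  dataset$filter_report <- report
  dataset
}

#' Per-age counts of CV-invalidated cells
#'
#' @param dataset An `expression_dataset` after [cv_filter()].
#' @return The filter-report tibble (`age_months`, `n_invalid`).
#' @export
filter_report <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$filter_report)) abort("cv_filter has not been run")
  dataset$filter_report
}
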
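#' Published per-age group means for the mouse multi-tissue aging series
#'
#' Per-age mean RNA production (normalized expression units) with 95%
#' confidence intervals for the housekeeping (HG) and integrative (IntG) gene
#' groups, as published for the GSE132040 multi-tissue *Mus musculus* aging
#' series (17 tissues, ages 1--27 months, 5--6 animals per tissue and age).
#' These summary values are the standard desk-scale input for the trend,
#' slope-comparison and ratio machinery in this package: every printed
#' regression statistic of the original analysis is a deterministic function
#' of them.
#'
#' @return A tibble with columns `age` (months), `group` (`"HG"` or `"IntG"`),
#'   `mean`, `ci_low`, `ci_high` (expression units), of class `age_table`.
#' @examples
#' ref <- reference_age_means()
#' hg <- dplyr::filter(ref, group == "HG")
#' fit_trend(hg)
#' @export
reference_age_means <- function() {
  tbl <- tibble::tribble(
    ~age, ~group,   ~mean, ~ci_low, ~ci_high,
    1,  "HG",   496.39, 474.49, 518.29,
    3,  "HG",   486.62, 464.47, 508.78,
    6,  "HG",   498.84, 476.33, 521.35,
    9,  "HG",   465.32, 444.47, 486.18,
    12, "HG",   480.44, 459.26, 501.62,
    15, "HG",   485.38, 462.60, 508.16,
    18, "HG",   475.54, 454.77, 496.30,
    21, "HG",   462.22, 441.06, 483.38,
    24, "HG",   460.17, 439.31, 481.02,
    27, "HG",   450.00, 428.02, 471.95,
    1,  "IntG", 135.49, 130.06, 140.92,
    3,  "IntG", 130.96, 125.71, 136.21,
    6,  "IntG", 134.88, 129.34, 140.43,
    9,  "IntG", 125.83, 120.84, 130.81,
    12, "IntG", 130.06, 124.95, 135.10,
    15, "IntG", 130.53, 125.17, 135.88,
    18, "IntG", 132.69, 127.45, 137.93,
    21, "IntG", 125.45, 120.34, 130.56,
    24, "IntG", 126.75, 121.61, 131.89,
    27, "IntG", 123.14, 118.02, 128.27
  )
  tbl
}

#' Extract one group's series from a two-group age table
#'
#' Convenience accessor used with [reference_age_means()]: filters one group
#' and returns it as an `age_series` tibble suitable for [fit_trend()],
#' [segmented_trends()] and [ratio_series()].
#'
#' @param data A tibble with columns `age`, `group`, `mean` and optionally
#'   `ci_low`, `ci_high`.
#' @param group Group label to extract (e.g. `"HG"`).
#' @return An `age_series` tibble (see [group_age_series()]).
#' @export
age_series_of <- function(data, group) {
  stopifnot(is.data.frame(data))
  grp <- group
  out <- data |>
    dplyr::filter(.data$group == grp) |>
    dplyr::arrange(.data$age)
  if (nrow(out) == 0) {
    abort(sprintf("no rows for group '%s'", grp))
  }
  if (!all(c("ci_low", "ci_high") %in% names(out))) {
    out$ci_low <- out$mean
    out$ci_high <- out$mean
  }
  n_genes <- if ("n_genes" %in% names(out)) out$n_genes else NA_integer_
  new_age_series(
    tibble::tibble(
      age = out$age, mean = out$mean,
      ci_low = out$ci_low, ci_high = out$ci_high,
      n_genes = n_genes
    )
  )
}
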
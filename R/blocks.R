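#' Per-age trajectory of a gene block
#'
#' [group_age_series()] applied to a named block's resolved genes: per age,
#' each member gene's mean over its valid samples, then the mean over the
#' block.
#'
#' @param dataset An `expression_dataset`.
#' @param block A `gene_block` (see [gene_block()], [read_gene_block()]).
#' @param ... Passed to [group_age_series()] (e.g. `tissues`).
#' @return An `age_series` tibble.
#' @export
block_trajectory <- function(dataset, block, ...) {
  stopifnot(inherits(block, "gene_block"))
  group_age_series(dataset, catalog = NULL, group = block, ...)
}

#' Start level and segment declines of a block trajectory
#'
#' Summarizes a block's trajectory the way the developmental-block results
#' are reported: the fitted production level at the first grid age (from the
#' early-segment fit) together with the early and late per-month slopes
#' around the a-priori breakpoint. Both numbers of the "start level, decline
#' per month" pair are emitted explicitly. Segment fitting is delegated to
#' [segment_fits()]; there is no independent fitting path.
#'
#' @param series An `age_series` (e.g. from [block_trajectory()]).
#' @param breakpoint Breakpoint age in months (default 9).
#' @return A one-row tibble: `start_level` (fitted value at the first age),
#'   `early_slope`, `late_slope` (units per month), `breakpoint`.
#' @export
block_decline_report <- function(series, breakpoint = 9) {
  fits <- segment_fits(series, breakpoint)
  first_age <- min(series$age)
  tibble::tibble(
    start_level = unname(predict(fits$early, first_age)),
    early_slope = fits$early$slope,
    late_slope = fits$late$slope,
    breakpoint = breakpoint
  )
}

#' Full JSON-ready report for a gene block
#'
#' @param dataset An `expression_dataset`.
#' @param block A `gene_block`.
#' @param breakpoint Breakpoint age in months (default 9).
#' @return A list: `block`, `n_genes`, `unresolved`, `series` (tibble) and
#'   the fields of [block_decline_report()].
#' @export
block_report <- function(dataset, block, breakpoint = 9) {
  series <- block_trajectory(dataset, block)
  decline <- block_decline_report(series, breakpoint)
  list(
    block = attr(block, "name"),
    n_genes = attr(block, "size"),
    unresolved = attr(block, "unresolved"),
    start_level = decline$start_level,
    early_slope = decline$early_slope,
    late_slope = decline$late_slope,
    breakpoint = breakpoint,
    series = tibble::as_tibble(series)
  )
}
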
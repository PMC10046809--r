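#' Ontogenesis stages of Mus musculus
#'
#' The four stages used to structure the 1--27 month observation window:
#' Stage I, development (1--6 months); Stage II, reproductive period (6--15);
#' Stage III, post-reproductive period (15--21); Stage IV, old age (21--27).
#' Stage boundaries coincide with grid ages and are inclusive on both sides,
#' so a boundary age belongs to both adjacent stages.
#'
#' @return A tibble with columns `stage`, `start`, `end` (months).
#' @export
mouse_stages <- function() {
  tibble::tribble(
    ~stage, ~start, ~end,
    "I", 1, 6,
    "II", 6, 15,
    "III", 15, 21,
    "IV", 21, 27
  )
}

#' Per-age HG/IntG production ratio
#'
#' Elementwise quotient of the two groups' per-age aggregated means — the
#' raw ratio, not normalized to its own average. The ratio is the analysis'
#' headline indicator of resource redistribution between the compartments:
#' a common rescaling of the whole expression matrix cancels out of it.
#'
#' @param hg,intg `age_series` tibbles on identical age grids.
#' @return A `ratio_series` tibble: `age`, `ratio`.
#' @examples
#' ref <- reference_age_means()
#' ratio_series(age_series_of(ref, "HG"), age_series_of(ref, "IntG"))
#' @export
ratio_series <- function(hg, intg) {
  stopifnot(is.data.frame(hg), is.data.frame(intg))
  if (!identical(hg$age, intg$age)) abort("HG and IntG series age grids differ")
  zero <- which(intg$mean <= 0)
  if (length(zero) > 0) {
    abort(sprintf("IntG mean is not positive at age %g", intg$age[zero[1]]))
  }
  out <- tibble::tibble(age = hg$age, ratio = hg$mean / intg$mean)
  structure(out, class = c("ratio_series", class(out)))
}

#' @export
print.ratio_series <- function(x, ...) {
  cat(sprintf("<ratio_series> %d age point(s)\n", nrow(x)))
  NextMethod()
}

#' Trend of the production ratio over a closed age interval
#'
#' @param ratio A `ratio_series`.
#' @param start,end Interval bounds in months (closed on both sides); the
#'   interval must contain at least 3 grid ages.
#' @return A `trend_fit` of ratio against age (units: ratio per month).
#' @export
interval_ratio_slope <- function(ratio, start, end) {
  stopifnot(inherits(ratio, "ratio_series"))
  seg <- dplyr::filter(tibble::as_tibble(ratio), .data$age >= start, .data$age <= end)
  if (nrow(seg) < 3) {
    abort(sprintf("interval %g-%g holds fewer than 3 age points", start, end))
  }
  fit_trend(seg, value = ratio)
}

#' Per-stage summary of the production ratio
#'
#' Mean ratio and ratio-per-month slope within each ontogenesis stage
#' (closed intervals; shared boundary ages count in both adjacent stages).
#' Stages holding only 2 grid ages report the two-point slope with a
#' `low_n` flag instead of a regression fit.
#'
#' @param ratio A `ratio_series`.
#' @param stages Stage definitions as in [mouse_stages()] (the default).
#' @return A tibble: `stage`, `n`, `mean_ratio`, `slope`, `low_n`.
#' @export
stage_summary <- function(ratio, stages = mouse_stages()) {
  stopifnot(inherits(ratio, "ratio_series"), is.data.frame(stages))
  if (any(stages$start >= stages$end)) abort("stage start must precede end")
  grid <- range(ratio$age)
  purrr::pmap_dfr(stages, function(stage, start, end) {
    if (start < grid[1] || end > grid[2]) {
      abort(sprintf("stage %s (%g-%g) lies outside the age grid", stage, start, end))
    }
    seg <- dplyr::filter(
      tibble::as_tibble(ratio),
      .data$age >= start, .data$age <= end
    )
    n <- nrow(seg)
    if (n < 2) abort(sprintf("stage %s holds fewer than 2 age points", stage))
    slope <- if (n >= 3) {
      fit_trend(seg, value = ratio)$slope
    } else {
      diff(seg$ratio) / diff(seg$age)
    }
    tibble::tibble(
      stage = stage, n = n, mean_ratio = mean(seg$ratio),
      slope = slope, low_n = n < 3
    )
  })
}

#' @export
autoplot.ratio_series <- function(object, stages = mouse_stages(), ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$ratio))
  if (!is.null(stages)) {
    p <- p + ggplot2::geom_vline(
      xintercept = unique(c(stages$start, stages$end)),
      linetype = "dotted", colour = "grey60"
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Age (months)", y = "HG / IntG production ratio",
      title = "Production-ratio trajectory across ontogenesis stages"
    ) +
    ggplot2::theme_minimal()
}
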
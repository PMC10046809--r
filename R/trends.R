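#' Ordinary least-squares age trend of an aggregated series
#'
#' Fits production = intercept + slope x age by OLS on the per-age aggregated
#' means — one equally weighted point per age, the resolution at which the
#' group trends are defined. Reports the slope with its standard error
#' (sqrt(rss / (n-2) / sxx)), the t statistic with a two-sided p on n-2
#' degrees of freedom, and the Pearson correlation of the same points with
#' its own two-sided p. A constant series is returned with slope 0, r = 0,
#' p = 1 and `degenerate = "constant"`; a zero-residual fit gets
#' `degenerate = "perfect_fit"` with p reported as 0.
#'
#' @param data A data frame of per-age points (e.g. an `age_series`).
#' @param age,value Column names (tidy-eval) holding the age grid in months
#'   and the per-age means; defaults `age` and `mean`.
#' @return A `trend_fit` object: list with `n`, `slope`, `intercept`,
#'   `slope_se`, `t`, `p`, `r`, `r_p`, `rss`, `sxx`, `ages`, `values`,
#'   `degenerate` (`NA`, `"constant"` or `"perfect_fit"`).
#' @examples
#' fit_trend(tibble::tibble(age = c(1, 2, 3), mean = c(1, 3, 5)))
#' @export
fit_trend <- function(data, age = age, value = mean) {
  stopifnot(is.data.frame(data))
  x <- dplyr::pull(data, {{ age }})
  y <- dplyr::pull(data, {{ value }})
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) abort("trend fit needs at least 3 age points")
  if (anyDuplicated(x)) abort("ages must be distinct (aggregate first)")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) abort("zero variance in ages")

  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  rss <- sum(resid(fit)^2)

  degenerate <- NA_character_
  if (sd(y) == 0) {
    slope <- 0
    intercept <- mean(y)
    out <- list(
      n = n, slope = 0, intercept = intercept, slope_se = 0,
      t = 0, p = 1, r = 0, r_p = 1, rss = 0, sxx = sxx,
      ages = x, values = y, degenerate = "constant"
    )
    return(structure(out, class = "trend_fit"))
  }

  slope_se <- sqrt(rss / (n - 2) / sxx)
  syy <- sum((y - mean(y))^2)
  if (rss <= 1e-20 * syy) {
    degenerate <- "perfect_fit"
    t_stat <- sign(slope) * Inf
    p <- 0
    r <- sign(slope)
    r_p <- 0
  } else {
    t_stat <- slope / slope_se
    p <- 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
    ct <- suppressWarnings(cor.test(x, y))
    r <- unname(ct$estimate)
    r_p <- ct$p.value
  }
  structure(
    list(
      n = n, slope = slope, intercept = intercept, slope_se = slope_se,
      t = t_stat, p = p, r = r, r_p = r_p, rss = rss, sxx = sxx,
      ages = x, values = y, degenerate = degenerate
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> n = %d: slope %.4f (se %.4f) per month, t = %.3f, p = %.4g; r = %.3f (p = %.4g)\n",
    x$n, x$slope, x$slope_se, x$t, x$p, x$r, x$r_p
  ))
  if (!is.na(x$degenerate)) cat(sprintf("  degenerate: %s\n", x$degenerate))
  invisible(x)
}

#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$slope_se),
    statistic = c(NA_real_, x$t),
    p.value = c(NA_real_, x$p)
  )
}

#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, slope = x$slope, slope_se = x$slope_se, t = x$t, p = x$p,
    r = x$r, r_p = x$r_p, rss = x$rss, sxx = x$sxx,
    degenerate = x$degenerate
  )
}

#' @export
predict.trend_fit <- function(object, ages = object$ages, ...) {
  object$intercept + object$slope * ages
}

#' @export
autoplot.trend_fit <- function(object, ...) {
  pts <- tibble::tibble(age = object$ages, value = object$values)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope,
      colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "Age (months)", y = "Mean production",
      subtitle = sprintf("slope %.4f per month (p = %.3g)", object$slope, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' Pooled-variance F test for equality of two trend slopes
#'
#' Tests slope homogeneity between two independently fitted age trends.
#' The residual variance is pooled, s2 = (rss_a + rss_b) / (n_a + n_b - 4);
#' the variance of the slope difference is s2 x (1/sxx_a + 1/sxx_b); and
#' F = (slope difference / its se)^2 is referred to the F distribution with
#' (1, n_a + n_b - 4) degrees of freedom (equivalently the squared t of the
#' group-by-age interaction). When both fits are residual-free the pooled
#' variance vanishes: the comparison is flagged degenerate with F = Inf and
#' p = 0 (or F = 0, p = 1 when the slopes are also identical).
#'
#' @param fit_a,fit_b `trend_fit` objects on the same age units.
#' @return A `slope_comparison` object: list with `slope_diff`, `f`, `df1`,
#'   `df2`, `p`, `degenerate`.
#' @export
compare_slopes <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "trend_fit"), inherits(fit_b, "trend_fit"))
  df2 <- as.integer(fit_a$n + fit_b$n - 4L)
  if (df2 <= 0) abort("slope comparison needs n_a + n_b - 4 >= 1")
  slope_diff <- fit_a$slope - fit_b$slope
  s2 <- (fit_a$rss + fit_b$rss) / df2
  syy <- sum((fit_a$values - mean(fit_a$values))^2) +
    sum((fit_b$values - mean(fit_b$values))^2)
  if (fit_a$rss + fit_b$rss <= 1e-20 * max(syy, .Machine$double.eps)) {
    degenerate <- TRUE
    if (abs(slope_diff) <= 1e-10 * max(abs(c(fit_a$slope, fit_b$slope, 1)))) {
      f <- 0
      p <- 1
    } else {
      f <- Inf
      p <- 0
    }
  } else {
    degenerate <- FALSE
    se_diff <- sqrt(s2 * (1 / fit_a$sxx + 1 / fit_b$sxx))
    f <- (slope_diff / se_diff)^2
    p <- pf(f, 1, df2, lower.tail = FALSE)
  }
  structure(
    list(slope_diff = slope_diff, f = f, df1 = 1L, df2 = df2, p = p,
         degenerate = degenerate),
    class = "slope_comparison"
  )
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf(
    "<slope_comparison> slope difference %.4f: F = %.3f on (%d, %d) df, p = %.4g%s\n",
    x$slope_diff, x$f, x$df1, x$df2, x$p,
    if (x$degenerate) " [degenerate: zero pooled residual]" else ""
  ))
  invisible(x)
}

#' @export
glance.slope_comparison <- function(x, ...) {
  tibble::tibble(
    slope_diff = x$slope_diff, f = x$f, df1 = x$df1, df2 = x$df2,
    p = x$p, degenerate = x$degenerate
  )
}

series_segment <- function(series, from, to) {
  seg <- dplyr::filter(tibble::as_tibble(series), .data$age >= from, .data$age <= to)
  if (nrow(seg) < 3) {
    abort(sprintf("interval %g-%g holds fewer than 3 age points", from, to))
  }
  seg
}

#' Segment fits of one series around a fixed breakpoint
#'
#' @param series An `age_series` (or any tibble with `age` and `mean`).
#' @param breakpoint Breakpoint age in months; must be one of the grid ages.
#'   The breakpoint belongs to both closed segments.
#' @return A list with `trend_fit` elements `early` (first age to
#'   breakpoint) and `late` (breakpoint to last age).
#' @export
segment_fits <- function(series, breakpoint = 9) {
  ages <- sort(unique(series$age))
  if (!breakpoint %in% ages) {
    abort(sprintf("breakpoint %g is not one of the grid ages", breakpoint))
  }
  list(
    early = fit_trend(series_segment(series, min(ages), breakpoint)),
    late = fit_trend(series_segment(series, breakpoint, max(ages)))
  )
}

#' A-priori segmented comparison of two groups' trends
#'
#' Fits both groups on the closed early segment (first age to breakpoint)
#' and the closed late segment (breakpoint to last age) — the breakpoint age
#' is shared by both segments — and compares the groups' slopes within each
#' segment with [compare_slopes()]. The breakpoint is fixed in advance (the
#' default, 9 months, is the mouse physiological peak of development), not
#' estimated from the data.
#'
#' @param series_a,series_b `age_series` tibbles on the same age grid.
#' @param breakpoint Breakpoint age in months (default 9).
#' @return A `segmented_trends` object: a named list of intervals, each with
#'   `fit_a`, `fit_b` and `comparison`, plus attributes `breakpoint` and
#'   `labels`.
#' @export
segmented_trends <- function(series_a, series_b, breakpoint = 9) {
  ages_a <- sort(unique(series_a$age))
  ages_b <- sort(unique(series_b$age))
  if (!identical(ages_a, ages_b)) abort("the two series must share an age grid")
  fits_a <- segment_fits(series_a, breakpoint)
  fits_b <- segment_fits(series_b, breakpoint)
  labels <- c(
    early = sprintf("%g-%g", min(ages_a), breakpoint),
    late = sprintf("%g-%g", breakpoint, max(ages_a))
  )
  out <- list(
    early = list(
      fit_a = fits_a$early, fit_b = fits_b$early,
      comparison = compare_slopes(fits_a$early, fits_b$early)
    ),
    late = list(
      fit_a = fits_a$late, fit_b = fits_b$late,
      comparison = compare_slopes(fits_a$late, fits_b$late)
    )
  )
  structure(out,
    breakpoint = breakpoint, labels = labels,
    class = "segmented_trends"
  )
}

#' @export
print.segmented_trends <- function(x, ...) {
  labels <- attr(x, "labels")
  cat(sprintf("<segmented_trends> breakpoint %g months\n", attr(x, "breakpoint")))
  for (seg in names(x)) {
    cmpr <- x[[seg]]$comparison
    cat(sprintf(
      "  %s months: slopes %.4f vs %.4f; F = %.3f on (1, %d) df, p = %.4g\n",
      labels[[seg]], x[[seg]]$fit_a$slope, x[[seg]]$fit_b$slope,
      cmpr$f, cmpr$df2, cmpr$p
    ))
  }
  invisible(x)
}

#' @export
tidy.segmented_trends <- function(x, ...) {
  labels <- attr(x, "labels")
  purrr::map_dfr(names(x), function(seg) {
    a <- x[[seg]]$fit_a
    b <- x[[seg]]$fit_b
    cmpr <- x[[seg]]$comparison
    tibble::tibble(
      interval = labels[[seg]],
      n = a$n,
      slope_a = a$slope, slope_b = b$slope,
      f = cmpr$f, df1 = cmpr$df1, df2 = cmpr$df2, p = cmpr$p
    )
  })
}
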
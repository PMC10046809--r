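test_that("closed-form toy fits are exact and degeneracies are flagged", {
  fit <- fit_trend(tibble::tibble(age = c(1, 2, 3), mean = c(1, 3, 5)))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, -1)
  expect_equal(fit$r, 1)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
  expect_identical(fit$degenerate, "perfect_fit")

  flat <- fit_trend(tibble::tibble(age = c(1, 2, 3, 4), mean = rep(7, 4)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r, 0)
  expect_equal(flat$p, 1)
  expect_identical(flat$degenerate, "constant")

  expect_error(fit_trend(tibble::tibble(age = 1:2, mean = 1:2)), "at least 3")
  expect_error(
    fit_trend(tibble::tibble(age = c(1, 1, 2), mean = 1:3)),
    "distinct"
  )
  expect_error(
    fit_trend(tibble::tibble(age = c(2, 2, 2), mean = 1:3)),
    "distinct|zero variance"
  )
})

test_that("trend fit agrees with a brute-force least-squares search", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    x <- sort(sample(1:40, n))
    y <- stats::rnorm(1, sd = 50) + stats::rnorm(1) * x + stats::rnorm(n, sd = 3)
    fit <- fit_trend(tibble::tibble(age = x, mean = y))
    oracle <- brute_force_ols(x, y)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-6)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-6)
  }
})

test_that("trend statistics satisfy their internal identities", {
  set.seed(102)
  for (i in 1:20) {
    x <- sort(sample(1:30, 8))
    y <- 100 - 2 * x + stats::rnorm(8, sd = 4)
    fit <- fit_trend(tibble::tibble(age = x, mean = y))
    expect_equal(fit$t, fit$slope / fit$slope_se)
    expect_equal(fit$slope_se, sqrt(fit$rss / (fit$n - 2) / fit$sxx))
    expect_equal(sign(fit$r), sign(fit$slope))
    expect_lte(fit$r^2, 1)
    expect_gt(fit$p, 0)
    expect_lte(fit$p, 1)
    # slope p equals correlation p for simple regression
    expect_equal(fit$p, fit$r_p, tolerance = 1e-12)
  }
})

test_that("p-values decrease monotonically in |t| at fixed degrees of freedom", {
  t_vals <- c(0.1, 0.5, 1, 2, 4, 8)
  p_vals <- 2 * stats::pt(abs(t_vals), df = 8, lower.tail = FALSE)
  expect_true(all(diff(p_vals) < 0))
  # and the fit reproduces that mapping
  fit <- fit_trend(ref_hg())
  expect_equal(
    fit$p, 2 * stats::pt(abs(fit$t), df = fit$n - 2, lower.tail = FALSE)
  )
})

test_that("slope comparison matches the interaction-term oracle", {
  set.seed(103)
  for (i in 1:15) {
    x <- c(1, 3, 6, 9, 12, 15, 18, 21, 24, 27)
    ya <- 480 - 1.5 * x + stats::rnorm(10, sd = 8)
    yb <- 130 - 0.4 * x + stats::rnorm(10, sd = 8)
    fa <- fit_trend(tibble::tibble(age = x, mean = ya))
    fb <- fit_trend(tibble::tibble(age = x, mean = yb))
    cmp <- compare_slopes(fa, fb)

    # independent route: separate-intercept separate-slope model, squared
    # t of the group:age interaction
    df <- data.frame(
      y = c(ya, yb), x = c(x, x),
      g = rep(c("a", "b"), each = 10)
    )
    full <- lm(y ~ g + x + g:x, data = df)
    t_int <- summary(full)$coefficients["gb:x", "t value"]
    p_int <- summary(full)$coefficients["gb:x", "Pr(>|t|)"]
    expect_equal(cmp$f, t_int^2, tolerance = 1e-10)
    expect_equal(cmp$p, p_int, tolerance = 1e-10)
    expect_identical(cmp$df2, 16L + 0L)
  }
})

test_that("degenerate slope comparisons are flagged, not errors", {
  fit <- fit_trend(ref_hg())
  self <- compare_slopes(fit, fit)
  expect_equal(self$slope_diff, 0)
  expect_equal(self$f, 0)
  expect_equal(self$p, 1)

  a <- fit_trend(tibble::tibble(age = 1:4, mean = c(1, 2, 3, 4)))
  b <- fit_trend(tibble::tibble(age = 1:4, mean = c(1, 1, 1, 1)))
  perfect <- compare_slopes(a, b)
  expect_true(perfect$degenerate)
  expect_identical(perfect$f, Inf)
  expect_equal(perfect$p, 0)
})

test_that("F is invariant under common rescaling; shifts move only the intercept", {
  hg <- ref_hg()
  intg <- ref_intg()
  base <- compare_slopes(fit_trend(hg), fit_trend(intg))
  for (c_scale in c(0.01, 1, 42.5)) {
    hg2 <- dplyr::mutate(hg, mean = mean * c_scale)
    intg2 <- dplyr::mutate(intg, mean = mean * c_scale)
    scaled <- compare_slopes(fit_trend(hg2), fit_trend(intg2))
    expect_equal(scaled$f, base$f, tolerance = 1e-9)
    expect_equal(scaled$p, base$p, tolerance = 1e-9)
  }
  shifted <- fit_trend(dplyr::mutate(hg, mean = mean + 100))
  plain <- fit_trend(hg)
  expect_equal(shifted$slope, plain$slope)
  expect_equal(shifted$intercept, plain$intercept + 100)
  expect_equal(shifted$t, plain$t)
})

test_that("segments are closed around the breakpoint with 4 and 7 points", {
  hg <- ref_hg()
  intg <- ref_intg()
  seg <- segmented_trends(hg, intg, breakpoint = 9)
  expect_identical(seg$early$fit_a$n, 4L)
  expect_identical(seg$late$fit_a$n, 7L)
  expect_true(9 %in% seg$early$fit_a$ages)
  expect_true(9 %in% seg$late$fit_a$ages)
  expect_identical(attr(seg, "labels"), c(early = "1-9", late = "9-27"))

  expect_error(segmented_trends(hg, intg, breakpoint = 10), "not one of the grid")
  expect_error(
    segmented_trends(hg, intg, breakpoint = 3),
    "fewer than 3 age points"
  )
})

test_that("a symmetric V-shaped series yields mirror-image segment slopes", {
  v <- tibble::tibble(
    age = c(1, 3, 5, 7, 9, 11, 13),
    mean = c(40, 30, 20, 10, 20, 30, 40)
  )
  fits <- segment_fits(v, breakpoint = 7)
  expect_equal(fits$early$slope, -fits$late$slope)
  expect_equal(fits$early$slope, -5)
})

test_that("tidy and glance emit broom-shaped frames", {
  fit <- fit_trend(ref_hg())
  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "slope"))
  expect_equal(td$estimate[2], fit$slope)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  seg <- segmented_trends(ref_hg(), ref_intg())
  ts <- tidy(seg)
  expect_identical(ts$interval, c("1-9", "9-27"))
  expect_identical(ts$n, c(4L, 7L))
})
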
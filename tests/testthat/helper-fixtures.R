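# Shared fixtures and independent oracles, all built in code.

# Published per-age group means used as desk-scale input throughout.
ref_hg <- function() age_series_of(reference_age_means(), "HG")
ref_intg <- function() age_series_of(reference_age_means(), "IntG")

# Hand-buildable toy dataset: 4 genes x (2 tissues x 3 ages x 2 reps).
toy_dataset <- function() {
  ages <- c(1, 2, 3)
  tissues <- c("liver", "brain")
  meta <- expand.grid(
    rep = 1:2, age_months = ages, tissue = tissues,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  meta$sample <- sprintf("%s_a%d_r%d", meta$tissue, meta$age_months, meta$rep)
  meta$sex <- ifelse(meta$rep == 1, "M", "F")
  genes <- c("gA", "gB", "gC", "gD")
  base <- c(gA = 10, gB = 20, gC = 5, gD = 1)
  values <- outer(base, rep(1, nrow(meta)))
  dimnames(values) <- list(genes, meta$sample)
  expression_dataset(values, meta[, c("sample", "tissue", "age_months", "sex")])
}

# Independent least-squares oracle: coarse 2-D grid scan over (intercept,
# slope), iteratively refined around the optimum. Never touches lm().
brute_force_ols <- function(x, y, iters = 60) {
  # centred parameterization y ~ a0 + b (x - mean(x)) keeps the two grid
  # axes orthogonal so the refinement cannot slide off a diagonal valley
  xc <- x - mean(x)
  span_b <- 8 * (diff(range(y)) + 1) / max(diff(range(x)), 1e-9)
  centre <- c(stats::median(y), 0)
  span <- c(8 * (max(abs(y)) + 1), span_b)
  for (i in seq_len(iters)) {
    a_grid <- seq(centre[1] - span[1], centre[1] + span[1], length.out = 21)
    b_grid <- seq(centre[2] - span[2], centre[2] + span[2], length.out = 21)
    sse <- outer(a_grid, b_grid, function(a, b) {
      vapply(seq_along(a), function(k) sum((y - a[k] - b[k] * xc)^2), numeric(1))
    })
    idx <- arrayInd(which.min(sse), dim(sse))
    centre <- c(a_grid[idx[1]], b_grid[idx[2]])
    span <- pmax(span * 0.3, 1e-14)
  }
  list(intercept = centre[1] - centre[2] * mean(x), slope = centre[2])
}

# Small fast simulation config for property tests.
small_config <- function(...) {
  args <- list(
    n_genes = 120, hg_fraction = 0.4, n_tissues = 3,
    replicate_cv = 0.2, tissue_effect_sd = 0.3,
    high_var_fraction = 0, seed = 11
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

noiseless_config <- function(...) {
  small_config(
    replicate_cv = 0, tissue_effect_sd = 0, high_var_fraction = 0, ...
  )
}
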
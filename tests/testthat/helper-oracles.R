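# Shared oracles and fixture builders (independent of the package internals).

# One genotype-trait simulation cell at the standard design: 5 MA lines with
# generations spanning 19-25, 5 individuals per line, 15 controls.
cell_config <- function(z0 = 10, rm = 0, vm = 0, ve = 1,
                        g = c(19, 20.5, 22, 23.5, 25),
                        n_per = 5, n_control = 15) {
  ma_sim_config(
    tibble::tibble(population = "P", genotype = "X", trait = "tr",
                   z0_true = z0, rm_true = rm, vm_raw = vm, ve_raw = ve),
    list(X = g), n_ma_lines = length(g), n_per_ma_line = n_per,
    n_control = n_control
  )
}

# Build a line-summary tibble directly from per-line means.
make_lines <- function(means, g, sampling_variance = 1, n = 5) {
  L <- length(means)
  tibble::tibble(
    line_id = paste0("L", seq_len(L)), n = n, mean = means,
    sample_variance = sampling_variance * n,
    sampling_variance = rep_len(sampling_variance, L),
    generations = g, flagged = FALSE
  )
}

make_control <- function(mean, n = 15, sampling_variance = NA_real_) {
  tibble::tibble(mean = mean, n = n, sampling_variance = sampling_variance)
}

# Full REML -2*log-likelihood of the one-way random-intercept model at a
# given (v_g, v_e), computed by dense matrix algebra -- independent of the
# package's profiled search.
reml_m2ll_direct <- function(v_g, v_e, values, line) {
  line <- as.character(line)
  n <- length(values)
  Z <- outer(line, unique(line), "==") * 1
  V <- v_e * diag(n) + v_g * Z %*% t(Z)
  Vi <- solve(V)
  X <- matrix(1, n, 1)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% values)
  r <- values - X %*% beta
  as.numeric(determinant(V)$modulus + log(XtViX) + t(r) %*% Vi %*% r)
}

# Dense grid search of the REML criterion, iteratively refined around the
# best point.
reml_grid_oracle <- function(values, line, n_refine = 4, width = 41) {
  ybar <- tapply(values, line, mean)
  ni <- tapply(values, line, length)
  ssw <- sum((values - ave(values, as.character(line)))^2)
  msw <- ssw / (length(values) - length(ybar))
  v_e0 <- max(msw, 1e-6)
  v_g0 <- max(var(as.numeric(ybar)), 1e-6)
  lo <- c(v_g0 / 50, v_e0 / 50)
  hi <- c(v_g0 * 50, v_e0 * 50)
  best <- c(v_g0, v_e0)
  for (it in seq_len(n_refine)) {
    gs <- exp(seq(log(lo[1]), log(hi[1]), length.out = width))
    es <- exp(seq(log(lo[2]), log(hi[2]), length.out = width))
    obj <- outer(gs, es, Vectorize(function(a, b)
      reml_m2ll_direct(a, b, values, line)))
    ij <- which(obj == min(obj), arr.ind = TRUE)[1, ]
    best <- c(gs[ij[1]], es[ij[2]])
    span_g <- if (ij[1] == 1 || ij[1] == width) 10 else
      gs[min(ij[1] + 1, width)] / gs[max(ij[1] - 1, 1)]
    span_e <- if (ij[2] == 1 || ij[2] == width) 10 else
      es[min(ij[2] + 1, width)] / es[max(ij[2] - 1, 1)]
    lo <- best / c(span_g, span_e)
    hi <- best * c(span_g, span_e)
  }
  list(v_g = best[1], v_e = best[2])
}

# Balanced one-way ANOVA variance components (closed form).
anova_components <- function(values, line) {
  line <- as.character(line)
  k <- length(unique(line))
  n <- length(values) / k
  ybar <- tapply(values, line, mean)
  msb <- n * var(as.numeric(ybar))
  msw <- sum((values - ave(values, line))^2) / (length(values) - k)
  list(v_e = msw, v_g = (msb - msw) / n)
}
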
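#' Mean-scale MA observations for one genotype-trait
#'
#' Divides every MA observation by the grand mean of the MA-line means
#' for that genotype-trait, so variance components of the scaled data are
#' dimensionless (squared coefficients of variation). A `per_line` option
#' divides each observation by its own line's mean instead; note that
#' this forces every scaled line mean to 1 and hence an among-line
#' variance of exactly zero, so it only makes sense when the within-line
#' spread is the quantity of interest.
#'
#' @param values Numeric vector of MA observations for one genotype-trait.
#' @param line Line identifier for each observation.
#' @param scaling `"grand_mean"` (default) or `"per_line"`.
#' @return Tibble with columns `line` and `scaled`.
#' @export
scale_values <- function(values, line, scaling = c("grand_mean", "per_line")) {
  scaling <- match.arg(scaling)
  line <- as.character(line)
  line_means <- tapply(values, line, mean)
  if (length(line_means) < 2) stop("need at least 2 MA lines")
  if (scaling == "grand_mean") {
    gm <- mean(line_means)
    if (gm == 0) stop("grand mean of line means is zero: cannot scale")
    scaled <- values / gm
  } else {
    scaled <- values / line_means[line]
  }
  tibble::tibble(line = line, scaled = as.numeric(scaled))
}

# profiled -2 * REML log-likelihood (up to an additive constant) of the
# one-way random-intercept model at variance ratio lambda = v_g / v_e
reml_profile <- function(lambda, n_i, ybar_i, ssw, N) {
  w <- n_i / (1 + lambda * n_i)
  mu <- sum(w * ybar_i) / sum(w)
  Q <- ssw + sum(w * (ybar_i - mu)^2)
  (N - 1) * log(Q) + sum(log1p(lambda * n_i)) + log(sum(w))
}

# analytic derivative (score) of reml_profile in lambda; dQ/dlambda uses the
# envelope theorem (mu is the minimizer at each lambda)
reml_score <- function(lambda, n_i, ybar_i, ssw, N) {
  w <- n_i / (1 + lambda * n_i)
  mu <- sum(w * ybar_i) / sum(w)
  Q <- ssw + sum(w * (ybar_i - mu)^2)
  -(N - 1) * sum(w^2 * (ybar_i - mu)^2) / Q + sum(w) - sum(w^2) / sum(w)
}

#' One-way random-effects REML variance components
#'
#' Fits `y_ij = mu + a_i + e_ij` with `a_i ~ N(0, v_g)` (among-line) and
#' `e_ij ~ N(0, v_e)` (within-line) by restricted maximum likelihood.
#' The REML criterion is profiled down to a 1-D search over the variance
#' ratio `lambda = v_g / v_e` (with `mu` and `v_e` available in closed
#' form at each `lambda`), constrained to `lambda >= 0`; the optimum is
#' compared against the `lambda = 0` boundary, so `v_g` is never
#' negative and boundary fits report exactly 0. In the balanced case the
#' interior solution coincides with the ANOVA estimators
#' `v_e = MSW`, `v_g = (MSB - MSW) / n`.
#'
#' @param values Numeric observations (typically scaled; see
#'   [scale_values()]).
#' @param line Line identifier per observation; >= 2 lines, and >= 2
#'   observations in at least one line.
#' @return List with `v_g`, `v_e`, `reml_loglik`, `boundary` (`TRUE` when
#'   `v_g` is pinned at 0), and `degenerate` (`TRUE` when there is no
#'   within-line variation, in which case `v_e = 0` and `v_g` is the
#'   sample variance of the line means).
#' @export
reml_oneway <- function(values, line) {
  line <- as.character(line)
  if (any(!is.finite(values))) stop("values must be finite")
  n_i <- as.numeric(tapply(values, line, length))
  ybar_i <- as.numeric(tapply(values, line, mean))
  k <- length(n_i)
  N <- length(values)
  if (k < 2) stop("need at least 2 lines")
  if (all(n_i < 2)) stop("need at least one line with >= 2 observations")
  ssw <- sum((values - ave(values, line))^2)

  if (ssw <= 0) {
    # no within-line variation: v_e degenerates to 0 and the line means
    # carry all the variance
    return(list(v_g = stats::var(ybar_i), v_e = 0, reml_loglik = Inf,
                boundary = FALSE, degenerate = TRUE))
  }

  crit <- function(loglambda) reml_profile(exp(loglambda), n_i, ybar_i, ssw, N)
  at0 <- reml_profile(0, n_i, ybar_i, ssw, N)
  opt <- stats::optimize(crit, interval = c(-30, 30), tol = 1e-12)
  if (opt$objective < at0 - 1e-12) {
    lambda <- exp(opt$minimum)
    # polish past golden-section precision: root of the analytic score
    lo <- lambda / 4; hi <- lambda * 4
    s_lo <- reml_score(lo, n_i, ybar_i, ssw, N)
    s_hi <- reml_score(hi, n_i, ybar_i, ssw, N)
    if (is.finite(s_lo) && is.finite(s_hi) && s_lo < 0 && s_hi > 0) {
      lambda <- stats::uniroot(reml_score, c(lo, hi), n_i = n_i,
                               ybar_i = ybar_i, ssw = ssw, N = N,
                               tol = lambda * 1e-12)$root
    }
    boundary <- FALSE
    obj <- reml_profile(lambda, n_i, ybar_i, ssw, N)
  } else {
    lambda <- 0
    boundary <- TRUE
    obj <- at0
  }
  w <- n_i / (1 + lambda * n_i)
  mu <- sum(w * ybar_i) / sum(w)
  Q <- ssw + sum(w * (ybar_i - mu)^2)
  v_e <- Q / (N - 1)
  loglik <- -0.5 * (obj - (N - 1) * log(N - 1) + (N - 1) + (N - 1) * log(2 * pi))
  list(v_g = lambda * v_e, v_e = v_e, reml_loglik = loglik,
       boundary = boundary, degenerate = FALSE)
}

#' Evolvability from variance components
#'
#' The per-generation input of mean-standardized mutational variance:
#' `CV_m^2 = V_g / mean_god`, the among-line variance component of the
#' mean-scaled data divided by the mean generations of divergence across
#' the genotype's MA lines. Dimensionless because the data were scaled.
#'
#' @param v_g Among-line variance component of scaled data.
#' @param mean_god Mean generations of divergence (> 0).
#' @return `v_g / mean_god`.
#' @export
cv_m2 <- function(v_g, mean_god) {
  if (mean_god <= 0) stop("mean generations of divergence must be > 0")
  v_g / mean_god
}

#' Permutation (or LRT) test of the among-line variance component
#'
#' Default: a permutation test that shuffles line labels across
#' observations `n_null` times, refits the REML among-line component, and
#' reports `p = (1 + #(v_g_perm >= v_g_obs)) / (1 + n_null)` (add-one
#' correction). Alternative `"lrt"`: a restricted likelihood-ratio test
#' of `v_g = 0` against the one-sided alternative, with the standard
#' 50:50 mixture of a point mass at 0 and chi-square(1) as the null.
#'
#' @param values,line As in [reml_oneway()].
#' @param n_null Number of permutations (default 1000; a warning is
#'   issued below 100).
#' @param seed Integer seed for the permutations.
#' @param method `"permutation"` (default) or `"lrt"`.
#' @return p-value in (0, 1].
#' @export
test_vg <- function(values, line, n_null = 1000, seed = NULL,
                    method = c("permutation", "lrt")) {
  method <- match.arg(method)
  line <- as.character(line)
  if (method == "lrt") {
    fit <- reml_oneway(values, line)
    if (fit$degenerate) return(if (stats::var(values) == 0) 1 else 0)
    if (fit$boundary) return(1)
    n_i <- as.numeric(tapply(values, line, length))
    ybar_i <- as.numeric(tapply(values, line, mean))
    ssw <- sum((values - ave(values, line))^2)
    lrt <- reml_profile(0, n_i, ybar_i, ssw, length(values)) -
      reml_profile(fit$v_g / fit$v_e, n_i, ybar_i, ssw, length(values))
    return(0.5 * stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE))
  }
  if (n_null < 100) warning("n_null < 100: permutation p-value is coarse")
  if (stats::var(values) == 0) return(1)
  obs <- reml_oneway(values, line)$v_g
  local_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_null)) {
      vb <- reml_oneway(values, sample(line))$v_g
      if (vb >= obs) exceed <- exceed + 1L
    }
    (1 + exceed) / (1 + n_null)
  })
}

#' Estimate evolvability for every genotype-trait
#'
#' High-level wrapper: for each genotype-trait, mean-scales the MA
#' observations, partitions their variance with [reml_oneway()], divides
#' the among-line component by the mean generations of divergence, and
#' (optionally) tests it against zero.
#'
#' @param records Phenotype tibble (canonical columns).
#' @param scaling Scaling convention for [scale_values()].
#' @param test `"permutation"`, `"lrt"`, or `"none"`.
#' @param n_null,seed Passed to [test_vg()] when testing.
#' @return Tibble with one row per genotype-trait: `population`,
#'   `genotype`, `trait`, `god`, `v_g`, `v_e`, `cv_m2`, `p`, `boundary`,
#'   `degenerate`.
#' @export
estimate_cv_m2 <- function(records, scaling = "grand_mean",
                           test = c("permutation", "lrt", "none"),
                           n_null = 1000, seed = NULL) {
  test <- match.arg(test)
  ma <- records[records$line_class == "MA", ]
  cells <- unique(ma[c("population", "genotype", "trait")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- ma[ma$population == cell$population & ma$genotype == cell$genotype &
                ma$trait == cell$trait, ]
    god <- mean_generations(tapply(sub$generations, sub$line_id, unique))
    sc <- scale_values(sub$value, sub$line_id, scaling = scaling)
    fit <- reml_oneway(sc$scaled, sc$line)
    p <- switch(test,
      none = NA_real_,
      permutation = test_vg(sc$scaled, sc$line, n_null = n_null,
                            seed = seed, method = "permutation"),
      lrt = test_vg(sc$scaled, sc$line, method = "lrt")
    )
    tibble::tibble(
      population = cell$population, genotype = cell$genotype,
      trait = cell$trait, god = god,
      v_g = fit$v_g, v_e = fit$v_e,
      cv_m2 = cv_m2(fit$v_g, god), p = p,
      boundary = fit$boundary, degenerate = fit$degenerate
    )
  })
  dplyr::bind_rows(out)
}
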
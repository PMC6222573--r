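#' Inverse-sampling-variance line weights
#'
#' Weights for the mutational-bias regression: each MA-line mean enters
#' with weight `1 / max(sampling_variance, variance_floor)`. The floor
#' keeps a line whose assayed individuals happened to be identical (zero
#' sample variance) from receiving infinite weight; lines with undefined
#' sampling variance (a single individual) also fall back to the floor,
#' with a warning.
#'
#' @param lines Line-summary tibble from [summarize_lines()].
#' @param variance_floor Positive lower bound on the sampling variance.
#' @return Numeric vector of weights, one per line.
#' @export
line_weights <- function(lines, variance_floor) {
  if (variance_floor <= 0) stop("variance_floor must be > 0")
  sv <- lines$sampling_variance
  if (all(is.na(sv)))
    stop("no line has a defined sampling variance (all n = 1)")
  undefined <- is.na(sv)
  floored <- !undefined & sv < variance_floor
  if (any(undefined))
    warning(sum(undefined), " line(s) with n = 1: sampling variance undefined, ",
            "weight set to 1/variance_floor")
  if (any(floored))
    warning(sum(floored), " line(s) with sampling variance below the floor (",
            format(variance_floor), ")")
  sv[undefined] <- variance_floor
  1 / pmax(sv, variance_floor)
}

#' Weighted least-squares slope through a fixed control intercept
#'
#' Fits the per-generation change in mean phenotype `R_m` as the slope of
#' the weighted least-squares regression of MA-line means `z_M` on their
#' generations of divergence `g`, with the intercept fixed at the control
#' mean `z_0`. The minimizer of
#' `sum w_i (z_Mi - z0 - Rm * g_i)^2` is
#' `Rm = sum(w g (zM - z0)) / sum(w g^2)`.
#'
#' The standard error has two components: the weighted residual mean
#' square `sum(w r^2) / (L - 1)` scaled by `1 / sum(w g^2)` (robust to
#' the overall scale of the weights), plus the sampling error of the
#' estimated control mean propagated through the fixed intercept,
#' `(sum(w g) / sum(w g^2))^2 * Var(z0_hat)`. The second term matters:
#' with generations nearly constant across lines, an error in the
#' intercept is absorbed almost entirely by the slope, so ignoring it
#' badly understates the slope's uncertainty. Degrees of freedom are
#' `L - 1`, the intercept being fixed.
#'
#' @param lines Line-summary tibble (needs `mean`, `generations`).
#' @param control Control summary tibble (needs `mean` and, for the
#'   intercept-error term, `sampling_variance`); `z_0`.
#' @param weights Weights from [line_weights()] (or any positive vector).
#' @return List with `rm`, `se_rm`, `df` (Welch-Satterthwaite effective
#'   df combining the residual component, `L - 1`, with the control df;
#'   possibly fractional), the SE components `se_resid` (residual-only)
#'   and `se_z0` (intercept-error), and `df_resid = L - 1`.
#' @export
fit_rm <- function(lines, control, weights) {
  L <- nrow(lines)
  if (L < 2) stop("need at least 2 MA lines to estimate R_m")
  g <- lines$generations
  if (any(g <= 0)) stop("all MA lines must have generations > 0")
  if (length(weights) != L) stop("one weight per line required")
  z0 <- control$mean
  d <- lines$mean - z0
  swg2 <- sum(weights * g^2)
  if (swg2 == 0) stop("sum of w * g^2 is zero: slope undefined")
  rm_hat <- sum(weights * g * d) / swg2
  r <- d - rm_hat * g
  s2 <- sum(weights * r^2) / (L - 1)
  se_resid <- sqrt(s2 / swg2)
  vz0 <- control$sampling_variance
  if (is.null(vz0) || length(vz0) == 0 || is.na(vz0)) {
    warning("control sampling variance unavailable: ",
            "intercept error not propagated into se_rm")
    vz0 <- 0
  }
  se_z0 <- (sum(weights * g) / swg2) * sqrt(vz0)
  se_rm <- sqrt(se_resid^2 + se_z0^2)
  # Welch-Satterthwaite effective df. The intercept component carries the
  # control df (n0 - 1). The residual component is assigned 1 effective
  # df, not L - 1: with inverse-variance weights estimated from few
  # individuals per line, the weighted standardized residuals are
  # heavy-tailed (t-like with ~n-1 df, lacking a fourth moment), so the
  # chi-square-equivalent df of the residual mean square is far below
  # L - 1; null-calibration simulations at the 5-line, 5-individual
  # design put it at ~1. With no intercept-error term the classical
  # L - 1 is used.
  df_z0 <- if (!is.null(control$n) && length(control$n) == 1 && !is.na(control$n))
    max(control$n - 1, 1) else 1
  df_eff <- if (se_rm == 0 || se_z0 == 0) L - 1 else
    se_rm^4 / (se_resid^4 / 1 + se_z0^4 / df_z0)
  list(rm = rm_hat, se_rm = se_rm, df = df_eff,
       se_resid = se_resid, se_z0 = se_z0, df_resid = L - 1L)
}

#' Scale R_m by the control mean
#'
#' The mutational bias `delta_M = R_m / z_0`: the proportional
#' per-generation change in the trait mean, comparable across traits and
#' genotypes with different measurement scales.
#'
#' @param rm Per-generation change in mean phenotype (trait units/gen).
#' @param z0 Control mean phenotype (nonzero).
#' @return `rm / z0`.
#' @export
delta_m <- function(rm, z0) {
  if (any(z0 == 0)) stop("z0 = 0: the scaled bias delta_M is undefined")
  rm / z0
}

#' t-test of the mutational-bias slope
#'
#' Two-sided t-test of `R_m = 0` using `t = rm / se_rm` on `df` degrees
#' of freedom.
#'
#' @param rm,se_rm,df Slope, its standard error and residual degrees of
#'   freedom, as from [fit_rm()].
#' @return List with `t_stat` and `p_value`. A zero standard error with a
#'   nonzero slope is degenerate: `p` is reported as 0 with a warning.
#' @export
test_slope <- function(rm, se_rm, df) {
  if (df < 1) stop("df must be >= 1")
  if (se_rm == 0) {
    if (rm == 0) return(list(t_stat = 0, p_value = 1))
    warning("se_rm = 0: slope test degenerate, p reported as 0")
    return(list(t_stat = sign(rm) * Inf, p_value = 0))
  }
  t <- rm / se_rm
  list(t_stat = t, p_value = 2 * stats::pt(-abs(t), df))
}

#' Estimate mutational bias for every genotype-trait
#'
#' High-level wrapper: for each genotype-trait present in a phenotype
#' table, summarizes MA lines and controls, fits the fixed-intercept
#' weighted regression, scales the slope by the control mean, and tests
#' it against zero.
#'
#' @param records Phenotype tibble (canonical columns).
#' @param variance_floor_scale The variance floor passed to
#'   [line_weights()] is `variance_floor_scale * z0^2` (a dimensionless
#'   floor on the squared scale of the trait); default `1e-8`.
#' @return Tibble with one row per genotype-trait: `population`,
#'   `genotype`, `trait`, `n_lines`, `god`, `z0`, `rm`, `se_rm`,
#'   `delta_m`, `t`, `p`.
#' @export
estimate_delta_m <- function(records, variance_floor_scale = 1e-8) {
  cells <- unique(records[records$line_class == "MA",
                          c("population", "genotype", "trait")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- records[records$population == cell$population, ]
    s <- summarize_lines(sub, cell$genotype, cell$trait)
    z0 <- s$control$mean
    floor_i <- variance_floor_scale * max(z0^2, .Machine$double.eps)
    w <- line_weights(s$lines, floor_i)
    fit <- fit_rm(s$lines, s$control, w)
    ts <- test_slope(fit$rm, fit$se_rm, fit$df)
    tibble::tibble(
      population = cell$population, genotype = cell$genotype,
      trait = cell$trait, n_lines = nrow(s$lines),
      god = mean_generations(s$lines), z0 = z0,
      rm = fit$rm, se_rm = fit$se_rm,
      delta_m = delta_m(fit$rm, z0),
      t = ts$t_stat, p = ts$p_value
    )
  })
  dplyr::bind_rows(out)
}
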
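# tie-correction factor C = 1 - sum(t^3 - t) / (N^3 - N) over tie groups
tie_correction_factor <- function(x) {
  N <- length(x)
  t <- table(x)
  1 - sum(t^3 - t) / (N^3 - N)
}

# exhaustive enumeration of group assignments for the exact permutation
# distribution of H (multiset of group labels over pooled ranks)
kw_exact_p <- function(values, sizes, h_obs) {
  N <- length(values)
  r <- rank(values)
  C <- tie_correction_factor(values)
  if (C <= 0) return(1)
  count <- 0L; total <- 0L
  recurse <- function(remaining, sizes_left, acc) {
    if (length(sizes_left) == 1) {
      groups <- c(acc, list(remaining))
      Rj <- vapply(groups, function(i) sum(r[i]), numeric(1))
      nj <- lengths(groups)
      h <- (12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)) / C
      total <<- total + 1L
      if (h >= h_obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    picks <- utils::combn(remaining, sizes_left[1], simplify = FALSE)
    for (p in picks)
      recurse(setdiff(remaining, p), sizes_left[-1], c(acc, list(p)))
  }
  recurse(seq_len(N), sizes, list())
  count / total
}

#' Tie-corrected Kruskal-Wallis test
#'
#' The k-sample rank test on a list of groups: mid-ranks over the pooled
#' sample, `H = [12/(N(N+1)) * sum R_j^2/n_j - 3(N+1)] / C` with tie
#' correction `C = 1 - sum(t^3 - t)/(N^3 - N)`, and a chi-square p-value
#' on `k - 1` degrees of freedom (via [stats::kruskal.test()]).
#' Optionally an exact permutation p-value, obtained by enumerating all
#' reassignments of the pooled values to groups of the observed sizes
#' (feasible for pooled N up to about 12).
#'
#' @param groups List of numeric vectors, one per group (>= 2 non-empty
#'   groups, pooled N >= 3).
#' @param exact Also compute the exact permutation p-value (`p_exact`).
#' @param grouping Optional label describing what the groups are.
#' @return A list of class `"kw_result"`: `h_stat`, `df`, `p_value`,
#'   `tie_correction`, `group_sizes`, `grouping`, and `p_exact` (`NA`
#'   unless `exact = TRUE`). When every pooled value is identical the
#'   statistic is degenerate: `H = 0`, `p = 1`, with a warning.
#' @export
kruskal_wallis <- function(groups, exact = FALSE, grouping = NA_character_) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  sizes <- lengths(groups)
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("pooled sample must have N >= 3")
  g <- factor(rep(seq_along(groups), sizes))
  C <- tie_correction_factor(x)
  if (C <= 0) {
    warning("all pooled values identical: H degenerate, reported as 0")
    res <- list(h_stat = 0, df = length(groups) - 1L, p_value = 1,
                tie_correction = 0, group_sizes = as.integer(sizes),
                grouping = grouping, p_exact = if (exact) 1 else NA_real_)
    class(res) <- "kw_result"
    return(res)
  }
  kt <- stats::kruskal.test(x, g)
  h <- unname(kt$statistic)
  p_exact <- NA_real_
  if (exact) {
    if (length(x) > 12)
      stop("exact permutation p only supported for pooled N <= 12")
    p_exact <- kw_exact_p(x, sizes, h)
  }
  res <- list(h_stat = h, df = unname(kt$parameter), p_value = kt$p.value,
              tie_correction = C, group_sizes = as.integer(sizes),
              grouping = grouping, p_exact = p_exact)
  class(res) <- "kw_result"
  res
}

#' @export
print.kw_result <- function(x, ...) {
  cat("Kruskal-Wallis", if (!is.na(x$grouping)) paste0("[", x$grouping, "]"),
      "\n  H =", format(x$h_stat, digits = 5), " df =", x$df,
      " p =", format(x$p_value, digits = 4),
      if (!is.na(x$p_exact)) paste(" p_exact =", format(x$p_exact, digits = 4)),
      "\n  tie correction =", format(x$tie_correction, digits = 5),
      " group sizes =", paste(x$group_sizes, collapse = ", "), "\n")
  invisible(x)
}

as_kw_row <- function(res) {
  tibble::tibble(grouping = res$grouping, h = res$h_stat, df = res$df,
                 p = res$p_value, tie_correction = res$tie_correction,
                 n_groups = length(res$group_sizes))
}

#' Compare |delta_M| among traits
#'
#' Kruskal-Wallis on the absolute mutational bias grouped by trait: do
#' traits differ in the magnitude of their per-generation response to
#' mutation? The absolute value discards the direction of change, which
#' differs in meaning across traits.
#'
#' @param estimates Tibble with columns `trait` and `delta_m` (one row
#'   per genotype-trait, as from [estimate_delta_m()] or
#'   [dmagna_ma_estimates()]).
#' @return A `"kw_result"`.
#' @export
compare_traits <- function(estimates) {
  groups <- split(abs(estimates$delta_m), estimates$trait)
  if (length(groups) < 2 || any(lengths(groups) < 2))
    stop("need >= 2 traits with >= 2 estimates each")
  kruskal_wallis(groups, grouping = "traits (|delta_M|)")
}

#' Compare |delta_M| between behavioral and non-behavioral traits
#'
#' Two-group Kruskal-Wallis (equivalent to a two-sided rank-sum test) on
#' the absolute mutational bias, pooling traits into behavioral and
#' non-behavioral sets.
#'
#' @inheritParams compare_traits
#' @param behavioral,non_behavioral Disjoint character sets covering the
#'   traits in `estimates`; defaults [behavioral_traits()] /
#'   [non_behavioral_traits()].
#' @return A `"kw_result"`.
#' @export
compare_trait_types <- function(estimates,
                                behavioral = behavioral_traits(),
                                non_behavioral = non_behavioral_traits()) {
  if (length(behavioral) == 0 || length(non_behavioral) == 0)
    stop("both trait sets must be non-empty")
  if (length(intersect(behavioral, non_behavioral)) > 0)
    stop("behavioral and non_behavioral sets must be disjoint")
  unknown <- setdiff(unique(estimates$trait), c(behavioral, non_behavioral))
  if (length(unknown) > 0)
    stop("trait(s) not assigned to a type: ", paste(unknown, collapse = ", "))
  type <- ifelse(estimates$trait %in% behavioral, "behavioral", "non_behavioral")
  kruskal_wallis(split(abs(estimates$delta_m), type),
                 grouping = "trait type (|delta_M|)")
}

#' Compare signed delta_M among genotypes or populations
#'
#' Kruskal-Wallis on the signed mutational bias grouped by genotype
#' (within-population labels are combined with the population to keep
#' genotypes distinct) or by population: do genomic backgrounds differ in
#' both the magnitude and direction of their response to mutation?
#'
#' @inheritParams compare_traits
#' @return A `"kw_result"`.
#' @export
compare_genotypes <- function(estimates) {
  lab <- paste0(estimates$population, ":", estimates$genotype)
  groups <- split(estimates$delta_m, lab)
  if (length(groups) < 2 || any(lengths(groups) < 2))
    stop("need >= 2 genotypes with >= 2 estimates each")
  kruskal_wallis(groups, grouping = "genotypes (delta_M)")
}

#' @rdname compare_genotypes
#' @export
compare_populations <- function(estimates) {
  groups <- split(estimates$delta_m, estimates$population)
  if (length(groups) < 2 || any(lengths(groups) < 2))
    stop("need >= 2 populations with >= 2 estimates each")
  kruskal_wallis(groups, grouping = "populations (delta_M)")
}

#' All four hierarchy comparisons
#'
#' Runs the trait, trait-type, genotype and population comparisons of the
#' mutational-bias estimates and stacks the results.
#'
#' @inheritParams compare_trait_types
#' @return Tibble with one row per comparison: `grouping`, `h`, `df`,
#'   `p`, `tie_correction`, `n_groups`.
#' @export
hierarchy_tests <- function(estimates,
                            behavioral = behavioral_traits(),
                            non_behavioral = non_behavioral_traits()) {
  dplyr::bind_rows(
    as_kw_row(compare_traits(estimates)),
    as_kw_row(compare_trait_types(estimates, behavioral, non_behavioral)),
    as_kw_row(compare_genotypes(estimates)),
    as_kw_row(compare_populations(estimates))
  )
}
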
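test_that("separated groups reproduce the hand-computed H = 27/7", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$h_stat, 27 / 7, tolerance = 1e-12)
  expect_equal(kw$df, 1L)
  expect_equal(kw$tie_correction, 1)
  expect_equal(kw$p_value, pchisq(27 / 7, 1, lower.tail = FALSE))
})

test_that("exchangeable identical groups give H = 0", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw$h_stat, 0, tolerance = 1e-12)
  expect_gt(kw$p_value, 0.99)
})

test_that("fully tied data degenerate to H = 0, p = 1 with a warning", {
  expect_warning(kw <- kruskal_wallis(list(c(2, 2), c(2, 2, 2))), "identical")
  expect_equal(kw$h_stat, 0)
  expect_equal(kw$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric())), "empty")
})

test_that("tie-corrected H on duplicate-free data equals the uncorrected statistic", {
  set.seed(3)
  x <- sample(100, 9) # distinct values
  groups <- split(x, rep(1:3, each = 3))
  kw <- kruskal_wallis(groups)
  r <- rank(unlist(groups))
  Rj <- tapply(r, rep(1:3, each = 3), sum)
  N <- 9
  h_raw <- 12 / (N * (N + 1)) * sum(Rj^2 / 3) - 3 * (N + 1)
  expect_equal(kw$h_stat, h_raw, tolerance = 1e-12)
  expect_equal(kw$tie_correction, 1)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(5)
  groups <- split(rnorm(12), rep(1:3, each = 4))
  kw <- kruskal_wallis(groups)
  kw2 <- kruskal_wallis(lapply(groups, function(v) exp(3 * v) - 1))
  expect_equal(kw2$h_stat, kw$h_stat, tolerance = 1e-12)
})

test_that("exact permutation p: extreme two-group split has p = 2/20", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)), exact = TRUE)
  # only the observed split and its mirror reach H = 27/7 among C(6,3) = 20
  expect_equal(kw$p_exact, 2 / 20)
  expect_error(kruskal_wallis(list(rnorm(7), rnorm(7)), exact = TRUE),
               "N <= 12")
})

test_that("chi-square p tracks the exact permutation p where it matters", {
  # The chi-square tail approximation at pooled N <= 12 is accurate in the
  # rejection-relevant region (exact p <= 0.15) but can drift by up to ~0.1
  # deep in the null region, where the discrepancy never changes a decision.
  set.seed(7)
  gaps <- c()
  for (i in 1:30) {
    sizes <- sample(list(c(5, 5), c(6, 6), c(4, 4, 4), c(5, 4, 3)), 1)[[1]]
    groups <- lapply(sizes, function(n) rnorm(n, mean = runif(1, 0, 1.5)))
    kw <- kruskal_wallis(groups, exact = TRUE)
    gap <- abs(kw$p_value - kw$p_exact)
    if (kw$p_exact <= 0.15) expect_lt(gap, 0.05)
    gaps <- c(gaps, gap)
  }
  expect_lt(mean(gaps), 0.05)
})

test_that("two-group H equals the squared standardized rank-sum statistic", {
  set.seed(9)
  for (i in 1:10) {
    n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    kw <- kruskal_wallis(list(x, y))
    # normal-approximation z of the Wilcoxon rank-sum, no continuity correction
    N <- n1 + n2
    W <- sum(rank(c(x, y))[1:n1])
    z <- (W - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
    expect_equal(kw$h_stat, z^2, tolerance = 1e-10)
    expect_equal(kw$p_value, pchisq(z^2, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("trait comparison groups |delta_M| by trait", {
  est <- dmagna_ma_estimates()
  kw <- compare_traits(est)
  expect_equal(kw$df, 5L)
  expect_equal(sort(kw$group_sizes), rep(6L, 6))
  # one trait shifted far above the others becomes detectable
  shifted <- est
  shifted$delta_m[shifted$trait == "AM"] <- shifted$delta_m[shifted$trait == "AM"] + 10
  expect_lt(compare_traits(shifted)$p_value, 0.01)
})

test_that("trait-type comparison is symmetric under label swap and checks sets", {
  est <- dmagna_ma_estimates()
  a <- compare_trait_types(est)
  b <- compare_trait_types(est,
                           behavioral = non_behavioral_traits(),
                           non_behavioral = behavioral_traits())
  expect_equal(a$h_stat, b$h_stat, tolerance = 1e-12)
  expect_error(compare_trait_types(est, behavioral = c("MaxV")),
               "not assigned")
  expect_error(compare_trait_types(est, behavioral = c("MaxV", "AM"),
                                   non_behavioral = c("AM", "Egg", "Size",
                                                      "MeanV", "SDV")),
               "disjoint")
})

test_that("genotype and population comparisons use signed estimates", {
  est <- dmagna_ma_estimates()
  kg <- compare_genotypes(est)
  expect_equal(kg$df, 5L)
  kp <- compare_populations(est)
  expect_equal(kp$df, 1L)
  expect_equal(sort(kp$group_sizes), c(18L, 18L))
  # flipping every sign leaves H unchanged (ranks reverse)
  flipped <- est
  flipped$delta_m <- -flipped$delta_m
  expect_equal(compare_populations(flipped)$h_stat, kp$h_stat,
               tolerance = 1e-12)
})

test_that("observed genotype H sits in the permutation tail", {
  est <- dmagna_ma_estimates()
  kg <- compare_genotypes(est)
  lab <- paste0(est$population, est$genotype)
  set.seed(15)
  h_perm <- replicate(2000, {
    kruskal_wallis(split(est$delta_m, sample(lab)))$h_stat
  })
  expect_gt(kg$h_stat, quantile(h_perm, 0.95))
})

test_that("hierarchy_tests stacks the four comparisons", {
  out <- hierarchy_tests(dmagna_ma_estimates())
  expect_equal(nrow(out), 4)
  expect_equal(out$df, c(5L, 1L, 5L, 1L))
  expect_true(all(out$p >= 0 & out$p <= 1))
})
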
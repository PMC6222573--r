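test_that("grand-mean scaling divides by the mean of line means", {
  values <- c(1, 3, 3, 5) # line means 2 and 4, grand mean 3
  line <- c("a", "a", "b", "b")
  sc <- scale_values(values, line)
  m <- tapply(sc$scaled, sc$line, mean)
  expect_equal(as.numeric(m[c("a", "b")]), c(2 / 3, 4 / 3))
  same <- scale_values(rep(7, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(same$scaled, rep(1, 6))
  expect_error(scale_values(c(-1, 1), c("a", "b")), "grand mean")
  expect_error(scale_values(1:3, rep("a", 3)), "at least 2")
})

test_that("per-line scaling forces every scaled line mean to one", {
  set.seed(2)
  values <- rnorm(12, 10)
  line <- rep(letters[1:3], each = 4)
  sc <- scale_values(values, line, scaling = "per_line")
  expect_equal(as.numeric(tapply(sc$scaled, sc$line, mean)), rep(1, 3))
})

test_that("scaling scales the among-line variance by 1 / grand_mean^2", {
  set.seed(3)
  values <- rnorm(20, 10, 2)
  line <- rep(letters[1:4], each = 5)
  lm_raw <- tapply(values, line, mean)
  gm <- mean(lm_raw)
  sc <- scale_values(values, line)
  expect_equal(var(as.numeric(tapply(sc$scaled, sc$line, mean))),
               var(as.numeric(lm_raw)) / gm^2)
})

test_that("REML degenerates cleanly with no within-line variation", {
  values <- c(1, 1, 2, 2, 3, 3)
  line <- rep(c("a", "b", "c"), each = 2)
  fit <- reml_oneway(values, line)
  expect_true(fit$degenerate)
  expect_equal(fit$v_e, 0)
  expect_equal(fit$v_g, 1) # sample variance of line means {1,2,3}
})

test_that("REML hits the v_g = 0 boundary when lines do not separate", {
  values <- c(0, 2, 1, 3, 2, 4)
  line <- rep(c("a", "b", "c"), each = 2)
  fit <- reml_oneway(values, line)
  expect_true(fit$boundary)
  expect_equal(fit$v_g, 0)
  expect_equal(fit$v_e, 2)
  expect_false(fit$degenerate)
})

test_that("balanced interior REML equals the ANOVA closed form", {
  set.seed(11)
  for (i in 1:25) {
    k <- sample(4:8, 1); n <- sample(3:6, 1)
    line <- rep(paste0("L", 1:k), each = n)
    values <- rnorm(k * n, rep(rnorm(k, 0, 2), each = n), 1)
    fit <- reml_oneway(values, line)
    cf <- anova_components(values, line)
    if (cf$v_g > 0.05) { # comfortably interior
      expect_false(fit$boundary)
      expect_equal(fit$v_e, cf$v_e, tolerance = 1e-8)
      expect_equal(fit$v_g, cf$v_g, tolerance = 1e-8)
    } else {
      expect_gte(fit$v_g, 0)
    }
  }
})

test_that("unbalanced REML matches a dense grid search of the criterion", {
  set.seed(13)
  for (i in 1:8) {
    k <- sample(4:6, 1)
    n_i <- sample(2:7, k, replace = TRUE)
    line <- rep(paste0("L", 1:k), n_i)
    values <- rnorm(sum(n_i), rep(rnorm(k, 0, 1.5), n_i), 1)
    fit <- reml_oneway(values, line)
    if (fit$boundary) next
    oracle <- reml_grid_oracle(values, line, n_refine = 6)
    expect_equal(fit$v_g, oracle$v_g, tolerance = 1e-4)
    expect_equal(fit$v_e, oracle$v_e, tolerance = 1e-4)
    # the package optimum is at least as good under the oracle criterion
    expect_lte(reml_m2ll_direct(fit$v_g, fit$v_e, values, line),
               reml_m2ll_direct(oracle$v_g, oracle$v_e, values, line) + 1e-8)
  }
})

test_that("REML agrees with lme4 on unbalanced fits", {
  set.seed(17)
  for (i in 1:5) {
    k <- sample(4:7, 1)
    n_i <- sample(2:8, k, replace = TRUE)
    line <- rep(paste0("L", 1:k), n_i)
    values <- rnorm(sum(n_i), rep(rnorm(k, 0, 1.5), n_i), 1)
    fit <- reml_oneway(values, line)
    lf <- lme4::lmer(values ~ 1 + (1 | line), REML = TRUE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(lf))
    expect_equal(fit$v_g, vc$vcov[1], tolerance = 1e-5)
    expect_equal(fit$v_e, vc$vcov[2], tolerance = 1e-6)
    expect_equal(fit$reml_loglik, as.numeric(logLik(lf)), tolerance = 1e-6)
  }
})

test_that("cv_m2 divides the among-line component by mean generations", {
  expect_equal(cv_m2(0, 22), 0)
  expect_equal(cv_m2(0.05, 25), 0.002)
  expect_error(cv_m2(0.05, 0), "> 0")
})

test_that("permutation test: degenerate data give p = 1; signal is detected", {
  expect_equal(test_vg(rep(3, 10), rep(c("a", "b"), 5), n_null = 200, seed = 1), 1)
  expect_warning(test_vg(rnorm(10), rep(c("a", "b"), 5), n_null = 50, seed = 1),
                 "coarse")
  # strong separation among lines
  set.seed(23)
  line <- rep(paste0("L", 1:5), each = 5)
  values <- rnorm(25, rep(c(0, 5, 10, 15, 20), each = 5), 0.5)
  p <- test_vg(values, line, n_null = 300, seed = 2)
  expect_lt(p, 0.01)
  # same seed, same p
  expect_equal(p, test_vg(values, line, n_null = 300, seed = 2))
})

test_that("restricted LRT agrees qualitatively with the permutation test", {
  set.seed(29)
  line <- rep(paste0("L", 1:5), each = 5)
  strong <- rnorm(25, rep(c(0, 5, 10, 15, 20), each = 5), 0.5)
  expect_lt(test_vg(strong, line, method = "lrt"), 0.001)
  null_ish <- rnorm(25, 0, 1)
  expect_gt(test_vg(null_ish, line, method = "lrt"), 0.01)
})

test_that("CV_m^2 is dimensionless: invariant to rescaling raw phenotypes", {
  rec <- simulate_experiment(cell_config(vm = 0.2, ve = 1), seed = 37)
  e1 <- estimate_cv_m2(rec, test = "none")
  rec2 <- rec
  rec2$value <- rec2$value * 0.013
  e2 <- estimate_cv_m2(rec2, test = "none")
  expect_equal(e2$cv_m2, e1$cv_m2, tolerance = 1e-8)
  expect_equal(e2$v_g, e1$v_g, tolerance = 1e-8)
})

test_that("estimate_cv_m2 reports boundary fits as exactly zero", {
  rec <- simulate_experiment(cell_config(vm = 0, ve = 1), seed = 41)
  e <- estimate_cv_m2(rec, test = "none")
  if (e$boundary) expect_identical(e$cv_m2, 0)
  expect_gte(e$cv_m2, 0)
  expect_equal(e$god, 22)
})
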
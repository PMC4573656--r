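# Recovery of residual variance and covariance matrices.

test_that("recovered residual variance is prediction variance times (1/R2 - 1)", {
  eq <- registry_equation("beech_1")$equation
  set.seed(3)
  trees <- data.frame(dbh_cm = runif(30, 10, 60), ht_m = runif(30, 8, 35))
  v <- var(predict(eq, trees, type = "link"))
  expect_equal(recover_residual_variance(eq, trees, 0.96),
               v * (1 / 0.96 - 1), tolerance = 1e-12)
  # perfect fit leaves no residual variance; R2 = 0.5 returns V itself
  expect_equal(recover_residual_variance(eq, trees, 1), 0)
  expect_equal(recover_residual_variance(eq, trees, 0.5), v)
  # log-linear equations work on the log scale
  gz <- registry_equation("guazuma_ulmifolia")$equation
  dtrees <- data.frame(dbh_cm = c(8, 12.9, 25))
  vlog <- var(-1.62 + 2.12 * log(dtrees$dbh_cm))
  expect_equal(recover_residual_variance(gz, dtrees, 0.97),
               vlog * (1 / 0.97 - 1), tolerance = 1e-12)
  expect_error(recover_residual_variance(
    eq, data.frame(dbh_cm = c(30, 30), ht_m = c(20, 20)), 0.9),
    "degenerate")
  expect_error(recover_residual_variance(eq, trees, 0), "0, 1")
})

test_that("recovered residual variance decreases strictly in R-squared", {
  eq <- registry_equation("beech_1")$equation
  set.seed(4)
  trees <- data.frame(dbh_cm = runif(40, 10, 60), ht_m = runif(40, 8, 35))
  r2 <- seq(0.5, 0.999, by = 0.01)
  s2 <- vapply(r2, function(r) recover_residual_variance(eq, trees, r),
               numeric(1))
  expect_true(all(diff(s2) < 0))
})

test_that("basic recovery on a fixed replicate equals the textbook
           least-squares covariance to machine precision", {
  pop <- fixed_design_population(n = 50)
  reg <- registry_equation("beech_1")
  rec <- basic_recovery(reg$equation, pop, reg$fit,
                        recovery_config(B = 1, seed = 9))
  # independent route: hand-rolled normal equations on the same trees
  X <- cbind(pop$dbh_cm^2, sqrt(pop$dbh_cm * pop$ht_m))
  pred <- X %*% c(0.901, -6.382)
  s2 <- var(as.vector(pred)) * (1 / 0.96 - 1)
  expect_equal(rec$cov, s2 * solve(t(X) %*% X), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rec$sigma2_resid, s2, tolerance = 1e-12)
})

test_that("orthonormal single-coefficient design returns the residual
           variance itself", {
  eq <- single_coef_equation(b1 = 2)
  x <- c(0.3, 0.5, sqrt(1 - 0.09 - 0.25))   # sum(x^2) = 1
  pop <- data.frame(species = "t", dbh_cm = x)
  fit <- fit_stats(n = 3, r_squared = 0.8)
  rec <- basic_recovery(eq, pop, fit, recovery_config(B = 1, n = 3, seed = 1))
  s2 <- var(2 * x) * (1 / 0.8 - 1)
  expect_equal(drop(rec$cov), s2, tolerance = 1e-12)
})

test_that("recovery refuses non-recoverable generalized equations", {
  pop <- beech_population(500)
  gen <- registry_equation("beech_generalized_13")
  expect_error(basic_recovery(gen$equation, pop, gen$fit,
                              recovery_config(B = 2, seed = 1)),
               "non-recoverable")
})

test_that("recovery validates sample sizes", {
  reg <- registry_equation("beech_1")
  pop <- beech_population(30)
  expect_error(basic_recovery(reg$equation, pop, reg$fit,
                              recovery_config(B = 2, seed = 1)),
               "smaller than the fitting sample")
  expect_error(basic_recovery(reg$equation, pop, reg$fit,
                              recovery_config(B = 2, n = 2, seed = 1)),
               "must exceed")
})

test_that("weighted recovery normalizes inverse-DBH^2 weights within
           each replicate", {
  # equal diameters: W = I/n, so the weighted covariance is n times the
  # unweighted one
  eq <- biomass_equation("wt", "linear-in-basis", c(0.9, -6),
                         basis = c("dbh2", "sqrt_dbh_ht"),
                         weight_rule = "inverse-dbh-squared")
  pop <- data.frame(species = "t", dbh_cm = rep(30, 10),
                    ht_m = seq(10, 28, by = 2))
  fit <- fit_stats(n = 10, r_squared = 0.9)
  w <- weighted_recovery(eq, pop, fit, recovery_config(B = 1, seed = 2))
  eq_u <- eq; eq_u$weight_rule <- "none"
  b <- basic_recovery(eq_u, pop, fit, recovery_config(B = 1, seed = 2))
  expect_equal(w$cov, 10 * b$cov, tolerance = 1e-10)
  # unweighted equations refuse the weighted path
  expect_error(weighted_recovery(eq_u, pop, fit,
                                 recovery_config(B = 1, seed = 2)),
               "no weighting rule")
})

test_that("weighted recovery matches a hand-built two-tree weight vector", {
  # diameters 10 and 20 cm: unnormalized 1/DBH^2 weights (1/100, 1/400)
  # normalize to (0.8, 0.2)
  eq <- biomass_equation("wt1", "linear-in-basis", 2, basis = "dbh",
                         weight_rule = "inverse-dbh-squared")
  pop <- data.frame(species = "t", dbh_cm = c(10, 20))
  fit <- fit_stats(n = 2, r_squared = 0.9)
  rec <- weighted_recovery(eq, pop, fit, recovery_config(B = 1, seed = 3))
  s2 <- var(2 * c(10, 20)) * (1 / 0.9 - 1)
  expect_equal(drop(rec$cov), s2 / (0.8 * 100 + 0.2 * 400),
               tolerance = 1e-12)
})

test_that("gamma shape solves the first-order variance identity", {
  expect_equal(solve_gamma_nu(2, 1, 2), 5)
  expect_error(solve_gamma_nu(2, 1, 1), "no real-valued solution")
  expect_error(solve_gamma_nu(2, 0, 1), "positive")
  # variance of the multiplicative error vanishes as the target variance
  # approaches the prediction variance from above
  expect_gt(solve_gamma_nu(2, 1, 1 + 1e-10), 1e9)
  # Monte-Carlo check of the identity at nu = 5
  set.seed(11)
  yhat <- c(2, 5, 9, 14, 20)
  n <- 2e5
  e <- rgamma(n * length(yhat), shape = 5, rate = 5)
  v_emp <- var(rep(yhat, each = n) * e)
  m <- mean(yhat)
  v_pred <- mean((yhat - m)^2)
  expect_equal(v_emp, v_pred + (m^2 + v_pred) / 5, tolerance = 0.02)
})

test_that("robust recovery needs at least 3 t degrees of freedom", {
  eq <- single_coef_equation()
  pop <- data.frame(species = "t", dbh_cm = 1:10)
  expect_error(robust_recovery(eq, pop, fit_stats(5, 0.9),
                               recovery_config(B = 2, seed = 1)),
               "at least 3")
  # n = 6 gives df = 3 and runs
  rec <- robust_recovery(eq, pop, fit_stats(6, 0.9),
                         recovery_config(B = 5, seed = 1))
  expect_s3_class(rec, "recovered_stats")
  expect_true(all(is.finite(rec$cov)))
})

test_that("refit recovery returns the exact coefficients and zero
           covariance in the noiseless limit", {
  pop <- fixed_design_population(n = 40)
  reg <- registry_equation("beech_1")
  rec <- refit_recovery(reg$equation, pop, fit_stats(40, 1),
                        recovery_config(B = 3, n = 40, seed = 2))
  expect_equal(rec$sigma2_resid, 0)
  expect_equal(max(abs(rec$cov)), 0, tolerance = 1e-16)
  expect_equal(rec$n_fallback, 0L)
})

test_that("gamma fallback never triggers when predictions sit far from zero", {
  set.seed(21)
  pop <- data.frame(species = "t", dbh_cm = runif(200, 40, 60),
                    ht_m = runif(200, 25, 35))
  reg <- registry_equation("beech_1")
  rec <- refit_recovery(reg$equation, pop, fit_stats(50, 0.995),
                        recovery_config(B = 100, seed = 4))
  expect_equal(rec$n_fallback, 0L)
})

test_that("refit recovery of a nonlinear equation stays close to the
           basic matrix on a fixed design", {
  pop <- fixed_design_population(n = 30)
  reg <- registry_equation("beech_2")   # nested-square form
  fit <- fit_stats(30, 0.98)
  bas <- basic_recovery(reg$equation, pop, fit,
                        recovery_config(B = 1, seed = 1))
  ref <- refit_recovery(reg$equation, pop, fit,
                        recovery_config(B = 400, seed = 1))
  expect_equal(ref$cov / bas$cov, matrix(1, 2, 2), tolerance = 0.25,
               ignore_attr = TRUE)
})

test_that("Monte-Carlo error monitor computes the relative standard error
           of the mean determinant", {
  expect_equal(mc_error_monitor(c(1, 1, 1, 3)), 100 * 0.5 / 1.5)
  expect_equal(mc_error_monitor(rep(2.5, 10)), 0)
  expect_error(mc_error_monitor(1), "at least two")
  expect_error(mc_error_monitor(c(-1, 1)), "zero")
})

test_that("off-diagonal recovery reproduces the correlation-times-SE
           construction", {
  # perfectly collinear gradient components: ht proportional to dbh^2
  eq <- registry_equation("beech_2")$equation
  trees <- data.frame(dbh_cm = c(10, 20, 30, 40),
                      ht_m = c(10, 20, 30, 40)^2 / 50)
  V <- offdiagonal_recovery(eq, trees, coef_se = c(0.5, 3))
  expect_equal(V[1, 2], 0.5 * 3, tolerance = 1e-8)
  expect_equal(diag(V), c(0.25, 9), tolerance = 1e-8)

  # orthogonal components give a diagonal matrix
  eq2 <- biomass_equation("orth", "linear-in-basis", c(1, 1),
                          basis = c("dbh", "sqrt_ht"))
  trees2 <- data.frame(dbh_cm = c(1, 1, 2, 2), ht_m = c(1, 4, 4, 1))
  V2 <- offdiagonal_recovery(eq2, trees2, coef_se = c(1, 2))
  expect_equal(V2, diag(c(1, 4)), tolerance = 1e-12, ignore_attr = TRUE)

  # constant gradient component: correlation undefined
  eq3 <- biomass_equation("const", "linear-in-basis", c(1, 1),
                          basis = c("intercept", "dbh"))
  expect_error(offdiagonal_recovery(eq3, trees2, coef_se = c(1, 1)),
               "constant")
  # robust variant is deterministic per seed and still PSD
  V4 <- offdiagonal_recovery(eq, beech_population(50), coef_se = c(0.05, 3),
                             robust = TRUE, seed = 8)
  expect_identical(V4, offdiagonal_recovery(eq, beech_population(50),
                                            coef_se = c(0.05, 3),
                                            robust = TRUE, seed = 8))
  expect_symmetric_psd(matrix(V4, 2, 2))
})

test_that("recovered covariance matrices are symmetric PSD and the run is
           reproducible byte for byte", {
  pop <- beech_population(1500)
  reg <- registry_equation("beech_1")
  cfg <- recovery_config(B = 40, seed = 123)
  for (fun in list(basic_recovery, refit_recovery, robust_recovery)) {
    a <- fun(reg$equation, pop, reg$fit, cfg)
    b <- fun(reg$equation, pop, reg$fit, cfg)
    expect_identical(a, b)
    expect_symmetric_psd(a$cov)
    expect_gt(a$sigma2_resid, 0)
  }
})

test_that("enlarging B leaves earlier replicate draws unchanged", {
  pop <- beech_population(1500)
  reg <- registry_equation("beech_1")
  small <- basic_recovery(reg$equation, pop, reg$fit,
                          recovery_config(B = 10, seed = 55))
  large <- basic_recovery(reg$equation, pop, reg$fit,
                          recovery_config(B = 20, seed = 55))
  # the B=10 average is recoverable from the B=20 run only if the first
  # ten substreams are identical; check via a third run at B=10 after an
  # unrelated RNG disturbance
  set.seed(9999); rnorm(100)
  again <- basic_recovery(reg$equation, pop, reg$fit,
                          recovery_config(B = 10, seed = 55))
  expect_identical(small, again)
  expect_false(identical(small$cov, large$cov))
})
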
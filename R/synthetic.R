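# Seeded synthetic inventory populations and the fit-hide-recover-compare
# validation experiment.
#
# Tree diameters are drawn from a lognormal (default) or gamma
# distribution moment-matched to a requested mean and SD; heights, when
# requested, are coupled to diameter through a bivariate normal on the log
# scale with a configurable log-scale correlation (default 0.7, a typical
# inventory DBH-height association).  An optional AGB field is produced by
# pushing the generated trees through a biomass equation and multiplying
# by uniform noise on [0.9, 1.1] — the error model behind the German
# calibration data.  Everything is deterministic for a fixed seed.

#' Specification of a synthetic inventory population
#'
#' @param species Species label.
#' @param n_trees Number of trees to generate.
#' @param dbh_mean,dbh_sd Target mean and SD of DBH (cm).
#' @param ht_mean,ht_sd Optional target mean and SD of height (m); omit
#'   both for a diameter-only population.
#' @param dbh_ht_corr Log-scale correlation between DBH and height in
#'   [-1, 1] (default 0.7).
#' @param dbh_family `"lognormal"` (default) or `"gamma"`; the DBH marginal
#'   is moment-matched within the chosen family (the gamma variant draws
#'   through a Gaussian copula so the height coupling is preserved).
#' @param agb_rule `"none"` or `"equation-times-uniform-noise"`; the latter
#'   requires `equation` and adds an `agb_kg` column equal to the equation
#'   prediction times independent uniform noise on `noise_interval`.
#' @param noise_interval Two-element interval for the multiplicative noise
#'   (default `c(0.9, 1.1)`).
#' @param equation Optional [biomass_equation()] for the AGB rule.
#' @param seed Integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(species, n_trees, dbh_mean, dbh_sd,
                            ht_mean = NULL, ht_sd = NULL,
                            dbh_ht_corr = 0.7,
                            dbh_family = c("lognormal", "gamma"),
                            agb_rule = c("none",
                                         "equation-times-uniform-noise"),
                            noise_interval = c(0.9, 1.1),
                            equation = NULL, seed = 1L) {
  dbh_family <- match.arg(dbh_family)
  agb_rule <- match.arg(agb_rule)
  if (n_trees < 1L) stop("'n_trees' must be positive")
  if (dbh_mean <= 0 || dbh_sd <= 0)
    stop("DBH moments must be positive")
  if (xor(is.null(ht_mean), is.null(ht_sd)))
    stop("supply both or neither of 'ht_mean' and 'ht_sd'")
  if (!is.null(ht_mean) && (ht_mean <= 0 || ht_sd <= 0))
    stop("height moments must be positive")
  if (abs(dbh_ht_corr) > 1) stop("'dbh_ht_corr' must lie in [-1, 1]")
  if (agb_rule == "equation-times-uniform-noise" && is.null(equation))
    stop("the AGB rule requires an 'equation'")
  if (length(noise_interval) != 2L || diff(noise_interval) < 0)
    stop("'noise_interval' must be an increasing length-2 interval")
  structure(list(species = as.character(species),
                 n_trees = as.integer(n_trees),
                 dbh_mean = dbh_mean, dbh_sd = dbh_sd,
                 ht_mean = ht_mean, ht_sd = ht_sd,
                 dbh_ht_corr = dbh_ht_corr, dbh_family = dbh_family,
                 agb_rule = agb_rule, noise_interval = noise_interval,
                 equation = equation, seed = as.integer(seed)),
            class = "population_spec")
}

# Lognormal parameters matching a mean/SD pair.
.lnorm_pars <- function(m, s) {
  s2 <- log(1 + (s / m)^2)
  list(mu = log(m) - s2 / 2, sigma = sqrt(s2))
}

#' Generate a synthetic inventory population
#'
#' @param spec A [population_spec()].
#' @return Data.frame with columns `species`, `dbh_cm`, optionally `ht_m`
#'   and `agb_kg`.
#' @export
#' @examples
#' pop <- generate_population(population_spec("BEECH", 1000, 35, 15, 25, 7,
#'                                            seed = 42))
#' summary(pop$dbh_cm)
generate_population <- function(spec) {
  if (!inherits(spec, "population_spec"))
    stop("'spec' must be a population_spec")
  set.seed(spec$seed)
  n <- spec$n_trees
  z1 <- stats::rnorm(n)
  dbh <- if (spec$dbh_family == "lognormal") {
    p <- .lnorm_pars(spec$dbh_mean, spec$dbh_sd)
    exp(p$mu + p$sigma * z1)
  } else {
    shape <- (spec$dbh_mean / spec$dbh_sd)^2
    rate <- spec$dbh_mean / spec$dbh_sd^2
    stats::qgamma(stats::pnorm(z1), shape = shape, rate = rate)
  }
  out <- data.frame(species = spec$species, dbh_cm = dbh,
                    stringsAsFactors = FALSE)
  if (!is.null(spec$ht_mean)) {
    rho <- spec$dbh_ht_corr
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    ph <- .lnorm_pars(spec$ht_mean, spec$ht_sd)
    out$ht_m <- exp(ph$mu + ph$sigma * z2)
  }
  if (spec$agb_rule == "equation-times-uniform-noise") {
    u <- stats::runif(n, spec$noise_interval[1], spec$noise_interval[2])
    out$agb_kg <- predict_agb(spec$equation, out) * u
  }
  out
}

#' Draw an inventory sample from a population
#'
#' Without-replacement sample of n trees, either with equal probability or
#' with probability proportional to basal area at breast height (PPS,
#' inclusion weight proportional to DBH^2) — the selection rule of
#' angle-count inventory sampling.
#'
#' @param population Data.frame of trees (needs `dbh_cm` for PPS).
#' @param n Sample size (<= population size).
#' @param pps_by_basal_area Logical; PPS-by-DBH^2 selection.
#' @param seed Optional integer seed.
#' @return Data.frame of n sampled trees.
#' @export
sample_inventory <- function(population, n, pps_by_basal_area = FALSE,
                             seed = NULL) {
  N <- nrow(population)
  if (n > N) stop("sample size n = ", n, " exceeds population size ", N)
  if (!is.null(seed)) set.seed(as.integer(seed))
  prob <- if (pps_by_basal_area) population$dbh_cm^2
  idx <- sample.int(N, n, prob = prob)
  population[idx, , drop = FALSE]
}

#' Simulate the "actual" fit of a biomass equation
#'
#' Draws n trees from the population, simulates responses from the
#' equation under a chosen noise model, refits the equation by least
#' squares and returns the refitted coefficients together with the
#' textbook covariance matrix and fit statistics — the ground truth that a
#' recovery procedure then has to approximate from (n, R-squared) alone.
#'
#' Noise models: `"uniform-multiplicative"` multiplies the prediction by
#' U[1 - halfwidth, 1 + halfwidth] (heteroscedastic, the German
#' calibration model); `"additive"` adds N(0, sd) noise on the fitted
#' scale; `"none"` gives an exact fit (R-squared 1, zero covariance).
#'
#' @param eq A [biomass_equation()].
#' @param population Data.frame of trees.
#' @param n Fitting sample size (> q).
#' @param noise List with `type` and `halfwidth` or `sd`.
#' @param seed Integer seed.
#' @param weighted Logical; fit by weighted least squares using the
#'   equation's weighting rule.
#' @return List with `coefficients`, `cov` (actual covariance), `sigma2`,
#'   `fit` (a [fit_stats()]), and `trees_idx` (row indices of the fitting
#'   trees, for exclusion from subsequent recovery draws).
#' @export
simulate_actual_fit <- function(eq, population, n,
                                noise = list(type = "uniform-multiplicative",
                                             halfwidth = 0.1),
                                seed = 1L, weighted = FALSE) {
  q <- length(eq$coefficients)
  if (n <= q) stop("n must exceed the number of parameters q = ", q)
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(population), n)
  trees <- population[idx, , drop = FALSE]
  link <- predict(eq, trees, type = "link")
  y <- switch(noise$type,
    "uniform-multiplicative" = {
      h <- if (is.null(noise$halfwidth)) 0.1 else noise$halfwidth
      if (eq$scale == "log")
        stop("multiplicative uniform noise applies to identity-scale ",
             "equations; use additive noise on the log scale instead")
      link * stats::runif(n, 1 - h, 1 + h)
    },
    "additive" = link + stats::rnorm(n, 0, noise$sd),
    "none" = link,
    stop("unknown noise type '", noise$type, "'"))
  w <- if (weighted) {
    wr <- 1 / trees$dbh_cm^2
    wr / sum(wr)
  }
  fitb <- .fit_equation(eq, trees, y, weights = w)
  list(coefficients = fitb$coefficients, cov = fitb$cov,
       sigma2 = fitb$sigma2,
       fit = fit_stats(n = n, r_squared = min(fitb$r_squared, 1),
                       residual_sd = sqrt(max(fitb$sigma2, 0))),
       trees_idx = idx)
}

#' Fit-hide-recover-compare validation experiment
#'
#' Runs the full validation design on a synthetic population: simulate an
#' "actual" fit on n randomly drawn trees, hide its covariance matrix,
#' recover substitutes from (n, R-squared) with the requested methods on
#' the remaining trees, test each substitute against the actual matrix
#' with Box's M, and propagate each matrix to the relative model error of
#' the mean per-tree AGB.
#'
#' @param population Data.frame of trees, or a [population_spec()].
#' @param eq A [biomass_equation()] (its stored coefficients define the
#'   generating model).
#' @param n_fit Fitting sample size (default 50).
#' @param B Recovery replicates per method (default 800).
#' @param methods Character subset of `c("basic", "refit", "robust")`.
#' @param weighted Logical; weighted fitting and recovery.
#' @param noise Noise model passed to [simulate_actual_fit()].
#' @param seed Integer root seed.
#' @return A list of class `validation_outcome` with components
#'   `actual_cov`, `actual_sigma2`, `fit`, `recovered` (per-method
#'   `recovered_stats`), `mtests` (per-method [box_m_test()] results) and
#'   `relative_errors` (per-method percent error of the mean per-tree AGB,
#'   with `actual` as reference).
#' @export
validation_experiment <- function(population, eq, n_fit = 50L, B = 800L,
                                  methods = c("basic", "refit", "robust"),
                                  weighted = FALSE,
                                  noise = list(
                                    type = "uniform-multiplicative",
                                    halfwidth = 0.1),
                                  seed = 1L) {
  if (inherits(population, "population_spec"))
    population <- generate_population(population)
  methods <- match.arg(methods, several.ok = TRUE)
  actual <- simulate_actual_fit(eq, population, n_fit, noise = noise,
                                seed = seed, weighted = weighted)
  pool <- population[-actual$trees_idx, , drop = FALSE]
  recovered <- list()
  for (i in seq_along(methods)) {
    m <- methods[i]
    cfg <- recovery_config(B = B, method = m, weighted = weighted,
                           seed = .replicate_seed(seed, 0L, i))
    recovered[[m]] <- switch(m,
      basic  = basic_recovery(eq, pool, actual$fit, cfg),
      refit  = refit_recovery(eq, pool, actual$fit, cfg),
      robust = robust_recovery(eq, pool, actual$fit, cfg))
  }
  # a noiseless scenario yields exactly-zero matrices whose
  # log-determinants (hence Box's M) are undefined
  mtests <- lapply(recovered, function(r)
    tryCatch(box_m_test(list(actual$cov, r$cov), c(n_fit, n_fit)),
             error = function(e) NA))
  mean_pred <- mean(predict_agb(eq, pool))
  rel_err <- function(sigma2, cov) {
    v <- species_mean_error_variance(
      eq, pool, list(sigma2_resid = sigma2, cov = cov))
    if (eq$scale == "log") log_scale_relative_error(v)
    else relative_error(mean_pred, v)
  }
  rels <- c(actual = rel_err(actual$sigma2, actual$cov),
            vapply(recovered, function(r) rel_err(r$sigma2_resid, r$cov),
                   numeric(1)))
  structure(list(actual_cov = actual$cov, actual_sigma2 = actual$sigma2,
                 fit = actual$fit, recovered = recovered, mtests = mtests,
                 relative_errors = rels, seed = as.integer(seed)),
            class = "validation_outcome")
}

#' @export
print.validation_outcome <- function(x, ...) {
  cat("Validation experiment (actual fit: n =", x$fit$n, ", R^2 =",
      signif(x$fit$r_squared, 4), ")\n")
  cat("  actual covariance:\n"); print(signif(x$actual_cov, 4))
  for (m in names(x$recovered)) {
    mt <- x$mtests[[m]]
    pv <- if (inherits(mt, "box_m_test")) signif(mt$p_value, 3) else NA
    cat("  ", m, ": Box-M p = ", pv,
        ", relative error = ", signif(x$relative_errors[[m]], 3),
        "%\n", sep = "")
  }
  cat("  relative error with actual matrix:",
      signif(x$relative_errors[["actual"]], 3), "%\n")
  invisible(x)
}
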
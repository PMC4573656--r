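# Recovery of missing fit statistics.
#
# Given only a published sample size n and coefficient of determination R^2,
# a substitute residual variance and parameter covariance matrix are
# recovered by repeatedly drawing size-n samples of the explanatory
# variables from the inventory population targeted for biomass estimation.
# Per resample b:
#   sigma2_b = V(f(x_b | b_hat)) * (1/R^2 - 1)          (V with denominator n-1)
#   cov_b    = sigma2_b * (F_b' F_b)^-1                  (basic)
#            = sigma2_b * (F_b' W F_b)^-1                (weighted, sum-to-one W)
#            = (F'F)^-1 (sum e_i^2 g_i g_i') (F'F)^-1    (robust sandwich,
#                e_i ~ t(floor(n/2)) scaled to variance sigma2_b)
#            = textbook covariance of a least-squares refit to pseudo-data
#              y* = f + sigma_b * t(n - q)               (refit bootstrap)
# and the average over B replicates is returned.  Replicate substreams are
# seeded deterministically from the root seed so enlarging B never
# reshuffles earlier replicates.

.replicate_seed <- function(seed, b, attempt = 0L) {
  x <- (as.numeric(seed) %% 2147483 + 1) * 997 + 1000003 * as.numeric(b) +
    7919 * as.numeric(attempt)
  as.integer(x %% 2147483647)
}

# (X' W X)^-1 for a diagonal weight vector w (or NULL), via QR.
.xtwx_inverse <- function(X, w = NULL) {
  Xw <- if (is.null(w)) X else sqrt(w) * X
  R <- qr.R(qr(Xw))
  if (any(abs(diag(R)) < .Machine$double.eps * 1e3 * max(abs(diag(R)))))
    stop("singular design: F'F (or F'WF) is not invertible")
  chol2inv(R)
}

# Symmetrize and clip negative eigenvalues to zero.  Returns the repaired
# matrix plus a flag indicating whether a repair was necessary.
.psd_repair <- function(M, tol = 1e-12) {
  S <- (M + t(M)) / 2
  repaired <- max(abs(M - t(M))) > tol * max(1, max(abs(M)))
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -tol * max(abs(ev$values), 1)) {
    repaired <- TRUE
    v <- pmax(ev$values, 0)
    S <- ev$vectors %*% (v * t(ev$vectors))
    S <- (S + t(S)) / 2
  }
  list(mat = S, repaired = repaired)
}

# Sum-to-one inverse-DBH^2 weights for a replicate sample.
.recovery_weights <- function(eq, trees) {
  if (eq$weight_rule == "none")
    stop("equation '", eq$name, "' carries no weighting rule; ",
         "use basic_recovery() or set a weight_rule on the equation")
  w <- 1 / trees$dbh_cm^2
  w / sum(w)
}

#' Recover the residual variance from predictions and R-squared
#'
#' Computes the substitute residual variance
#' \eqn{\tilde\sigma^2_e = V(f(x | \hat b)) (1/R^2 - 1)}, where `V` is the
#' sample variance (denominator n - 1) of the fitted-scale predictions over
#' the supplied trees.  For a log-linear equation the predictions — and
#' hence the recovered variance — are on the log scale.
#'
#' @param eq A [biomass_equation()].
#' @param trees Data.frame of at least two trees.
#' @param r_squared Published coefficient of determination in (0, 1].
#' @return The recovered residual variance (fitted scale).
#' @export
#' @examples
#' eq <- registry_equation("beech_1")$equation
#' trees <- data.frame(dbh_cm = c(20, 35, 50), ht_m = c(18, 25, 30))
#' recover_residual_variance(eq, trees, r_squared = 0.96)
recover_residual_variance <- function(eq, trees, r_squared) {
  if (!is.numeric(r_squared) || r_squared <= 0 || r_squared > 1)
    stop("'r_squared' must lie in (0, 1]")
  if (nrow(trees) < 2L)
    stop("at least two trees are required to estimate a prediction variance")
  v <- stats::var(predict(eq, trees, type = "link"))
  if (v == 0)
    stop("degenerate sample: all trees give identical predictions")
  v * (1 / r_squared - 1)
}

#' Configuration of a recovery run
#'
#' @param B Number of resampling replicates (default 800, at which the
#'   Monte-Carlo error in the determinant of the recovered covariance is
#'   typically below 4 percent).
#' @param n Fitting sample size to emulate; defaults to the published `n`
#'   of the fit statistics when omitted.
#' @param method `"basic"`, `"refit"` or `"robust"`.
#' @param weighted Logical; apply the equation's weighting rule.
#' @param seed Integer root seed; replicate substreams are derived from it
#'   deterministically.
#' @param max_redraws Maximum redraw attempts per replicate on a singular
#'   design or a failed refit.
#' @return An object of class `recovery_config`.
#' @export
recovery_config <- function(B = 800L, n = NULL, method = c("basic", "refit",
                                                           "robust"),
                            weighted = FALSE, seed = 1L, max_redraws = 10L) {
  method <- match.arg(method)
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("'B' must be a positive integer")
  structure(list(B = B, n = if (!is.null(n)) as.integer(n), method = method,
                 weighted = isTRUE(weighted), seed = as.integer(seed),
                 max_redraws = as.integer(max_redraws)),
            class = "recovery_config")
}

# Container for recovered statistics.
.recovered_stats <- function(sigma2, cov, B, dets, method, weighted,
                             repaired, n_redraws, n_fallback, seed) {
  mc <- if (length(dets) >= 2L && mean(dets) != 0)
    mc_error_monitor(dets) else 0
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  cond <- if (min(ev) > 0) max(ev) / min(ev) else Inf
  structure(list(sigma2_resid = sigma2, cov = cov, B_used = B,
                 mc_error_det_pct = mc, method = method, weighted = weighted,
                 condition_number = cond, n_repairs = as.integer(repaired),
                 n_redraws = as.integer(n_redraws),
                 n_fallback = as.integer(n_fallback),
                 seed = as.integer(seed)),
            class = "recovered_stats")
}

#' @export
print.recovered_stats <- function(x, ...) {
  cat("Recovered fit statistics (", x$method,
      if (x$weighted) ", weighted" else "", ", B = ", x$B_used, ")\n",
      sep = "")
  cat("  residual variance (fitted scale):", signif(x$sigma2_resid, 6), "\n")
  cat("  covariance matrix:\n")
  print(signif(x$cov, 4))
  cat("  MC error of determinant:", signif(x$mc_error_det_pct, 3), "%\n")
  cat("  condition number:", signif(x$condition_number, 4),
      " PSD repairs:", x$n_repairs, "\n")
  invisible(x)
}

# Shared replicate loop.  `replicate_fun(trees_b, sigma2_b, seed_b)` returns
# a list(cov=, fallback=logical) for one replicate.
.recovery_loop <- function(eq, population, fit, cfg, replicate_fun) {
  if (!inherits(eq, "biomass_equation")) stop("'eq' must be a biomass_equation")
  if (!eq$recoverable)
    stop("equation '", eq$name, "' is flagged non-recoverable: its ",
         "published fit statistics describe a generalized model set and ",
         "are incompatible with covariance recovery")
  if (!inherits(fit, "fit_stats")) stop("'fit' must be a fit_stats object")
  n <- if (!is.null(cfg$n)) cfg$n else fit$n
  q <- length(eq$coefficients)
  if (n <= q) stop("fitting sample size n = ", n,
                   " must exceed the number of parameters q = ", q)
  N <- nrow(population)
  if (N < n)
    stop("population (", N, " trees) is smaller than the fitting sample ",
         "size n = ", n)
  B <- cfg$B
  covs <- vector("list", B)
  s2 <- dets <- numeric(B)
  n_redraws <- n_fallback <- 0L
  for (b in seq_len(B)) {
    done <- FALSE
    for (attempt in 0:cfg$max_redraws) {
      seed_b <- .replicate_seed(cfg$seed, b, attempt)
      set.seed(seed_b)
      idx <- sample.int(N, n)
      trees_b <- population[idx, , drop = FALSE]
      res <- tryCatch({
        sigma2_b <- recover_residual_variance(eq, trees_b, fit$r_squared)
        replicate_fun(trees_b, sigma2_b, seed_b)
      }, error = function(e) e)
      if (!inherits(res, "error")) {
        covs[[b]] <- res$cov
        s2[b] <- res$sigma2
        dets[b] <- det(res$cov)
        if (isTRUE(res$fallback)) n_fallback <- n_fallback + 1L
        done <- TRUE
        break
      }
      n_redraws <- n_redraws + 1L
    }
    if (!done)
      stop("replicate ", b, " failed after ", cfg$max_redraws,
         " redraws: ", conditionMessage(res))
  }
  if (n_redraws > 0.05 * B)
    stop("more than 5% of replicates required redraws (", n_redraws,
         " of ", B, "); the recovery is unreliable for this configuration")
  cov_mean <- Reduce(`+`, covs) / B
  rep_res <- .psd_repair(cov_mean)
  .recovered_stats(mean(s2), rep_res$mat, B, dets, cfg$method, cfg$weighted,
                   rep_res$repaired, n_redraws, n_fallback, cfg$seed)
}

#' Basic recovery of a missing covariance matrix
#'
#' For each of B replicates, draws n trees without replacement from the
#' inventory population, recovers the residual variance from the published
#' R-squared ([recover_residual_variance()]) and forms the textbook
#' covariance \eqn{\tilde\sigma^2_b (F_b' F_b)^{-1}} on that sample; the
#' replicate averages of the residual variance and covariance matrix are
#' returned.
#'
#' @param eq A recoverable [biomass_equation()].
#' @param population Data.frame of inventory trees from the population
#'   targeted for biomass estimation (trees used to fit the equation, when
#'   known, should be excluded beforehand).
#' @param fit A [fit_stats()] with at least `n` and `r_squared`.
#' @param cfg A [recovery_config()].
#' @return A `recovered_stats` object.
#' @export
#' @examples
#' pop <- generate_population(population_spec("BEECH", 2000, 35, 15, 25, 7,
#'                                            seed = 1))
#' reg <- registry_equation("beech_1")
#' basic_recovery(reg$equation, pop, reg$fit,
#'                recovery_config(B = 50, seed = 1))
basic_recovery <- function(eq, population, fit,
                           cfg = recovery_config(method = "basic")) {
  cfg$method <- "basic"
  .recovery_loop(eq, population, fit, cfg, function(trees_b, sigma2_b, seed_b) {
    F <- gradient_matrix(eq, trees_b)
    w <- if (cfg$weighted) .recovery_weights(eq, trees_b)
    list(cov = sigma2_b * .xtwx_inverse(F, w), sigma2 = sigma2_b)
  })
}

#' Weighted recovery
#'
#' As [basic_recovery()] but with the weighted-least-squares covariance
#' \eqn{\tilde\sigma^2_b (F_b' W F_b)^{-1}}, where W is diagonal with
#' weights proportional to 1/DBH^2 (the equation's weighting rule),
#' normalized to sum to one within each replicate.
#'
#' @inheritParams basic_recovery
#' @return A `recovered_stats` object.
#' @export
weighted_recovery <- function(eq, population, fit,
                              cfg = recovery_config(method = "basic",
                                                    weighted = TRUE)) {
  cfg$weighted <- TRUE
  basic_recovery(eq, population, fit, cfg)
}

#' Robust (sandwich) recovery
#'
#' Per replicate, draws one residual per tree from a Student-t distribution
#' with floor(n/2) degrees of freedom, scaled so its distribution variance
#' equals the recovered residual variance, and forms the sandwich
#' \eqn{(F'F)^{-1} (\sum_i \tilde e_i^2 g_i g_i') (F'F)^{-1}}.  The modest
#' degrees of freedom give heavier-than-normal tails, reflecting the small
#' samples behind most published biomass equations.  With a weighted
#' configuration the bread is \eqn{(F'WF)^{-1}} and the meat
#' \eqn{\sum_i w_i^2 \tilde e_i^2 g_i g_i'}.
#'
#' @inheritParams basic_recovery
#' @return A `recovered_stats` object.
#' @export
robust_recovery <- function(eq, population, fit,
                            cfg = recovery_config(method = "robust")) {
  cfg$method <- "robust"
  n <- if (!is.null(cfg$n)) cfg$n else fit$n
  df <- floor(0.5 * n)
  if (df < 3L)
    stop("floor(0.5 n) = ", df, " degrees of freedom; at least 3 are ",
         "needed for the t-distribution to have a finite variance")
  .recovery_loop(eq, population, fit, cfg, function(trees_b, sigma2_b, seed_b) {
    F <- gradient_matrix(eq, trees_b)
    w <- if (cfg$weighted) .recovery_weights(eq, trees_b)
    e <- stats::rt(nrow(F), df) * sqrt(sigma2_b * (df - 2) / df)
    bread <- .xtwx_inverse(F, w)
    Fe <- if (is.null(w)) e * F else (w * e) * F
    meat <- crossprod(Fe)
    list(cov = bread %*% meat %*% bread, sigma2 = sigma2_b)
  })
}

#' Gamma shape parameter for multiplicative bootstrap residuals
#'
#' Solves the first-order variance identity
#' \eqn{V(\hat y e^*) = V(\hat y) + \nu^{-1}(\bar{\hat y}^2 + V(\hat y))}
#' for the shape \eqn{\nu} of a mean-one gamma(\eqn{\nu}, 1/\eqn{\nu})
#' multiplicative residual, so that predictions times gamma noise attain a
#' requested total variance.
#'
#' @param pred_mean Mean of the predictions.
#' @param pred_var Variance of the predictions (> 0).
#' @param target_var Requested variance of prediction-times-noise; must
#'   exceed `pred_var`, otherwise no real-valued solution exists.
#' @return The shape parameter \eqn{\nu}.
#' @export
#' @examples
#' solve_gamma_nu(pred_mean = 2, pred_var = 1, target_var = 2)  # 5
solve_gamma_nu <- function(pred_mean, pred_var, target_var) {
  if (!is.numeric(pred_var) || pred_var <= 0)
    stop("'pred_var' must be positive")
  if (!is.numeric(target_var) || target_var <= pred_var)
    stop("no real-valued solution: 'target_var' (", target_var,
         ") must exceed 'pred_var' (", pred_var, ")")
  (pred_mean^2 + pred_var) / (target_var - pred_var)
}

#' Recovery by refitting (parametric bootstrap)
#'
#' Per replicate, draws n trees from the population, forms pseudo-responses
#' \eqn{y^* = f(x | \hat b) + \tilde\sigma_b t_{n-q}} (t residuals with
#' scale \eqn{\tilde\sigma_b}, the recovered residual SD), refits the
#' equation by (iterative) least squares and records the textbook
#' covariance of the refit; the mean over B of those matrices is returned.
#' Should any pseudo-response of an identity-scale equation fall below
#' zero (biomass cannot be negative), the whole replicate instead uses
#' multiplicative mean-one gamma residuals \eqn{y^* = f \cdot e^*} with the
#' shape from [solve_gamma_nu()] chosen to match the same total variance.
#'
#' @inheritParams basic_recovery
#' @return A `recovered_stats` object; component `n_fallback` counts the
#'   replicates that used the multiplicative gamma fallback.
#' @export
refit_recovery <- function(eq, population, fit,
                           cfg = recovery_config(method = "refit")) {
  cfg$method <- "refit"
  q <- length(eq$coefficients)
  n <- if (!is.null(cfg$n)) cfg$n else fit$n
  df <- n - q
  if (df < 1L) stop("n - q degrees of freedom must be positive")
  .recovery_loop(eq, population, fit, cfg, function(trees_b, sigma2_b, seed_b) {
    pred <- predict(eq, trees_b, type = "link")
    e <- sqrt(sigma2_b) * stats::rt(length(pred), df)
    y <- pred + e
    fallback <- FALSE
    if (eq$scale == "identity" && any(y < 0) && sigma2_b > 0) {
      fallback <- TRUE
      nu <- solve_gamma_nu(mean(pred), stats::var(pred),
                           stats::var(pred) + sigma2_b)
      y <- pred * stats::rgamma(length(pred), shape = nu, rate = nu)
    }
    w <- if (cfg$weighted) .recovery_weights(eq, trees_b)
    fitb <- .fit_equation(eq, trees_b, y, weights = w)
    list(cov = fitb$cov, sigma2 = sigma2_b, fallback = fallback)
  })
}

#' Monte-Carlo error of the replicate-averaged determinant
#'
#' The relative standard error (in percent) of the B-average of the
#' per-replicate covariance determinants:
#' `100 * sd(det) / sqrt(B) / |mean(det)|`.  Used to judge whether B is
#' large enough; at B = 800 on typical inventory scenarios it stays below
#' 4 percent.
#'
#' @param dets Numeric vector of per-replicate determinants (length >= 2).
#' @return The Monte-Carlo error in percent.
#' @export
mc_error_monitor <- function(dets) {
  if (length(dets) < 2L) stop("at least two replicates are required")
  m <- mean(dets)
  if (m == 0) stop("mean determinant is zero; Monte-Carlo error undefined")
  100 * stats::sd(dets) / sqrt(length(dets)) / abs(m)
}

# Weighted Pearson correlation with normalized weights.
.weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0)
    stop("a gradient component is constant across trees; ",
         "its correlation with the others is undefined")
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Recover off-diagonal covariance elements from coefficient standard errors
#'
#' When published fit statistics include standard errors of the
#' coefficients but no covariances, the off-diagonal elements are
#' approximated by the correlation of the corresponding gradient components
#' across inventory trees times the geometric mean of the variances:
#' \eqn{cov(b_k, b_l) = corr(\partial f/\partial b_k, \partial f/\partial
#' b_l) \sqrt{var(b_k) var(b_l)}}.  With `robust = TRUE` the correlations
#' are weighted proportional to \eqn{1/|\tilde e_i|}, where the
#' \eqn{\tilde e_i} are Student-t draws with floor(n/2) degrees of freedom
#' (the weights are scale-free, so no residual variance is needed).
#'
#' @param eq A [biomass_equation()].
#' @param trees Data.frame of at least three inventory trees.
#' @param coef_se Positive vector of published coefficient standard errors
#'   (length q).
#' @param robust Logical; use residual-magnitude-weighted correlations.
#' @param seed Integer seed for the robust residual draws.
#' @return A q x q positive semi-definite covariance matrix (attribute
#'   `"repaired"` flags whether an eigenvalue clip was needed).
#' @export
offdiagonal_recovery <- function(eq, trees, coef_se, robust = FALSE,
                                 seed = 1L) {
  q <- length(eq$coefficients)
  if (length(coef_se) != q || any(coef_se <= 0))
    stop("'coef_se' must be ", q, " positive standard errors")
  if (nrow(trees) < 3L) stop("at least three trees are required")
  G <- gradient_matrix(eq, trees, check_rank = FALSE)
  n <- nrow(G)
  w <- if (robust) {
    set.seed(as.integer(seed))
    e <- stats::rt(n, max(floor(0.5 * n), 3L))
    1 / pmax(abs(e), .Machine$double.eps)
  } else rep(1, n)
  V <- diag(coef_se^2, q)
  for (k in seq_len(q - 1)) {
    for (l in (k + 1):q) {
      r <- max(-1, min(1, .weighted_cor(G[, k], G[, l], w)))
      V[k, l] <- V[l, k] <- r * coef_se[k] * coef_se[l]
    }
  }
  rep_res <- .psd_repair(V)
  out <- rep_res$mat
  attr(out, "repaired") <- rep_res$repaired
  out
}
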
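# Propagation of recovered (or published) fit statistics to model-error
# variances of tree-level, species-mean and per-hectare AGB estimates.
#
# The first-order (delta-method) variance of a single out-of-sample
# prediction is sigma_e^2 + g' cov(b) g with g the parameter gradient at
# the tree.  For the mean over n_s inventory trees of one species the
# residual term declines as 1/n_s while the parameter term is driven by
# the quadratic form in the average gradient.  Log-scale equations are
# propagated on the fitted (log) scale; to first order the SE of log-AGB
# is the relative SE of AGB.

# Accept either a recovered_stats object or a bare list(sigma2_resid, cov).
.stats_parts <- function(stats, q) {
  if (inherits(stats, "recovered_stats"))
    stats <- list(sigma2_resid = stats$sigma2_resid, cov = stats$cov)
  if (is.null(stats$sigma2_resid) || is.null(stats$cov))
    stop("'stats' must carry components 'sigma2_resid' and 'cov'")
  cov <- as.matrix(stats$cov)
  if (!all(dim(cov) == c(q, q)))
    stop("covariance matrix is ", nrow(cov), " x ", ncol(cov),
         " but the equation has q = ", q, " parameters")
  list(sigma2 = stats$sigma2_resid, cov = cov)
}

#' Model-error variance of a single-tree AGB prediction
#'
#' Computes \eqn{\tilde\sigma^2_e + g' \tilde{cov}(\hat b) g} with g the
#' parameter gradient at the tree.  For log-scale equations the result is
#' the variance of log(AGB) and carries attribute `log_scale = TRUE`.
#'
#' @param eq A [biomass_equation()].
#' @param tree One-row data.frame.
#' @param stats A `recovered_stats` object, or any list with components
#'   `sigma2_resid` and `cov` (e.g. published statistics).
#' @return Variance in kg^2 (identity scale) or log-scale variance.
#' @export
tree_error_variance <- function(eq, tree, stats) {
  p <- .stats_parts(stats, length(eq$coefficients))
  g <- gradient(eq, tree)
  v <- p$sigma2 + drop(t(g) %*% p$cov %*% g)
  attr(v, "log_scale") <- eq$scale == "log"
  v
}

#' Inventory panel for one species
#'
#' Bundles the inventory trees of one species with an optional stem-density
#' estimate (stems per hectare) and its variance, as needed for
#' per-hectare error propagation.
#'
#' @param species Species label.
#' @param trees Data.frame of the species' inventory trees.
#' @param stem_density Optional stems per hectare.
#' @param stem_density_var Optional variance of the stem-density estimate
#'   (requires `stem_density`).
#' @return An object of class `species_panel`.
#' @export
species_panel <- function(species, trees, stem_density = NULL,
                          stem_density_var = NULL) {
  if (!is.data.frame(trees) || nrow(trees) < 1L)
    stop("'trees' must be a data.frame with at least one tree")
  if (!is.null(stem_density_var) && is.null(stem_density))
    stop("'stem_density_var' requires 'stem_density'")
  if (!is.null(stem_density) && stem_density <= 0)
    stop("'stem_density' must be positive")
  if (!is.null(stem_density_var) && stem_density_var < 0)
    stop("'stem_density_var' must be non-negative")
  structure(list(species = as.character(species), trees = trees,
                 stem_density = stem_density,
                 stem_density_var = stem_density_var),
            class = "species_panel")
}

#' Model-error variance of a species-mean AGB estimate
#'
#' Computes \eqn{\tilde\sigma^2_e / n_s + \bar g' \tilde{cov}(\hat b) \bar
#' g}, where \eqn{\bar g} is the parameter gradient averaged over the
#' species' n_s inventory trees (average first, then quadratic form).  The
#' mathematically distinct average-of-quadratic-forms variant (mean over
#' trees of \eqn{g_j' cov\, g_j / n_s + ...}) is available with
#' `average = "quadratic"` but is not the default convention.
#'
#' @param eq A [biomass_equation()].
#' @param panel A [species_panel()] (or plain data.frame of trees).
#' @param stats As in [tree_error_variance()].
#' @param average `"gradient"` (default) or `"quadratic"`.
#' @return Variance of the species-mean AGB (kg^2, or log-scale).
#' @export
species_mean_error_variance <- function(eq, panel, stats,
                                        average = c("gradient",
                                                    "quadratic")) {
  average <- match.arg(average)
  trees <- if (inherits(panel, "species_panel")) panel$trees else panel
  p <- .stats_parts(stats, length(eq$coefficients))
  G <- gradient_matrix(eq, trees, check_rank = FALSE)
  ns <- nrow(G)
  term <- if (average == "gradient") {
    gbar <- colMeans(G)
    drop(t(gbar) %*% p$cov %*% gbar)
  } else {
    mean(rowSums((G %*% p$cov) * G))
  }
  v <- p$sigma2 / ns + term
  attr(v, "log_scale") <- eq$scale == "log"
  v
}

#' Model-error variance of a per-hectare AGB estimate
#'
#' Scales the species-mean model-error variance by the squared stem
#' density and adds the stem-density uncertainty under a zero-covariance
#' assumption: \eqn{\hat\lambda^2 V(\overline{AGB}) + \overline{AGB}^2
#' V(\hat\lambda)}.  Units are the caller's: with the mean in Mg and
#' density in stems per hectare the result is Mg^2 per hectare^2.
#'
#' @param mean_agb Species-mean AGB per tree.
#' @param mean_agb_var Variance of the species-mean AGB.
#' @param lambda_hat Stem density (stems per hectare).
#' @param lambda_var Variance of the stem-density estimate.
#' @return Per-hectare model-error variance.
#' @export
per_hectare_error_variance <- function(mean_agb, mean_agb_var, lambda_hat,
                                       lambda_var = 0) {
  vals <- c(mean_agb, mean_agb_var, lambda_hat, lambda_var)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all inputs must be finite and non-negative")
  lambda_hat^2 * mean_agb_var + mean_agb^2 * lambda_var
}

#' Combine per-species model-error variances
#'
#' Sums species-level variances under the assumption of independent model
#' errors across species.  This assumption fails when two species share a
#' single biomass equation — their model errors are then correlated — and
#' the function refuses such input.
#'
#' @param per_species_vars Numeric vector of non-negative variances.
#' @param shared_equation Logical; set `TRUE` when at least two of the
#'   species share one biomass equation.
#' @return The summed variance.
#' @export
combine_species <- function(per_species_vars, shared_equation = FALSE) {
  if (isTRUE(shared_equation))
    stop("species sharing one biomass equation have correlated model ",
         "errors; a plain sum of variances is not valid for that case")
  if (any(per_species_vars < 0)) stop("variances must be non-negative")
  sum(per_species_vars)
}

#' Relative error of an estimate
#'
#' @param estimate Positive point estimate.
#' @param variance Non-negative variance of the estimate.
#' @return `100 * sqrt(variance) / estimate`, in percent.
#' @export
relative_error <- function(estimate, variance) {
  if (!is.numeric(estimate) || estimate <= 0)
    stop("'estimate' must be positive")
  if (variance < 0) stop("'variance' must be non-negative")
  100 * sqrt(variance) / estimate
}

#' Relative error implied by a log-scale variance
#'
#' First-order (delta-method) conversion: the standard error of log(AGB)
#' approximates the relative standard error of AGB, so a log-scale
#' model-error variance v maps to a relative error of `100 * sqrt(v)`
#' percent on the natural scale.
#'
#' @param log_variance Non-negative variance on the log scale.
#' @return Relative error in percent.
#' @export
log_scale_relative_error <- function(log_variance) {
  if (log_variance < 0) stop("'log_variance' must be non-negative")
  100 * sqrt(log_variance)
}

#' Convert kilograms to megagrams
#' @param kg Mass in kg.
#' @return Mass in Mg (1 Mg = 1000 kg).
#' @export
kg_to_mg <- function(kg) kg / 1000

#' Convert megagrams to kilograms
#' @param mg Mass in Mg.
#' @return Mass in kg.
#' @export
mg_to_kg <- function(mg) mg * 1000
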
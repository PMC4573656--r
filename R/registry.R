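# Built-in registry of published biomass equations.
#
# German entries: four equations (linear / nested-square, unweighted /
# DBH^-2-weighted) per species group (BEECH, SPRUCE, PINE), each fitted to
# n = 50 trees from the 1987 West-German national inventory (BWI-1987),
# plus three generalized temperate-zone exp-ratio equations whose published
# fit statistics describe the set of generalizing models rather than a data
# fit — those are flagged non-recoverable.  Mexican entries: four log-log
# equations and three power equations with published R^2, residual SD and
# sample size.
#
# DBH is taken in cm and HT in m throughout: at the published BEECH
# inventory moments (DBH 35 cm, HT 25 m) the cm/m convention reproduces the
# published mean AGB of ~1.1 Mg per tree, whereas mm/dm would not.
# Published residual variances for the German equations are carried as
# metadata only (their units are ambiguous as printed).

.german_basis <- c("dbh2", "sqrt_dbh_ht")

.registry_build <- function() {
  ger <- function(name, form, b, r2, s2, weighted) {
    list(equation = biomass_equation(
           name, form, b,
           basis = if (form == "linear-in-basis") .german_basis,
           weight_rule = if (weighted) "inverse-dbh-squared" else "none",
           sigma2_printed = s2),
         fit = fit_stats(n = 50L, r_squared = r2))
  }
  gen <- function(name, b) {
    list(equation = biomass_equation(name, "exp-ratio", b,
                                     recoverable = FALSE),
         fit = fit_stats(n = 50L, r_squared = 0.99))
  }
  loglin <- function(name, b, basis, r2, sd, n) {
    list(equation = biomass_equation(name, "log-linear", b, basis = basis),
         fit = fit_stats(n = n, r_squared = r2, residual_sd = sd,
                         adjusted = TRUE))
  }
  pow <- function(name, b, r2, sd, n) {
    list(equation = biomass_equation(name, "power", b),
         fit = fit_stats(n = n, r_squared = r2, residual_sd = sd))
  }
  ll2 <- c("intercept", "log_dbh")
  list(
    beech_1  = ger("beech_1",  "linear-in-basis", c(0.901, -6.382), 0.96, 75.3, FALSE),
    beech_2  = ger("beech_2",  "nested-square",   c(9.645, -0.648), 0.95, 79.2, FALSE),
    beech_3  = ger("beech_3",  "linear-in-basis", c(0.887, -6.487), 0.96, 74.4, TRUE),
    beech_4  = ger("beech_4",  "nested-square",   c(10.127, -1.167), 0.95, 75.3, TRUE),
    spruce_5 = ger("spruce_5", "linear-in-basis", c(0.447, -1.189), 0.98, 18.7, FALSE),
    spruce_6 = ger("spruce_6", "nested-square",   c(0.634, -0.426), 0.98, 18.2, FALSE),
    spruce_7 = ger("spruce_7", "linear-in-basis", c(0.492, -1.409), 0.97, 19.0, TRUE),
    spruce_8 = ger("spruce_8", "nested-square",   c(0.689, -0.064), 0.97, 18.7, TRUE),
    pine_9   = ger("pine_9",   "linear-in-basis", c(0.450, -0.014), 0.98, 14.5, FALSE),
    pine_10  = ger("pine_10",  "linear-in-basis", c(0.658, -0.124), 0.98, 14.5, FALSE),
    pine_11  = ger("pine_11",  "linear-in-basis", c(0.479, -1.927), 0.97, 14.7, TRUE),
    pine_12  = ger("pine_12",  "linear-in-basis", c(0.690, -0.205), 0.97, 14.5, TRUE),
    beech_generalized_13  = gen("beech_generalized_13",
                                c(0.006, 10.933, 21.216)),
    spruce_generalized_14 = gen("spruce_generalized_14",
                                c(-1.694, 10.825, 11.816)),
    pine_generalized_15   = gen("pine_generalized_15",
                                c(-2.688, 10.745, 8.062)),
    guazuma_ulmifolia = loglin("guazuma_ulmifolia", c(-1.62, 2.12), ll2,
                               0.97, 0.48, 18L),
    inga_vera = loglin("inga_vera", c(-4.04, 4.00, -0.29),
                       c("intercept", "log_dbh", "log_dbh2"),
                       0.97, 0.39, 15L),
    ochroma_pyramidale = loglin("ochroma_pyramidale", c(-2.45, 2.30), ll2,
                                0.90, 0.96, 16L),
    trichospernum_mexicanum = loglin("trichospernum_mexicanum",
                                     c(-2.82, 2.42), ll2, 0.96, 0.40, 16L),
    quercus_castenea = pow("quercus_castenea", c(0.0416, 2.7154),
                           0.97, 11.6, 38L),
    quercus_latea    = pow("quercus_latea", c(0.0333, 2.6648),
                           0.92, 12.8, 7L),
    quercus_spp      = pow("quercus_spp", c(0.0342, 2.7590),
                           0.93, 15.7, 45L)
  )
}

#' Registry of published biomass equations
#'
#' Returns the built-in registry of published biomass equations: 15 German
#' species-group equations (12 locally fitted with n = 50; 3 generalized
#' temperate-zone equations flagged non-recoverable) and 7 Mexican species
#' equations with published R-squared, residual SD and sample size.
#'
#' @return Named list; each element is a list with components `equation`
#'   (a [biomass_equation()]) and `fit` (a [fit_stats()]).
#' @export
#' @examples
#' names(builtin_registry())
#' registry_equation("guazuma_ulmifolia")
builtin_registry <- function() .registry_build()

#' Look up a single registry entry
#'
#' @param name Registry name, e.g. `"beech_1"` or `"guazuma_ulmifolia"`.
#' @return A list with components `equation` and `fit`.
#' @rdname builtin_registry
#' @export
registry_equation <- function(name) {
  reg <- builtin_registry()
  if (!name %in% names(reg))
    stop("unknown equation '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}
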
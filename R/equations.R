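# Representation and evaluation of allometric biomass equations.
#
# An equation predicts above-ground biomass (AGB, kg) of a single tree from
# stem diameter at breast height (DBH, cm) and, for some forms, total height
# (HT, m).  Five functional forms are supported; log-scale equations predict
# log(AGB) and are back-transformed by exp() without a bias correction.

.EQ_FORMS <- c("linear-in-basis", "nested-square", "power", "log-linear",
               "exp-ratio")
.EQ_BASIS <- c("intercept", "dbh", "dbh2", "ht", "sqrt_ht", "sqrt_dbh_ht",
               "log_dbh", "log_dbh2")
.EQ_WEIGHTS <- c("none", "inverse-dbh-squared")

#' Construct a biomass equation
#'
#' Creates a `biomass_equation` object describing a fitted allometric model
#' for tree above-ground biomass (kg) as a function of stem diameter at
#' breast height (`dbh_cm`, cm) and, optionally, total height (`ht_m`, m).
#'
#' Supported functional forms:
#' \describe{
#'   \item{`linear-in-basis`}{\eqn{f = \sum_k b_k x_k} where the regressors
#'     \eqn{x_k} are transforms of DBH and HT named in `basis`.}
#'   \item{`nested-square`}{\eqn{f = (b_1 DBH + b_2 \sqrt{HT})^2}.}
#'   \item{`power`}{\eqn{f = b_1 DBH^{b_2}}.}
#'   \item{`log-linear`}{linear in `basis` on the log scale; predictions on
#'     the natural scale are `exp(link)` with no bias correction.}
#'   \item{`exp-ratio`}{\eqn{f = \exp(b_1 + b_2 DBH / (DBH + b_3))}, the
#'     generalized temperate-zone form.}
#' }
#'
#' @param name Character identifier.
#' @param form One of `"linear-in-basis"`, `"nested-square"`, `"power"`,
#'   `"log-linear"`, `"exp-ratio"`.
#' @param coefficients Numeric vector of fitted coefficients (length q),
#'   stored exactly as published.
#' @param basis Character vector of regressor transforms for the linear
#'   forms; one of `"intercept"`, `"dbh"`, `"dbh2"`, `"ht"`, `"sqrt_ht"`,
#'   `"sqrt_dbh_ht"`, `"log_dbh"`, `"log_dbh2"`.
#' @param scale `"identity"` or `"log"` — the scale on which the model was
#'   fitted.  `"log"` is implied by (and required for) `form = "log-linear"`.
#' @param weight_rule `"none"` or `"inverse-dbh-squared"` (weighted least
#'   squares with weights proportional to DBH^-2).
#' @param recoverable Logical; `FALSE` marks equations (e.g. generalized
#'   multi-study equations) whose published fit statistics are incompatible
#'   with covariance recovery.  Recovery functions refuse such equations.
#' @param sigma2_printed Optional published residual variance carried as
#'   metadata only (units as printed; not used in computations).
#'
#' @return An object of class `biomass_equation`.
#' @seealso [predict.biomass_equation()], [gradient_matrix()],
#'   [builtin_registry()]
#' @export
#' @examples
#' eq <- biomass_equation("beech_demo", "linear-in-basis",
#'                        c(0.901, -6.382), basis = c("dbh2", "sqrt_dbh_ht"))
#' predict(eq, data.frame(dbh_cm = 35, ht_m = 25))
biomass_equation <- function(name, form, coefficients, basis = NULL,
                             scale = c("identity", "log"),
                             weight_rule = c("none", "inverse-dbh-squared"),
                             recoverable = TRUE, sigma2_printed = NULL) {
  form <- match.arg(form, .EQ_FORMS)
  scale <- match.arg(scale)
  weight_rule <- match.arg(weight_rule)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 1L || anyNA(coefficients))
    stop("'coefficients' must be a numeric vector without NA")
  if (form %in% c("linear-in-basis", "log-linear")) {
    if (is.null(basis))
      stop("'basis' is required for form '", form, "'")
    basis <- match.arg(basis, .EQ_BASIS, several.ok = TRUE)
    if (length(basis) != length(coefficients))
      stop("for linear forms the basis (p = ", length(basis),
           ") must have one regressor per coefficient (q = ",
           length(coefficients), ")")
  } else {
    basis <- NULL
    nq <- c("nested-square" = 2L, "power" = 2L, "exp-ratio" = 3L)[[form]]
    if (length(coefficients) != nq)
      stop("form '", form, "' takes exactly ", nq, " coefficients")
  }
  if (form == "log-linear") scale <- "log"
  if (scale == "log" && form != "log-linear")
    stop("scale 'log' is only supported for form 'log-linear'")
  structure(
    list(name = as.character(name), form = form,
         coefficients = coefficients, basis = basis, scale = scale,
         weight_rule = weight_rule, recoverable = isTRUE(recoverable),
         sigma2_printed = sigma2_printed),
    class = "biomass_equation")
}

#' @export
print.biomass_equation <- function(x, ...) {
  cat("Biomass equation '", x$name, "' (", x$form, ", scale = ", x$scale,
      ")\n", sep = "")
  cat("  coefficients:", paste(signif(x$coefficients, 6), collapse = ", "),
      "\n")
  if (!is.null(x$basis)) cat("  basis:", paste(x$basis, collapse = ", "), "\n")
  if (x$weight_rule != "none") cat("  weights:", x$weight_rule, "\n")
  if (!x$recoverable)
    cat("  flagged non-recoverable (generalized fit statistics)\n")
  invisible(x)
}

#' Published fit statistics of a biomass equation
#'
#' Minimal fit statistics as typically published alongside a biomass
#' equation: the fitting sample size and the coefficient of determination,
#' optionally the residual standard deviation (on the fitted scale) and
#' the standard errors of the coefficients.
#'
#' @param n Positive integer fitting sample size.
#' @param r_squared Coefficient of determination in (0, 1].  Either the
#'   plain or the adjusted value may be supplied; `adjusted` records which.
#' @param residual_sd Optional positive residual SD (fitted scale).
#' @param coef_se Optional vector of positive coefficient standard errors.
#' @param adjusted Logical; `TRUE` when `r_squared` is the adjusted value.
#' @return An object of class `fit_stats`.
#' @export
fit_stats <- function(n, r_squared, residual_sd = NULL, coef_se = NULL,
                      adjusted = FALSE) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2")
  if (!is.numeric(r_squared) || r_squared <= 0 || r_squared > 1)
    stop("'r_squared' must lie in (0, 1]")
  if (!is.null(residual_sd) && (!is.numeric(residual_sd) || residual_sd < 0))
    stop("'residual_sd' must be a non-negative number")
  if (!is.null(coef_se) && any(coef_se <= 0))
    stop("'coef_se' must be positive")
  structure(list(n = n, r_squared = as.numeric(r_squared),
                 residual_sd = residual_sd,
                 coef_se = if (!is.null(coef_se)) as.numeric(coef_se),
                 adjusted = isTRUE(adjusted)),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat("Fit statistics: n =", x$n, ", R^2 =", x$r_squared,
      if (x$adjusted) "(adjusted)" else "", "\n")
  if (!is.null(x$residual_sd)) cat("  residual SD:", x$residual_sd, "\n")
  if (!is.null(x$coef_se))
    cat("  coef SE:", paste(signif(x$coef_se, 4), collapse = ", "), "\n")
  invisible(x)
}

# Does the equation use tree height?
uses_height <- function(eq) {
  if (eq$form == "nested-square") return(TRUE)
  if (eq$form %in% c("power", "exp-ratio")) return(FALSE)
  any(eq$basis %in% c("ht", "sqrt_ht", "sqrt_dbh_ht"))
}

# Validate and extract (dbh, ht) from a tree data.frame for an equation.
.tree_inputs <- function(eq, trees) {
  if (!is.data.frame(trees))
    stop("'trees' must be a data.frame with at least a 'dbh_cm' column")
  if (is.null(trees$dbh_cm)) stop("column 'dbh_cm' is missing")
  dbh <- as.numeric(trees$dbh_cm)
  if (anyNA(dbh) || any(dbh <= 0)) {
    bad <- which(is.na(dbh) | dbh <= 0)
    stop("non-positive or missing DBH in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ht <- NULL
  if (uses_height(eq)) {
    if (is.null(trees$ht_m))
      stop("equation '", eq$name,
           "' requires tree height but column 'ht_m' is missing")
    ht <- as.numeric(trees$ht_m)
    if (anyNA(ht) || any(ht <= 0)) {
      bad <- which(is.na(ht) | ht <= 0)
      stop("equation '", eq$name,
           "' requires positive height; bad row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  list(dbh = dbh, ht = ht)
}

.basis_value <- function(token, dbh, ht) {
  switch(token,
         intercept    = rep(1, length(dbh)),
         dbh          = dbh,
         dbh2         = dbh^2,
         ht           = ht,
         sqrt_ht      = sqrt(ht),
         sqrt_dbh_ht  = sqrt(dbh * ht),
         log_dbh      = log(dbh),
         log_dbh2     = log(dbh)^2,
         stop("unknown basis transform '", token, "'"))
}

# n x p matrix of basis regressors for the linear forms.
.basis_matrix <- function(eq, dbh, ht) {
  X <- vapply(eq$basis, .basis_value, numeric(length(dbh)),
              dbh = dbh, ht = ht)
  if (length(dbh) == 1L) X <- matrix(X, nrow = 1L)
  dimnames(X) <- NULL
  X
}

# Fitted-scale (link) prediction; log scale for log-linear equations.
.eval_link <- function(eq, dbh, ht, coefficients = eq$coefficients) {
  b <- coefficients
  switch(eq$form,
         "linear-in-basis" = ,
         "log-linear"      = drop(.basis_matrix(eq, dbh, ht) %*% b),
         "nested-square"   = (b[1] * dbh + b[2] * sqrt(ht))^2,
         "power"           = b[1] * dbh^b[2],
         "exp-ratio"       = exp(b[1] + b[2] * dbh / (dbh + b[3])))
}

#' Predict above-ground biomass
#'
#' Evaluates a biomass equation for a set of trees.  `type = "response"`
#' returns AGB in kg (log-scale equations are back-transformed with a plain
#' `exp`, no bias correction); `type = "link"` returns the prediction on the
#' fitted scale, i.e. log(AGB) for log-linear equations.
#'
#' @param object A [biomass_equation()].
#' @param newdata A data.frame of trees with columns `dbh_cm` (cm) and,
#'   when the equation uses height, `ht_m` (m).
#' @param type `"response"` (kg) or `"link"` (fitted scale).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.biomass_equation <- function(object, newdata,
                                     type = c("response", "link"), ...) {
  type <- match.arg(type)
  inp <- .tree_inputs(object, newdata)
  eta <- .eval_link(object, inp$dbh, inp$ht)
  if (type == "response" && object$scale == "log") exp(eta) else eta
}

#' Convenience wrapper returning AGB in kg
#'
#' @inheritParams predict.biomass_equation
#' @param eq A [biomass_equation()].
#' @param trees Data.frame of trees (`dbh_cm`, optional `ht_m`).
#' @return Numeric vector of AGB predictions (kg).
#' @export
predict_agb <- function(eq, trees) {
  predict(eq, trees, type = "response")
}

#' Gradient of the prediction function with respect to the parameters
#'
#' Returns the n x q matrix of derivatives of the fitted-scale prediction
#' with respect to the model parameters, evaluated at the stored coefficient
#' estimates — the matrix \eqn{\hat F} of the first-order (delta-method)
#' variance approximation.  For linear forms the rows are simply the basis
#' regressor vectors.
#'
#' @param eq A [biomass_equation()].
#' @param trees Data.frame of trees.
#' @param check_rank Logical; when `TRUE` (default) a rank-deficient
#'   gradient matrix raises a singular-design error (with the condition
#'   number in the message) instead of being returned silently.
#' @return Numeric matrix with one row per tree and one column per
#'   coefficient, with attribute `"evaluated_at"`.
#' @export
gradient_matrix <- function(eq, trees, check_rank = TRUE) {
  inp <- .tree_inputs(eq, trees)
  dbh <- inp$dbh; ht <- inp$ht
  b <- eq$coefficients
  G <- switch(eq$form,
    "linear-in-basis" = ,
    "log-linear"      = .basis_matrix(eq, dbh, ht),
    "nested-square"   = {
      u <- b[1] * dbh + b[2] * sqrt(ht)
      cbind(2 * u * dbh, 2 * u * sqrt(ht))
    },
    "power"           = cbind(dbh^b[2], b[1] * dbh^b[2] * log(dbh)),
    "exp-ratio"       = {
      f <- exp(b[1] + b[2] * dbh / (dbh + b[3]))
      r <- dbh / (dbh + b[3])
      cbind(f, f * r, -f * b[2] * dbh / (dbh + b[3])^2)
    })
  if (!all(is.finite(G))) {
    bad <- which(rowSums(!is.finite(G)) > 0)[1]
    stop("non-finite gradient for tree in row ", bad,
         " (dbh_cm = ", dbh[bad], ")")
  }
  if (check_rank && nrow(G) >= ncol(G)) {
    r <- qr(G)$rank
    if (r < ncol(G))
      stop("singular design: gradient matrix has rank ", r, " < q = ",
           ncol(G), " (condition number ",
           format(kappa(G, exact = TRUE), digits = 3), ")")
  }
  attr(G, "evaluated_at") <- b
  G
}

#' Gradient for a single tree
#'
#' @inheritParams gradient_matrix
#' @param tree One-row data.frame.
#' @return Numeric vector of length q.
#' @export
gradient <- function(eq, tree) {
  drop(gradient_matrix(eq, tree[1, , drop = FALSE], check_rank = FALSE))
}

#' Central finite-difference gradient (numerical oracle / fallback)
#'
#' Central differences of the fitted-scale prediction with a relative step,
#' useful as an independent check of the analytic gradients or for
#' user-supplied functional forms.
#'
#' @inheritParams gradient_matrix
#' @param rel_step Relative step size (absolute step for coefficients at 0).
#' @return n x q matrix of numerical derivatives.
#' @export
numeric_gradient_matrix <- function(eq, trees, rel_step = 1e-6) {
  inp <- .tree_inputs(eq, trees)
  b <- eq$coefficients
  q <- length(b)
  G <- matrix(NA_real_, length(inp$dbh), q)
  for (k in seq_len(q)) {
    h <- rel_step * max(abs(b[k]), 1)
    bp <- b; bp[k] <- b[k] + h
    bm <- b; bm[k] <- b[k] - h
    G[, k] <- (.eval_link(eq, inp$dbh, inp$ht, bp) -
               .eval_link(eq, inp$dbh, inp$ht, bm)) / (2 * h)
  }
  G
}
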
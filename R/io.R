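# File formats: tree lists as CSV (header species,plot_id,dbh_cm,ht_m;
# ht_m may be empty), equation specifications and machine-readable reports
# as JSON.  Covariance matrices are serialized row-major with an explicit
# dimension so round-trips are unambiguous.

#' Read a tree list from CSV
#'
#' Expects a header containing at least `species` and `dbh_cm`; `plot_id`
#' and `ht_m` are optional and an empty `ht_m` cell is read as missing.
#' Rows failing validation are reported with their line numbers.
#'
#' @param path Path to a UTF-8 CSV file with '.' as decimal separator.
#' @return Data.frame with columns `species`, `dbh_cm` and, when present,
#'   `ht_m` and `plot_id`.
#' @export
read_tree_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("species", "dbh_cm")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("malformed header in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  dbh <- suppressWarnings(as.numeric(df$dbh_cm))
  bad <- which(is.na(dbh) | dbh <= 0)
  if (length(bad))
    stop("invalid dbh_cm in ", path, " at data line(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         " (values must be positive numbers)")
  df$dbh_cm <- dbh
  if (!is.null(df$ht_m)) {
    ht_chr <- as.character(df$ht_m)
    empty <- is.na(ht_chr) | trimws(ht_chr) == ""
    ht <- suppressWarnings(as.numeric(ht_chr))
    bad <- which(!empty & (is.na(ht) | ht <= 0))
    if (length(bad))
      stop("invalid ht_m in ", path, " at data line(s) ",
           paste(utils::head(bad, 10), collapse = ", "),
           " (values must be positive numbers or empty)")
    ht[empty] <- NA_real_
    df$ht_m <- ht
  }
  df
}

#' Write a tree list to CSV
#'
#' @param trees Data.frame of trees.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_tree_csv <- function(trees, path) {
  utils::write.csv(trees, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

.EQ_SPEC_KEYS <- c("name", "form", "coefficients", "basis", "scale",
                   "weight_rule", "recoverable", "sigma2_printed", "fit")

#' Read an equation specification from JSON
#'
#' The schema is `{name, form, coefficients[], basis[], scale,
#' weight_rule, recoverable, sigma2_printed?, fit: {n, r2, sigma_e?,
#' coef_se?[]}}`.  Unknown keys
#' produce a warning (forward compatibility), not an error; a missing
#' `fit.r2` is an error.
#'
#' @param path Path to a JSON file.
#' @return List with components `equation` ([biomass_equation()]) and
#'   `fit` ([fit_stats()]).
#' @export
read_equation_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- setdiff(names(js), .EQ_SPEC_KEYS)
  if (length(extra))
    warning("ignoring unknown key(s) in ", path, ": ",
            paste(extra, collapse = ", "))
  for (key in c("name", "form", "coefficients", "fit"))
    if (is.null(js[[key]]))
      stop("equation spec ", path, " lacks required key '", key, "'")
  if (is.null(js$fit$r2)) stop("equation spec ", path, " lacks fit.r2")
  if (is.null(js$fit$n)) stop("equation spec ", path, " lacks fit.n")
  eq <- biomass_equation(
    name = js$name, form = js$form, coefficients = js$coefficients,
    basis = js$basis,
    scale = if (is.null(js$scale)) "identity" else js$scale,
    weight_rule = if (is.null(js$weight_rule)) "none" else js$weight_rule,
    recoverable = if (is.null(js$recoverable)) TRUE else js$recoverable,
    sigma2_printed = js$sigma2_printed)
  fit <- fit_stats(n = js$fit$n, r_squared = js$fit$r2,
                   residual_sd = js$fit$sigma_e, coef_se = js$fit$coef_se)
  list(equation = eq, fit = fit)
}

#' Write an equation specification to JSON
#'
#' Round-trips bit-exactly with [read_equation_spec()].
#'
#' @param eq A [biomass_equation()].
#' @param fit A [fit_stats()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_equation_spec <- function(eq, fit, path) {
  spec <- list(name = eq$name, form = eq$form,
               coefficients = eq$coefficients)
  if (!is.null(eq$basis)) spec$basis <- eq$basis
  spec$scale <- eq$scale
  spec$weight_rule <- eq$weight_rule
  spec$recoverable <- eq$recoverable
  if (!is.null(eq$sigma2_printed)) spec$sigma2_printed <- eq$sigma2_printed
  spec$fit <- list(n = fit$n, r2 = fit$r_squared)
  if (!is.null(fit$residual_sd)) spec$fit$sigma_e <- fit$residual_sd
  if (!is.null(fit$coef_se)) spec$fit$coef_se <- fit$coef_se
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize recovered statistics to JSON
#'
#' The covariance matrix is written row-major together with its dimension.
#'
#' @param stats A `recovered_stats` object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_recovered_stats <- function(stats, path) {
  q <- nrow(stats$cov)
  out <- list(sigma2_resid = stats$sigma2_resid,
              cov = as.numeric(t(stats$cov)), q = q,
              B = stats$B_used,
              mc_error_det_pct = stats$mc_error_det_pct,
              method = stats$method, weighted = stats$weighted,
              condition_number = stats$condition_number,
              n_repairs = stats$n_repairs, seed = stats$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read recovered statistics from JSON
#'
#' @param path Path written by [write_recovered_stats()].
#' @return A list with `sigma2_resid` and `cov` (q x q matrix) plus the
#'   run metadata.
#' @export
read_recovered_stats <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  js$cov <- matrix(js$cov, nrow = js$q, byrow = TRUE)
  js
}

#' Assemble a self-describing run report
#'
#' @param command Name of the command or function that produced the run.
#' @param config List echoing the configuration used.
#' @param seed Integer seed of the run.
#' @param inputs Named character vector of input paths.
#' @param outputs Named character vector of output paths.
#' @param warnings Character vector of warnings (e.g. PSD repairs,
#'   condition-number flags).
#' @return A list of class `run_report`.
#' @export
run_report <- function(command, config = list(), seed = NA_integer_,
                       inputs = character(), outputs = character(),
                       warnings = character()) {
  digest <- vapply(inputs, function(p) {
    if (file.exists(p)) format(file.size(p)) else "missing"
  }, character(1))
  structure(list(command = as.character(command), config = config,
                 seed = as.integer(seed),
                 inputs = as.list(inputs), input_sizes = as.list(digest),
                 outputs = as.list(outputs),
                 warnings = as.list(warnings),
                 version = as.character(utils::packageVersion("allomvar"))),
            class = "run_report")
}

#' Write a run report as deterministic JSON
#'
#' Keys are sorted so identical runs produce byte-identical files.
#'
#' @param report A [run_report()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path) {
  sort_keys <- function(x) {
    if (is.list(x) && !is.null(names(x)) && length(x))
      lapply(x[order(names(x))], sort_keys)
    else x
  }
  jsonlite::write_json(sort_keys(unclass(report)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run report
#' @param path Path written by [write_report()].
#' @return List with the report fields.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
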
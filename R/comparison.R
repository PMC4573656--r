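# Statistical comparison of covariance matrices and residual variances:
# Box's M test (chi-square approximation with the standard small-sample
# correction) and a two-sided F-ratio test of two variances.

#' Box's M test for equality of covariance matrices
#'
#' Likelihood-ratio-based test of the null hypothesis that k groups share a
#' common covariance matrix.  The statistic is
#' \eqn{M = \sum_i (n_i - 1) \ln|S_p| - \sum_i (n_i - 1) \ln|S_i|}
#' with \eqn{S_p} the \eqn{(n_i - 1)}-weighted pooled matrix, corrected by
#' the standard Box scale factor and referred to a chi-square distribution
#' with \eqn{p(p+1)(k-1)/2} degrees of freedom.
#'
#' @param matrices List of k (>= 2) symmetric positive-definite p x p
#'   covariance matrices.
#' @param group_sizes Integer vector of the k group sizes (each > p).
#' @return A list of class `box_m_test` with components `M` (uncorrected
#'   statistic), `chi2` (corrected statistic), `df` and `p_value`.
#' @export
#' @examples
#' a <- diag(2); b <- matrix(c(1, .3, .3, 1.2), 2)
#' box_m_test(list(a, b), c(50, 50))
box_m_test <- function(matrices, group_sizes) {
  k <- length(matrices)
  if (k < 2L) stop("at least two covariance matrices are required")
  if (length(group_sizes) != k)
    stop("'group_sizes' must have one entry per matrix")
  p <- nrow(matrices[[1]])
  for (S in matrices) {
    if (!is.matrix(S) || any(dim(S) != p))
      stop("all matrices must be square with common dimension ", p)
  }
  if (any(group_sizes <= p))
    stop("every group size must exceed the matrix dimension p = ", p)
  nu <- group_sizes - 1
  logdets <- vapply(matrices, function(S) {
    d <- determinant(S, logarithm = TRUE)
    if (d$sign <= 0 || !is.finite(as.numeric(d$modulus)))
      stop("a covariance matrix is singular or not positive definite; ",
           "its log-determinant is undefined")
    as.numeric(d$modulus)
  }, numeric(1))
  Sp <- Reduce(`+`, Map(`*`, matrices, nu)) / sum(nu)
  dp <- determinant(Sp, logarithm = TRUE)
  if (dp$sign <= 0) stop("pooled covariance matrix is singular")
  M <- sum(nu) * as.numeric(dp$modulus) - sum(nu * logdets)
  c1 <- (sum(1 / nu) - 1 / sum(nu)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1))
  chi2 <- M * (1 - c1)
  df <- p * (p + 1) * (k - 1) / 2
  p_value <- stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(M = M, chi2 = chi2, df = df, p_value = p_value,
                 k = k, p = p),
            class = "box_m_test")
}

#' @export
print.box_m_test <- function(x, ...) {
  cat("Box's M test of covariance equality (", x$k, " groups, p = ", x$p,
      ")\n", sep = "")
  cat("  M =", signif(x$M, 5), " chi2 =", signif(x$chi2, 5),
      " df =", x$df, " p =", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Two-sided F-ratio test of two variances
#'
#' @param var1,var2 Positive variance estimates.
#' @param df1,df2 Their degrees of freedom (>= 1).
#' @return Two-sided p-value of the ratio `var1/var2` under the F
#'   distribution.
#' @export
f_ratio_test <- function(var1, df1, var2, df2) {
  if (var1 <= 0 || var2 <= 0) stop("variances must be positive")
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1")
  ratio <- var1 / var2
  min(1, 2 * min(stats::pf(ratio, df1, df2),
                 stats::pf(ratio, df1, df2, lower.tail = FALSE)))
}

#' Covariance to correlation matrix
#'
#' @param matrix Covariance matrix with strictly positive diagonal.
#' @return Correlation matrix with unit diagonal.
#' @export
cov_to_corr <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (any(diag(matrix) <= 0))
    stop("all diagonal elements must be positive")
  s <- 1 / sqrt(diag(matrix))
  R <- matrix * tcrossprod(s)
  diag(R) <- 1
  R
}
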
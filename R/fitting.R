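# Least-squares (re)fitting of a biomass equation to a response vector on
# the equation's fitted scale.  Linear forms go through lm.fit / lm.wfit;
# the nonlinear forms use Levenberg-Marquardt (minpack.lm) started at the
# equation's stored coefficients.  Returns the textbook covariance
# sigma^2 (F'WF)^-1 evaluated at the new estimates — the "actual"
# covariance a study would have published.

.fit_equation <- function(eq, trees, y, weights = NULL) {
  inp <- .tree_inputs(eq, trees)
  n <- length(y)
  q <- length(eq$coefficients)
  if (n <= q) stop("need more observations than parameters to refit")
  w <- weights
  if (eq$form %in% c("linear-in-basis", "log-linear")) {
    X <- .basis_matrix(eq, inp$dbh, inp$ht)
    fitb <- if (is.null(w)) stats::lm.fit(X, y) else stats::lm.wfit(X, y, w)
    b <- unname(fitb$coefficients)
    res <- y - drop(X %*% b)
    ww <- if (is.null(w)) rep(1, n) else w
    sigma2 <- sum(ww * res^2) / (n - q)
    cov <- sigma2 * .xtwx_inverse(X, w)
    fitted <- drop(X %*% b)
  } else {
    dat <- data.frame(y = y, dbh = inp$dbh)
    if (!is.null(inp$ht)) dat$ht <- inp$ht
    fml <- switch(eq$form,
      "nested-square" = y ~ (b1 * dbh + b2 * sqrt(ht))^2,
      "power"         = y ~ b1 * dbh^b2,
      "exp-ratio"     = y ~ exp(b1 + b2 * dbh / (dbh + b3)))
    start <- stats::setNames(as.list(eq$coefficients),
                             paste0("b", seq_len(q)))
    nfit <- minpack.lm::nlsLM(fml, data = dat, start = start,
                              weights = if (is.null(w)) rep(1, n) else w,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200))
    if (!nfit$convInfo$isConv && nfit$convInfo$stopCode > 3)
      stop("nonlinear refit did not converge")
    b <- unname(stats::coef(nfit))
    eqb <- eq; eqb$coefficients <- b
    Fhat <- gradient_matrix(eqb, trees, check_rank = FALSE)
    res <- y - .eval_link(eq, inp$dbh, inp$ht, b)
    ww <- if (is.null(w)) rep(1, n) else w
    sigma2 <- sum(ww * res^2) / (n - q)
    cov <- sigma2 * .xtwx_inverse(Fhat, w)
    fitted <- .eval_link(eq, inp$dbh, inp$ht, b)
  }
  ww <- if (is.null(w)) rep(1, n) else w
  ybar <- sum(ww * y) / sum(ww)
  sst <- sum(ww * (y - ybar)^2)
  r2 <- if (sst > 0) 1 - sum(ww * res^2) / sst else 1
  list(coefficients = b, cov = cov, sigma2 = sigma2,
       r_squared = r2, fitted = fitted)
}
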
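# Group-difference statistics for similarity (proportion) data and
# compositional similarity, plus stratified summary tables.

#' Beta regression for proportion responses
#'
#' Fits a beta-distributed response with a logit link on the mean and a
#' single precision parameter phi (log link), by maximum likelihood with
#' analytic gradients; coefficient tests are Wald tests from the observed
#' information. Responses at exactly 0 or 1 are first compressed with the
#' standard transform \eqn{y' = (y (n - 1) + 0.5) / n}.
#'
#' @param formula model formula, response a proportion in \eqn{[0, 1]}.
#' @param data data frame.
#' @param compress apply the 0/1 compression (default TRUE; applied to all
#'   values whenever any response touches 0 or 1, as the transform
#'   requires).
#' @return object of class `beta_regression`: list with `coefficients`
#'   (estimate, std. error, z, p per mean-model coefficient), `phi`,
#'   `log_phi_se`, `logLik`, `fitted`, `converged`, `n`.
#' @export
beta_regression <- function(formula, data, compress = TRUE) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  if (any(y < 0 | y > 1)) stop("response must lie in [0, 1]")
  if (any(y <= 0 | y >= 1)) {
    if (!compress)
      stop("response touches 0/1; enable `compress` or transform beforehand")
    y <- (y * (n - 1) + 0.5) / n
  }
  p <- ncol(X)
  negll <- function(par) {
    mu <- plogis(drop(X %*% par[1:p]))
    phi <- exp(par[p + 1])
    -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
           (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
  }
  grad <- function(par) {
    eta <- drop(X %*% par[1:p])
    mu <- plogis(eta)
    phi <- exp(par[p + 1])
    ystar <- log(y) - log1p(-y)
    mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
    dmu <- phi * (ystar - mustar) * mu * (1 - mu)
    dtau <- phi * sum(digamma(phi) - mu * digamma(mu * phi) -
                        (1 - mu) * digamma((1 - mu) * phi) +
                        mu * log(y) + (1 - mu) * log1p(-y))
    -c(drop(crossprod(X, dmu)), dtau)
  }
  # starting values: OLS on the logit scale; phi from residual variance
  lf <- stats::lm.fit(X, qlogis(y))
  mu0 <- plogis(lf$fitted.values)
  v <- stats::var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(v, 1e-8) - 1, 1)
  fit <- optim(c(lf$coefficients, log(phi0)), negll, grad, method = "BFGS",
               hessian = TRUE, control = list(maxit = 500))
  converged <- fit$convergence == 0
  if (!converged)
    warning("beta regression did not converge (optim code ", fit$convergence,
            "): ", fit$message %||% "no message")
  vc <- tryCatch(solve(fit$hessian), error = function(e) {
    warning("singular information matrix; standard errors unavailable")
    matrix(NA_real_, p + 1, p + 1)
  })
  est <- fit$par[1:p]
  se <- sqrt(diag(vc)[1:p])
  z <- est / se
  coefs <- data.frame(estimate = est, std_error = se, z = z,
                      p_value = 2 * pnorm(-abs(z)),
                      row.names = colnames(X))
  structure(list(coefficients = coefs, phi = unname(exp(fit$par[p + 1])),
                 log_phi_se = unname(sqrt(diag(vc)[p + 1])),
                 logLik = -fit$value,
                 fitted = plogis(drop(X %*% est)),
                 response = y, model_matrix = X,
                 converged = converged, n = n),
            class = "beta_regression")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.beta_regression <- function(x, ...) {
  cat(sprintf("Beta regression (logit link), n = %d, phi = %.3f, logLik = %.2f%s\n",
              x$n, x$phi, x$logLik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Linear trend of a normally distributed outcome
#'
#' Ordinary least squares of `values` on `predictor`; used for
#' compositional similarity, which is approximately normal.
#'
#' @param values numeric response.
#' @param predictor numeric predictor (age, time gap, ...).
#' @param conf confidence level for the slope interval.
#' @return list with `slope`, `se`, `ci`, `p`, `intercept`, `n`, `fit`.
#' @export
linear_trend <- function(values, predictor, conf = 0.95) {
  ok <- complete.cases(values, predictor)
  values <- values[ok]; predictor <- predictor[ok]
  if (length(values) < 3) stop("need at least 3 complete observations")
  if (sd(predictor) == 0) stop("constant predictor: trend undefined")
  fit <- lm(values ~ predictor)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, "predictor", level = conf)
  list(slope = sm["predictor", "Estimate"], se = sm["predictor", "Std. Error"],
       ci = unname(ci[1, ]), p = sm["predictor", "Pr(>|t|)"],
       intercept = sm["(Intercept)", "Estimate"], n = length(values),
       fit = fit)
}

#' Stratified medians with per-individual reduction
#'
#' Records are first reduced to one median per individual within each
#' stratum (avoiding pseudo-replication from repeated records per person),
#' then each stratum is summarized by the median and interquartile range of
#' the per-individual medians.
#'
#' @param records data frame.
#' @param value name of the numeric value column.
#' @param strata character vector of stratum column names.
#' @param individual name of the clustering-unit column.
#' @return data frame with one row per stratum: `median`, `iqr_low`,
#'   `iqr_high`, `n_individuals`.
#' @export
group_summary <- function(records, value = "similarity", strata,
                          individual = "individual_id") {
  need <- c(value, strata, individual)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  r <- records[!is.na(records[[value]]), ]
  if (!nrow(r))
    return(data.frame())
  per_ind <- aggregate(r[value], by = r[c(individual, strata)], FUN = median)
  agg <- aggregate(per_ind[value], by = per_ind[strata],
                   FUN = function(x) c(median = median(x),
                                       iqr_low = unname(quantile(x, 0.25)),
                                       iqr_high = unname(quantile(x, 0.75)),
                                       n = length(x)))
  out <- cbind(agg[strata], as.data.frame(agg[[value]]))
  names(out) <- c(strata, "median", "iqr_low", "iqr_high", "n_individuals")
  out
}
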
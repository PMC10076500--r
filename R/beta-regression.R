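# Beta regression with logit mean link and constant precision, fitted by
# maximum likelihood. Used for proportions of methylated sites across codon
# fold classes.

#' Shrink proportions away from the 0/1 boundary
#'
#' The beta likelihood is undefined at exactly 0 or 1; the standard
#' transformation `(y (N - 1) + 0.5) / N` pulls all observations strictly
#' inside (0, 1).
#'
#' @param y Proportions in \[0, 1\].
#' @param n Sample size used in the shrinkage (default `length(y)`).
#' @return Shrunk proportions.
#' @export
shrink_proportions <- function(y, n = length(y)) {
  (y * (n - 1) + 0.5) / n
}

#' Fit a beta regression by maximum likelihood
#'
#' Models proportions with a Beta(mu phi, (1 - mu) phi) likelihood, logit
#' link on the mean mu and a single constant precision phi shared by all
#' observations. Parameters are estimated by BFGS maximisation of the
#' log-likelihood; standard errors and Wald z statistics come from the
#' inverse observed information. Responses on the boundary are shrunk with
#' [shrink_proportions()] first.
#'
#' @param formula Model formula, e.g. `proportion ~ fold + sex`.
#' @param data Data frame holding the response and predictors.
#' @return A `beta_reg` object with [tidy()] and [glance()] methods.
#' @export
fit_beta_regression <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (any(y < 0 | y > 1)) abort("responses must lie in [0, 1]")
  if (any(y <= 0 | y >= 1)) y <- shrink_proportions(y)
  p <- ncol(X)

  negll <- function(par) {
    mu <- stats::plogis(drop(X %*% par[seq_len(p)]))
    phi <- exp(par[p + 1L])
    -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  # start from a logit-scale least-squares fit and a moment guess for phi
  start_beta <- tryCatch(
    stats::lm.fit(X, stats::qlogis(y))$coefficients,
    error = function(e) rep(0, p)
  )
  start_beta[is.na(start_beta)] <- 0
  mu0 <- stats::plogis(drop(X %*% start_beta))
  v <- stats::var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(v, 1e-8) - 1, 2)
  start <- c(start_beta, log(phi0))

  fit <- stats::optim(start, negll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) {
    abort(sprintf(
      "beta regression did not converge (optim code %d after %s evaluations)",
      fit$convergence, paste(fit$counts, collapse = "/")
    ))
  }
  vc <- tryCatch(solve(fit$hessian), error = function(e) {
    abort("beta regression: singular information matrix")
  })
  se <- sqrt(pmax(diag(vc), 0))
  est <- fit$par
  terms <- c(colnames(X), "(phi)")
  z <- est / se
  z[p + 1L] <- NA  # phi reported on the log scale, no Wald test
  structure(
    list(
      coefficients = setNames(est[seq_len(p)], colnames(X)),
      phi = exp(est[p + 1L]),
      se = setNames(se[seq_len(p)], colnames(X)),
      z = setNames(z[seq_len(p)], colnames(X)),
      p_values = setNames(2 * stats::pnorm(-abs(z[seq_len(p)])),
                          colnames(X)),
      logLik = -fit$value,
      n = length(y),
      counts = fit$counts,
      formula = formula,
      vcov = vc
    ),
    class = "beta_reg"
  )
}

#' @export
print.beta_reg <- function(x, ...) {
  cat("Beta regression (logit mean link, constant precision)\n")
  cat(sprintf("  n = %d, logLik = %.3f, phi = %.2f\n", x$n, x$logLik, x$phi))
  print(tidy(x))
  invisible(x)
}

#' @describeIn fit_beta_regression Coefficient table (term, estimate,
#'   std.error, statistic, p.value).
#' @param x A `beta_reg` object.
#' @param ... Unused.
#' @export
tidy.beta_reg <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(x$z),
    p.value = unname(x$p_values)
  )
}

#' @describeIn fit_beta_regression One-row model summary.
#' @export
glance.beta_reg <- function(x, ...) {
  tibble(logLik = x$logLik, phi = x$phi, nobs = x$n,
         df = length(x$coefficients) + 1L)
}
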
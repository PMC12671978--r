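#' Fit a log-binomial (risk-ratio) regression
#'
#' Maximum-likelihood fit of a Bernoulli model with log link, so each
#' coefficient is a log risk ratio. Log-binomial likelihoods are
#' boundary-prone (fitted risks must stay below 1), so the fit uses damped
#' iteratively reweighted least squares: each Newton step is halved until the
#' proposed coefficients keep every fitted probability at or below 1 and do
#' not decrease the log-likelihood. Starting values are the intercept-only
#' MLE (log of the weighted mean outcome), which is always feasible.
#'
#' A fit that lands on the boundary of the parameter space (some fitted
#' probability within 1e-8 of 1) is reported with `converged = FALSE`; the
#' boundary is where the model-based information matrix degenerates, so such
#' fits are never silently treated as interior maxima.
#'
#' @param data a data frame (e.g. a [sample_cohort()] cohort or a weighted
#'   covariate-pattern table) with a binary outcome column `Y` and one
#'   numeric column per model term.
#' @param terms character vector of covariate column names to include (the
#'   exposure `A` plus any adjustment variables); an intercept is always
#'   included.
#' @param weights optional non-negative case weights (counts for an
#'   aggregated table, probability masses for a population-level fit).
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change between Newton steps.
#' @param max_iter maximum number of Newton steps.
#'
#' @return An object of class `logbin` with components `coefficients`, `se`
#'   (information-based standard errors), `vcov`, `fitted`, `loglik`,
#'   `converged`, `boundary`, `iterations`, `n_used` and `terms`. Methods:
#'   [coef()], [vcov()], [predict.logbin()], [summary.logbin()],
#'   [residuals.logbin()], [simulate.logbin()], `confint`, `print`.
#' @examples
#' spec <- scenario_preset("instrument", n = 2000L, seed = 42L)
#' fit <- fit_log_binomial(sample_cohort(spec, 1L), c("A", "C"))
#' exp(coef(fit)["A"])  # risk ratio for exposure
#' @export
fit_log_binomial <- function(data, terms, weights = NULL,
                             tol = 1e-10, max_iter = 200L) {
  stopifnot(is.data.frame(data), length(terms) >= 0)
  if (!"Y" %in% names(data)) stop("data must contain an outcome column 'Y'")
  missing_terms <- setdiff(terms, names(data))
  if (length(missing_terms))
    stop("terms not found in data: ", paste(missing_terms, collapse = ", "))

  w <- if (is.null(weights)) rep(1, nrow(data)) else as.numeric(weights)
  if (length(w) != nrow(data)) stop("weights must match the number of rows")
  if (any(w < 0) || sum(w) <= 0)
    stop("weights must be non-negative with a positive sum")
  keep <- w > 0
  y <- as.numeric(data$Y[keep])
  w <- w[keep]
  if (!all(y %in% c(0, 1))) stop("Y must be binary (0/1)")

  X <- cbind("(Intercept)" = 1,
             as.matrix(data[keep, terms, drop = FALSE]))
  storage.mode(X) <- "double"

  ybar <- sum(w * y) / sum(w)
  if (ybar <= 0 || ybar >= 1)
    stop("no variation in outcome Y among used observations")
  for (v in terms)
    if (length(unique(X[, v])) < 2)
      stop(sprintf("no variation in covariate '%s'", v))

  loglik <- function(mu) {
    mu <- pmin(pmax(mu, .Machine$double.xmin), 1)
    sum(w * ifelse(y == 1, log(mu), log1p(-mu)))
  }

  p <- ncol(X)
  beta <- c(log(ybar), rep(0, p - 1))
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  ll <- loglik(mu)

  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mu_c <- pmin(mu, 1 - 1e-12)
    W <- w * mu_c / (1 - mu_c)
    z <- eta + (y - mu_c) / mu_c
    info <- crossprod(X, X * W)
    rhs <- crossprod(X, W * z)
    beta_prop <- tryCatch(drop(solve(info, rhs)), error = function(e) NULL)
    if (is.null(beta_prop)) break  # singular information: boundary/degenerate
    step <- beta_prop - beta

    h <- 1
    accepted <- FALSE
    for (half in 1:60) {
      cand <- beta + h * step
      eta_c <- drop(X %*% cand)
      if (max(eta_c) <= 0) {
        ll_c <- loglik(exp(eta_c))
        if (is.finite(ll_c) && ll_c >= ll - 1e-12) {
          accepted <- TRUE
          break
        }
      }
      h <- h / 2
    }
    if (!accepted) break

    delta <- max(abs(h * step))
    beta <- cand
    eta <- eta_c
    mu <- exp(eta)
    ll <- loglik(mu)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  boundary <- any(mu > 1 - 1e-8)
  if (boundary) converged <- FALSE

  mu_c <- pmin(mu, 1 - 1e-12)
  info <- crossprod(X, X * (w * mu_c / (1 - mu_c)))
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p, p, dimnames = dimnames(info))
  })
  se <- sqrt(pmax(diag(vc), 0))

  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    vcov = vc,
    fitted = mu,
    loglik = ll,
    converged = converged,
    boundary = boundary,
    iterations = it,
    n_used = if (is.null(weights)) sum(keep) else sum(w),
    terms = terms,
    y = y,
    weights = w,
    model_matrix = X,
    call = match.call()
  ), class = "logbin")
}

#' @export
print.logbin <- function(x, digits = 4, ...) {
  cat("Log-binomial regression (log link, Bernoulli likelihood)\n")
  cat("Terms:", if (length(x$terms)) paste(x$terms, collapse = ", ")
      else "(intercept only)", "\n")
  print(round(x$coefficients, digits))
  if (!x$converged)
    cat(if (x$boundary) "WARNING: fit on boundary (fitted risk ~ 1); "
        else "WARNING: ", "not converged\n", sep = "")
  invisible(x)
}

#' Summarize a log-binomial fit
#'
#' @param object a `logbin` fit.
#' @param ... unused.
#' @return A `summary.logbin` object holding the coefficient table (estimate,
#'   SE, z, p, risk ratio) and convergence diagnostics.
#' @export
summary.logbin <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  z <- est / se
  tab <- cbind(
    Estimate = est, `Std. Error` = se, `z value` = z,
    `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)), RR = exp(est)
  )
  structure(list(coefficients = tab, loglik = object$loglik,
                 converged = object$converged, boundary = object$boundary,
                 iterations = object$iterations, n_used = object$n_used),
            class = "summary.logbin")
}

#' @export
print.summary.logbin <- function(x, digits = 4, ...) {
  cat("Log-binomial regression\n\n")
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE], digits = digits)
  cat(sprintf("\nlog-likelihood %.6g on n = %s, %d iterations%s\n",
              x$loglik, format(x$n_used), x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
coef.logbin <- function(object, ...) object$coefficients

#' @export
vcov.logbin <- function(object, ...) object$vcov

#' Predict from a log-binomial fit
#'
#' @param object a `logbin` fit.
#' @param newdata data frame with the model's term columns; defaults to the
#'   training rows.
#' @param type `"response"` for fitted risks, `"link"` for the linear
#'   predictor (log risk).
#' @param ... unused.
#' @return A numeric vector.
#' @export
predict.logbin <- function(object, newdata = NULL,
                           type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$model_matrix
       else cbind("(Intercept)" = 1,
                  as.matrix(newdata[, object$terms, drop = FALSE]))
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else exp(eta)
}

#' Residuals of a log-binomial fit
#'
#' @param object a `logbin` fit.
#' @param type `"response"` (`y - mu`) or `"pearson"`
#'   (weighted by `sqrt(w / (mu (1 - mu)))`).
#' @param ... unused.
#' @return A numeric vector, one element per used observation (or covariate
#'   pattern for weighted fits).
#' @export
residuals.logbin <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson") {
    v <- pmax(object$fitted * (1 - object$fitted), .Machine$double.eps)
    r <- r * sqrt(object$weights / v)
  }
  r
}

#' Simulate outcomes from a log-binomial fit
#'
#' Draws Bernoulli outcomes at the fitted (or newly predicted) risks. For
#' weighted fits the draws are per covariate pattern, not per original
#' individual.
#'
#' @param object a `logbin` fit.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional seed passed to [set.seed()].
#' @param newdata optional data frame of covariate values.
#' @param ... unused.
#' @return A data frame with `nsim` columns of 0/1 outcomes.
#' @export
simulate.logbin <- function(object, nsim = 1, seed = NULL,
                            newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata = newdata, type = "response")
  out <- as.data.frame(
    matrix(stats::rbinom(length(p) * nsim, 1L, rep(p, nsim)),
           ncol = nsim, dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
  out
}

#' @export
confint.logbin <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  q <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lower = cf[parm] - q * object$se[parm],
        upper = cf[parm] + q * object$se[parm])
}
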
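#' Define an analysis plan
#'
#' One analysis plan is one recipe: which covariates enter the log-binomial
#' model alongside the exposure, and whether the analysis is restricted to
#' the exposure-potential stratum (women). Restriction is incompatible with
#' adjusting for sex, which is constant after restriction.
#'
#' @param label text label for reports.
#' @param adjustment_set subset of `c("C", "sex")`.
#' @param restrict analyse women only?
#' @return An object of class `eprr_plan`.
#' @examples
#' analysis_plan("Adjusted for C, restricted on sex", "C", restrict = TRUE)
#' @export
analysis_plan <- function(label, adjustment_set = character(0),
                          restrict = FALSE) {
  adjustment_set <- as.character(adjustment_set)
  extra <- setdiff(adjustment_set, c("C", "sex"))
  if (length(extra))
    stop("adjustment_set must be a subset of {C, sex}; got: ",
         paste(extra, collapse = ", "))
  if (restrict && "sex" %in% adjustment_set)
    stop("restricting on sex is incompatible with adjusting for sex ",
         "(sex is constant after restriction)")
  structure(list(label = as.character(label),
                 adjustment_set = adjustment_set,
                 restrict = isTRUE(restrict)),
            class = "eprr_plan")
}

.as_plan <- function(plan) {
  if (inherits(plan, "eprr_plan")) return(plan)
  stop("expected an analysis_plan()")
}

#' @export
print.eprr_plan <- function(x, ...) {
  cat(sprintf("Analysis plan: %s [adjust: %s%s]\n", x$label,
              if (length(x$adjustment_set))
                paste(x$adjustment_set, collapse = ", ") else "none",
              if (x$restrict) "; restricted to women" else ""))
  invisible(x)
}

#' The six canonical analysis plans
#'
#' In reporting order: adjusted for C; adjusted for C and sex; adjusted for C
#' restricted on sex; no adjustment; adjusted for sex; restriction on sex.
#' Evaluating all six under both the confounder and instrument scenarios
#' gives the full 12-cell grid ([run_table2()]).
#'
#' @return A list of six [analysis_plan()] objects.
#' @export
canonical_plans <- function() {
  list(
    analysis_plan("Adjusted for C", "C"),
    analysis_plan("Adjusted for C, sex", c("C", "sex")),
    analysis_plan("Adjusted for C, restricted on sex", "C", restrict = TRUE),
    analysis_plan("No adjustment"),
    analysis_plan("Adjusted for sex", "sex"),
    analysis_plan("Restriction on sex", restrict = TRUE)
  )
}

# Collapse binary records to covariate-pattern counts over cols + Y. All
# model variables are 0/1 so a bit-index tabulation is exact and fast.
.aggregate_binary <- function(df, cols) {
  vars <- c(cols, "Y")
  idx <- rep(1L, nrow(df))
  mult <- 1L
  for (v in vars) {
    idx <- idx + df[[v]] * mult
    mult <- mult * 2L
  }
  w <- tabulate(idx, nbins = mult)
  pat <- expand.grid(rep(list(0:1), length(vars)), KEEP.OUT.ATTRS = FALSE)
  names(pat) <- vars
  keep <- w > 0
  out <- pat[keep, , drop = FALSE]
  out$weight <- w[keep]
  rownames(out) <- NULL
  out
}

#' Estimate an exposure effect under an analysis plan
#'
#' Applies the plan to a cohort: restricts to women if requested, then fits
#' the log-binomial model of `Y` on the exposure `A` and the plan's
#' adjustment set. Records are collapsed to covariate-pattern counts before
#' fitting (the likelihood is identical), so the fit cost does not grow with
#' cohort size.
#'
#' @param cohort an `eprr_cohort`.
#' @param plan an [analysis_plan()].
#' @return An object of class `eprr_estimate`: list with `log_rr` (the
#'   exposure coefficient), `se_model` (information-based SE), `converged`,
#'   `n_used` and the underlying `logbin` fit as `fit`.
#' @examples
#' spec <- scenario_preset("instrument", n = 2000L, seed = 3L)
#' estimate_effect(sample_cohort(spec, 1L), analysis_plan("Adjusted for C", "C"))
#' @export
estimate_effect <- function(cohort, plan) {
  plan <- .as_plan(plan)
  stopifnot(is.data.frame(cohort))
  if (plan$restrict) cohort <- restrict_cohort(cohort)
  terms <- c("A", plan$adjustment_set)
  agg <- .aggregate_binary(as.data.frame(cohort), terms)
  fit <- fit_log_binomial(agg, terms = terms, weights = agg$weight)
  structure(list(
    log_rr = unname(fit$coefficients["A"]),
    se_model = unname(fit$se["A"]),
    converged = fit$converged,
    n_used = as.integer(round(fit$n_used)),
    plan = plan,
    fit = fit
  ), class = "eprr_estimate")
}

#' @export
print.eprr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s: log RR = %.*f (SE %.*f), RR = %.*f, n = %d%s\n",
              x$plan$label, digits, x$log_rr, digits, x$se_model,
              digits, exp(x$log_rr), x$n_used,
              if (x$converged) "" else " [NOT converged]"))
  invisible(x)
}
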
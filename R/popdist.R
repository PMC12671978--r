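#' Exact joint distribution over (sex, C, A, Y)
#'
#' Builds the 16-cell probability table implied by a scenario:
#' `P(sex) * P(C) * P(A | sex, C) * P(Y | sex, C, A)` with
#' `P(A = 1 | male, .) = 0`, `P(A = 1 | female, C) = p0 * rr_C_on_A^C`
#' (`p0` calibrated, see [calibrate_exposure_baseline()]) and
#' `P(Y = 1 | sex, C, A) = p_Y_baseline * rr_A_on_Y^A * rr_C_on_Y^C *
#' rr_sex_on_Y^male`. For a mirrored scenario the exposure column is recoded
#' `A' = 1 - A` after the outcome is generated, so men appear compelled to
#' the recoded exposure.
#'
#' This table is the package's exact oracle: every Monte Carlo quantity has a
#' population-level counterpart computed on it ([gformula_truth()],
#' [asymptotic_effect()]).
#'
#' @param spec an `eprr_scenario`.
#' @return An `eprr_joint` data frame with columns `sex` (`"female"`/
#'   `"male"`), `C`, `A`, `Y` and `probability`, summing to 1. The generating
#'   scenario is attached as attribute `"spec"`.
#' @examples
#' jt <- build_joint(scenario_preset("confounder"))
#' sum(jt$probability)
#' @export
build_joint <- function(spec) {
  stopifnot(inherits(spec, "eprr_scenario"))
  p0 <- calibrate_exposure_baseline(spec)
  grid <- expand.grid(sex = c("female", "male"), C = 0:1, A = 0:1, Y = 0:1,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  male <- as.integer(grid$sex == "male")
  pA1 <- ifelse(male == 1, 0, p0 * spec$rr_C_on_A^grid$C)
  pY1 <- spec$p_Y_baseline * spec$rr_A_on_Y^grid$A *
    spec$rr_C_on_Y^grid$C * spec$rr_sex_on_Y^male
  prob <- ifelse(male == 1, 1 - spec$p_female, spec$p_female) *
    ifelse(grid$C == 1, spec$p_C, 1 - spec$p_C) *
    ifelse(grid$A == 1, pA1, 1 - pA1) *
    ifelse(grid$Y == 1, pY1, 1 - pY1)
  if (spec$recode_exposure) grid$A <- 1L - grid$A
  out <- cbind(grid, probability = prob)
  out <- out[order(out$sex, out$C, out$A, out$Y), ]
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  class(out) <- c("eprr_joint", "data.frame")
  out
}

#' @export
print.eprr_joint <- function(x, digits = 6, ...) {
  cat("Exact joint distribution over (sex, C, A, Y); total mass",
      format(sum(x$probability)), "\n")
  print.data.frame(cbind(x[, c("sex", "C", "A", "Y")],
                         probability = signif(x$probability, digits)),
                   row.names = FALSE)
  invisible(x)
}

#' Read or write an exact joint table as CSV
#'
#' Columns `sex`, `C`, `A`, `Y`, `probability`.
#'
#' @param table an `eprr_joint`.
#' @param path file path.
#' @return `read_joint()` returns an `eprr_joint` (without a generating
#'   scenario attached); `write_joint()` returns `path` invisibly.
#' @export
write_joint <- function(table, path) {
  stopifnot(inherits(table, "eprr_joint"))
  utils::write.csv(as.data.frame(table)[, c("sex", "C", "A", "Y", "probability")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_joint
#' @export
read_joint <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "C", "A", "Y", "probability")
  if (!all(need %in% names(out)))
    stop("joint table CSV must have columns ", paste(need, collapse = ", "))
  if (abs(sum(out$probability) - 1) > 1e-8)
    stop("cell probabilities do not sum to 1")
  class(out) <- c("eprr_joint", "data.frame")
  out
}

#' Counterfactual risks by the g-formula
#'
#' Standardizes conditional outcome risks over the covariate distribution to
#' obtain `E[Y^{a}]` for `a = 0, 1` and the true log risk ratio. The default
#' target population is the exposure-potential stratum (women): they are the
#' only people for whom both exposure levels are well defined. Requesting the
#' whole population is refused unless the caller explicitly asserts that the
#' counterfactual outcome under exposure is well defined for men
#' (`assume_well_defined = TRUE`), in which case risks for men under
#' exposure are taken from the generating scenario's multiplicative risk
#' model (they have zero support in the table itself).
#'
#' @param table an `eprr_joint` built by [build_joint()].
#' @param population `"exposure_potential_only"` (women, renormalized) or
#'   `"all"`.
#' @param assume_well_defined caller's assertion that `Y^{a=1}` is well
#'   defined in the no-potential stratum; required for `population = "all"`.
#' @return An object of class `eprr_counterfactual`: list with `risk_a1`,
#'   `risk_a0`, `true_log_rr` and `population`.
#' @examples
#' jt <- build_joint(scenario_preset("instrument"))
#' gformula_truth(jt)$true_log_rr  # log(1.3)
#' @export
gformula_truth <- function(table,
                           population = c("exposure_potential_only", "all"),
                           assume_well_defined = FALSE) {
  stopifnot(inherits(table, "eprr_joint"))
  population <- match.arg(population)
  spec <- attr(table, "spec")
  if (population == "all" && !assume_well_defined)
    stop("undefined counterfactual: Y under exposure is not well defined ",
         "for the stratum with no exposure potential; pass ",
         "assume_well_defined = TRUE to assert otherwise")

  tab <- as.data.frame(table)
  if (population == "exposure_potential_only")
    tab <- tab[tab$sex == "female", , drop = FALSE]
  # covariate distribution P(sex, C) over the target population
  cov_mass <- stats::aggregate(probability ~ sex + C, tab, sum)
  cov_mass$probability <- cov_mass$probability / sum(cov_mass$probability)

  cond_risk <- function(sex, C, a) {
    sel <- tab$sex == sex & tab$C == C & tab$A == a
    denom <- sum(tab$probability[sel])
    if (denom > 0)
      return(sum(tab$probability[sel & tab$Y == 1]) / denom)
    # zero support: fall back to the generating risk model if available
    if (is.null(spec))
      stop("counterfactual risk undefined: no support for A = ", a,
           " in stratum (", sex, ", C = ", C, ") and no generating scenario")
    a_orig <- if (spec$recode_exposure) 1 - a else a
    male <- as.integer(sex == "male")
    spec$p_Y_baseline * spec$rr_A_on_Y^a_orig * spec$rr_C_on_Y^C *
      spec$rr_sex_on_Y^male
  }

  risk_a <- function(a)
    sum(mapply(function(s, cc, m) m * cond_risk(s, cc, a),
               cov_mass$sex, cov_mass$C, cov_mass$probability))

  r1 <- risk_a(1)
  r0 <- risk_a(0)
  structure(list(risk_a1 = r1, risk_a0 = r0,
                 true_log_rr = log(r1 / r0), population = population),
            class = "eprr_counterfactual")
}

#' @export
print.eprr_counterfactual <- function(x, digits = 5, ...) {
  cat(sprintf("g-formula counterfactual risks (%s population)\n",
              gsub("_", " ", x$population)))
  cat(sprintf("  E[Y^1] = %.*g, E[Y^0] = %.*g, log RR = %.*g (RR %.*g)\n",
              digits, x$risk_a1, digits, x$risk_a0,
              digits, x$true_log_rr, digits, exp(x$true_log_rr)))
  invisible(x)
}

#' Asymptotic limit of an analysis plan
#'
#' Fits the plan's log-binomial model to the exact cell probabilities (each
#' covariate pattern weighted by its population mass), giving the large-n
#' limit of the Monte Carlo mean for that plan. This is the brute-force
#' oracle behind every simulated table cell: a correctly specified plan
#' recovers the true conditional log risk ratio exactly, while a
#' mis-specified plan's limit quantifies its asymptotic bias.
#'
#' @param table an `eprr_joint`.
#' @param plan an [analysis_plan()].
#' @return The limiting log risk ratio for the exposure coefficient
#'   (a single number).
#' @examples
#' jt <- build_joint(scenario_preset("instrument"))
#' asymptotic_effect(jt, analysis_plan("Adjusted for C", "C"))  # log(1.3)
#' @export
asymptotic_effect <- function(table, plan) {
  stopifnot(inherits(table, "eprr_joint"))
  plan <- .as_plan(plan)
  dat <- as.data.frame(table)
  dat$sex <- as.integer(dat$sex == "male")
  if (plan$restrict) {
    dat <- dat[dat$sex == 0, , drop = FALSE]
    if (nrow(dat) == 0 || sum(dat$probability) == 0)
      stop("restriction empties the population")
  }
  dat <- dat[dat$probability > 0, , drop = FALSE]
  if (sum(dat$probability[dat$A == 1]) == 0)
    stop("no exposed probability mass after restriction")
  fit <- fit_log_binomial(dat, terms = c("A", plan$adjustment_set),
                          weights = dat$probability)
  unname(fit$coefficients["A"])
}
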
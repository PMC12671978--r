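# Deterministic per-iteration substream: a multiplicative mix of the base
# seed and iteration index, exact in double precision (all products < 2^53),
# reduced mod 2^31 - 2 so set.seed() always gets a valid positive integer.
.iteration_seed <- function(seed, iteration) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 69621 + as.numeric(iteration) * 181243 + 13) %% 2147483645 + 1)
}

#' Sample one cohort from a scenario
#'
#' Draws `spec$n` independent individuals: sex ~ Bernoulli(1 - p_female) for
#' male, `C` ~ Bernoulli(p_C) independently of sex, `A` from the calibrated
#' exposure model (probability 0 for men), and `Y` from the multiplicative
#' risk model. The random stream is seeded deterministically from
#' `(spec$seed, iteration)`, so any single iteration is reproducible without
#' regenerating the ones before it. For mirrored scenarios the exposure
#' column holds the recoded exposure `A' = 1 - A`.
#'
#' @param spec a valid `eprr_scenario`.
#' @param iteration non-negative iteration index.
#' @return An `eprr_cohort` data frame with binary columns `sex` (1 = male),
#'   `C`, `A`, `Y`; the generating scenario and iteration are attached as
#'   attributes `"spec"` and `"iteration"`.
#' @examples
#' cohort <- sample_cohort(scenario_preset("confounder", n = 1000L), 1L)
#' with(cohort, sum(sex == 1 & A == 1))  # men are never exposed
#' @export
sample_cohort <- function(spec, iteration = 1L) {
  stopifnot(inherits(spec, "eprr_scenario"), iteration >= 0)
  bad <- validate_spec(spec)
  if (length(bad)) stop("invalid scenario: ", paste(bad, collapse = "; "))
  p0 <- calibrate_exposure_baseline(spec)

  set.seed(.iteration_seed(spec$seed, iteration))
  n <- spec$n
  male <- stats::rbinom(n, 1L, 1 - spec$p_female)
  C <- stats::rbinom(n, 1L, spec$p_C)
  pA <- ifelse(male == 1L, 0, p0 * spec$rr_C_on_A^C)
  A <- stats::rbinom(n, 1L, pA)
  pY <- spec$p_Y_baseline * spec$rr_A_on_Y^A * spec$rr_C_on_Y^C *
    spec$rr_sex_on_Y^male
  Y <- stats::rbinom(n, 1L, pY)
  if (spec$recode_exposure) A <- 1L - A

  cohort <- data.frame(sex = male, C = C, A = A, Y = Y)
  attr(cohort, "spec") <- spec
  attr(cohort, "iteration") <- as.integer(iteration)
  class(cohort) <- c("eprr_cohort", "data.frame")
  cohort
}

#' Restrict a cohort to the exposure-potential stratum
#'
#' Drops all men (the stratum with no exposure potential) from a sampled
#' cohort; this is restriction as one way of conditioning on the
#' exposure-potential indicator. The subset is taken from the same sampled
#' cohort, so with `p_female = 0.5` and n = 10 000 the restricted analysis
#' uses about 5000 people.
#'
#' @param cohort an `eprr_cohort` (or any data frame with a binary `sex`
#'   column, 1 = male).
#' @return The female-only cohort, with generating attributes preserved.
#' @export
restrict_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort), "sex" %in% names(cohort))
  out <- cohort[cohort$sex == 0, , drop = FALSE]
  if (nrow(out) == 0)
    stop("restriction leaves an empty cohort: no individuals with exposure potential")
  rownames(out) <- NULL
  attr(out, "spec") <- attr(cohort, "spec")
  attr(out, "iteration") <- attr(cohort, "iteration")
  attr(out, "restricted") <- TRUE
  class(out) <- class(cohort)
  out
}

#' Write a cohort to CSV
#'
#' Columns `sex`, `C`, `A`, `Y`, for external cross-checking.
#'
#' @param cohort an `eprr_cohort`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  utils::write.csv(as.data.frame(cohort)[, c("sex", "C", "A", "Y")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @export
print.eprr_cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d individuals (iteration %s)\n", nrow(x),
              format(attr(x, "iteration"))))
  cat(sprintf("  %% female %.1f, %% C = 1 %.1f, %% exposed %.1f, %% with outcome %.1f\n",
              100 * mean(x$sex == 0), 100 * mean(x$C), 100 * mean(x$A),
              100 * mean(x$Y)))
  invisible(x)
}
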
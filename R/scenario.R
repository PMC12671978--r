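#' Define a data-generating scenario
#'
#' A scenario bundles every generative parameter of the multiplicative-risk
#' mechanism: a binary exposure-potential indicator (sex; men have zero
#' probability of exposure), a binary confounder `C`, a binary exposure `A`
#' available only to women, and a binary outcome `Y` whose risk is purely
#' multiplicative in `A`, `C` and sex (no product terms on the risk-ratio
#' scale).
#'
#' The baseline exposure probability among women with `C = 0` is not a free
#' parameter: it is calibrated so that the marginal exposure prevalence among
#' women equals `target_exposure_prev` (see
#' [calibrate_exposure_baseline()]).
#'
#' @param rr_A_on_Y conditional risk ratio of exposure on outcome (the target
#'   effect).
#' @param rr_C_on_A risk ratio of the confounder on exposure among women.
#' @param rr_C_on_Y risk ratio of the confounder on outcome.
#' @param rr_sex_on_Y risk ratio for male vs female on outcome; `0.75` makes
#'   sex a confounder, `1` makes it an instrumental variable.
#' @param p_female probability of belonging to the exposure-potential stratum.
#' @param p_C prevalence of the binary confounder.
#' @param p_Y_baseline outcome risk for an unexposed woman with `C = 0`.
#' @param target_exposure_prev marginal `Pr[A = 1 | female]` the baseline is
#'   calibrated to.
#' @param n cohort size per simulation iteration.
#' @param iterations number of Monte Carlo replicates.
#' @param seed base random seed; each iteration gets its own substream.
#' @param recode_exposure if `TRUE` the analysed exposure is the recoded
#'   `A' = 1 - A`, turning lack of exposure potential into exposure
#'   compulsion (see [mirror_compulsion()]).
#' @param label optional scenario label used in printed reports.
#'
#' @return An object of class `eprr_scenario`: a named list of the parameters
#'   above.
#' @seealso [scenario_preset()], [validate_spec()], [build_joint()],
#'   [sample_cohort()]
#' @examples
#' spec <- scenario_spec(rr_sex_on_Y = 1, label = "instrument")
#' validate_spec(spec)
#' true_log_rr(spec)
#' @export
scenario_spec <- function(rr_A_on_Y = 1.3,
                          rr_C_on_A = 1.75,
                          rr_C_on_Y = 1.75,
                          rr_sex_on_Y = 0.75,
                          p_female = 0.5,
                          p_C = 0.5,
                          p_Y_baseline = 0.10,
                          target_exposure_prev = 0.69,
                          n = 10000L,
                          iterations = 1000L,
                          seed = 1L,
                          recode_exposure = FALSE,
                          label = NULL) {
  spec <- list(
    rr_A_on_Y = as.numeric(rr_A_on_Y),
    rr_C_on_A = as.numeric(rr_C_on_A),
    rr_C_on_Y = as.numeric(rr_C_on_Y),
    rr_sex_on_Y = as.numeric(rr_sex_on_Y),
    p_female = as.numeric(p_female),
    p_C = as.numeric(p_C),
    p_Y_baseline = as.numeric(p_Y_baseline),
    target_exposure_prev = as.numeric(target_exposure_prev),
    n = as.integer(n),
    iterations = as.integer(iterations),
    seed = as.integer(seed),
    recode_exposure = isTRUE(recode_exposure),
    label = label
  )
  class(spec) <- "eprr_scenario"
  spec
}

#' Packaged scenario presets
#'
#' Two presets cover the study's data-generating mechanisms: `"confounder"`
#' (sex is independently preventive of the outcome, RR = 0.75) and
#' `"instrument"` (sex affects the outcome only through exposure, RR = 1).
#' Presets are stored as plain YAML under `inst/extdata` with exactly the
#' [scenario_spec()] field names.
#'
#' @param preset `"confounder"` or `"instrument"`.
#' @param ... overrides passed on to [scenario_spec()] (e.g. `seed`,
#'   `iterations`).
#' @return An `eprr_scenario`.
#' @examples
#' scenario_preset("instrument", seed = 7L)
#' @export
scenario_preset <- function(preset = c("confounder", "instrument"), ...) {
  preset <- match.arg(preset)
  path <- system.file("extdata", paste0("scenario-", preset, ".yaml"),
                      package = "eprr", mustWork = TRUE)
  spec <- read_scenario(path)
  overrides <- list(...)
  for (field in names(overrides)) spec[[field]] <- overrides[[field]]
  do.call(scenario_spec, spec[setdiff(names(spec), NULL)])
}

#' Validate a scenario
#'
#' Checks every structural invariant of the generative model and reports
#' violations without raising: probabilities in \[0, 1\], risk ratios
#' positive, no cell risk above 1
#' (`p_Y_baseline * rr_A_on_Y * rr_C_on_Y * max(1, rr_sex_on_Y) <= 1`), and
#' the calibration bound (the calibrated baseline exposure probability times
#' `rr_C_on_A` must not exceed 1).
#'
#' @param spec an `eprr_scenario`.
#' @return A character vector of violation messages; empty when the scenario
#'   is valid.
#' @export
validate_spec <- function(spec) {
  stopifnot(inherits(spec, "eprr_scenario"))
  bad <- character(0)
  probs <- c("p_female", "p_C", "p_Y_baseline", "target_exposure_prev")
  for (f in probs) {
    v <- spec[[f]]
    if (!is.finite(v) || v < 0 || v > 1)
      bad <- c(bad, sprintf("%s = %g outside [0, 1]", f, v))
  }
  rrs <- c("rr_A_on_Y", "rr_C_on_A", "rr_C_on_Y", "rr_sex_on_Y")
  for (f in rrs) {
    v <- spec[[f]]
    if (!is.finite(v) || v <= 0)
      bad <- c(bad, sprintf("%s = %g must be > 0", f, v))
  }
  if (!is.finite(spec$n) || spec$n < 1)
    bad <- c(bad, sprintf("n = %s must be a positive integer", spec$n))
  if (!is.finite(spec$iterations) || spec$iterations < 1)
    bad <- c(bad, sprintf("iterations = %s must be a positive integer",
                          spec$iterations))
  if (length(bad)) return(bad)

  max_risk <- spec$p_Y_baseline * spec$rr_A_on_Y * spec$rr_C_on_Y *
    max(1, spec$rr_sex_on_Y)
  if (max_risk > 1)
    bad <- c(bad, sprintf(
      "cell risk > 1: p_Y_baseline x rr_A_on_Y x rr_C_on_Y x max(1, rr_sex_on_Y) = %g",
      max_risk))

  p0 <- .calibrate_p0(spec)
  if (p0 > 1)
    bad <- c(bad, sprintf(
      "calibration bound: baseline exposure probability %g > 1", p0))
  if (spec$p_C > 0 && p0 * spec$rr_C_on_A > 1)
    bad <- c(bad, sprintf(
      "calibration bound: baseline exposure probability x rr_C_on_A = %g > 1",
      p0 * spec$rr_C_on_A))
  bad
}

# closed-form solve of p0 * [(1 - p_C) + rr_C_on_A * p_C] = target
.calibrate_p0 <- function(spec) {
  spec$target_exposure_prev /
    ((1 - spec$p_C) + spec$rr_C_on_A * spec$p_C)
}

#' Calibrate the baseline exposure probability
#'
#' Solves for `p0 = Pr[A = 1 | female, C = 0]` such that the marginal
#' exposure prevalence among women,
#' `p0 * ((1 - p_C) + rr_C_on_A * p_C)`, equals `target_exposure_prev`.
#' The solve is exact (the constraint is linear in `p0`).
#'
#' @param spec an `eprr_scenario` that passes [validate_spec()].
#' @return The calibrated probability `p0`.
#' @examples
#' calibrate_exposure_baseline(scenario_preset("confounder"))  # 0.69 / 1.375
#' @export
calibrate_exposure_baseline <- function(spec) {
  bad <- validate_spec(spec)
  if (length(bad)) stop("invalid scenario: ", paste(bad, collapse = "; "))
  p0 <- .calibrate_p0(spec)
  if (p0 > 1 || (spec$p_C > 0 && p0 * spec$rr_C_on_A > 1))
    stop("calibration infeasible: implied exposure probability exceeds 1")
  p0
}

#' Mirror a scenario into its exposure-compulsion form
#'
#' Lack of exposure potential (`Pr[A = 1 | men] = 0`) and exposure compulsion
#' (`Pr[A' = 1 | men] = 1`) are two sides of the same coin: recoding the
#' exposure as `A' = 1 - A` turns one into the other. The mirrored scenario
#' generates identical data but analyses the recoded exposure, whose true
#' conditional risk ratio is `1 / rr_A_on_Y`. Mirroring twice restores the
#' original scenario.
#'
#' @param spec an `eprr_scenario`.
#' @return The mirrored `eprr_scenario`.
#' @examples
#' m <- mirror_compulsion(scenario_preset("instrument"))
#' exp(true_log_rr(m))  # 1 / 1.3
#' @export
mirror_compulsion <- function(spec) {
  stopifnot(inherits(spec, "eprr_scenario"))
  spec$recode_exposure <- !spec$recode_exposure
  spec
}

#' True conditional log risk ratio of the analysed exposure
#'
#' `log(rr_A_on_Y)` for an ordinary scenario, `-log(rr_A_on_Y)` when the
#' exposure is recoded ([mirror_compulsion()]). This is the estimand every
#' bias in the package is measured against.
#'
#' @param spec an `eprr_scenario`.
#' @return A number (log risk ratio).
#' @export
true_log_rr <- function(spec) {
  stopifnot(inherits(spec, "eprr_scenario"))
  s <- if (spec$recode_exposure) -1 else 1
  s * log(spec$rr_A_on_Y)
}

#' @export
print.eprr_scenario <- function(x, ...) {
  lab <- if (is.null(x$label)) "unnamed" else x$label
  cat("Scenario:", lab,
      if (x$recode_exposure) "(exposure recoded: compulsion form)" else "",
      "\n")
  cat(sprintf("  risk ratios: A->Y %.3g, C->A %.3g, C->Y %.3g, male->Y %.3g\n",
              x$rr_A_on_Y, x$rr_C_on_A, x$rr_C_on_Y, x$rr_sex_on_Y))
  cat(sprintf("  p_female %.3g, p_C %.3g, baseline risk %.3g, target Pr[A=1|female] %.3g\n",
              x$p_female, x$p_C, x$p_Y_baseline, x$target_exposure_prev))
  cat(sprintf("  n = %d per iteration, %d iterations, seed %d\n",
              x$n, x$iterations, x$seed))
  invisible(x)
}

.scenario_fields <- c(
  "rr_A_on_Y", "rr_C_on_A", "rr_C_on_Y", "rr_sex_on_Y",
  "p_female", "p_C", "p_Y_baseline", "target_exposure_prev",
  "n", "iterations", "seed", "recode_exposure", "label"
)

#' Read or write a scenario configuration file
#'
#' Flat key-value configuration with exactly the [scenario_spec()] field
#' names; the format is chosen from the extension (`.yaml`/`.yml` or
#' `.json`). Unknown keys are rejected.
#'
#' @param path file path.
#' @param spec an `eprr_scenario`.
#' @return `read_scenario()` returns an `eprr_scenario`; `write_scenario()`
#'   returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext)
  )
  # YAML 1.1 reads a bare `n` key as the boolean FALSE; undo that
  names(raw)[names(raw) %in% c("FALSE", "F")] <- "n"
  unknown <- setdiff(names(raw), .scenario_fields)
  if (length(unknown))
    stop("unknown scenario fields: ", paste(unknown, collapse = ", "))
  do.call(scenario_spec, raw)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(spec, path) {
  stopifnot(inherits(spec, "eprr_scenario"))
  out <- unclass(spec)
  out <- out[!vapply(out, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(out, path),
    json = jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported config format: .", ext)
  )
  invisible(path)
}
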
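# Normalize a cohort (binary records) or an exact joint table to rows with
# columns male, C, A, Y and a weight column (1 per record, or cell mass).
.as_weighted <- function(data) {
  stopifnot(is.data.frame(data))
  if ("probability" %in% names(data)) {
    male <- if (is.character(data$sex) || is.factor(data$sex))
      as.integer(as.character(data$sex) == "male") else as.integer(data$sex)
    data.frame(male = male, C = data$C, A = data$A, Y = data$Y,
               w = data$probability)
  } else {
    data.frame(male = as.integer(data$sex), C = data$C, A = data$A,
               Y = data$Y, w = 1)
  }
}

#' Decompose the pooled unexposed outcome mean
#'
#' When people without exposure potential are pooled into the unexposed
#' group, the unexposed mean becomes a weighted average across the two
#' exposure-potential strata:
#' `E[Y | A=0] = E[Y | A=0, Z=1] P(Z=1 | A=0) + E[Y | A=0, Z=0] P(Z=0 | A=0)`
#' (`Z = 1` for women). This function returns every piece of that identity,
#' which holds exactly on any cohort or exact joint table.
#'
#' @param data an `eprr_cohort`, or an `eprr_joint` for the exact version.
#' @return A list with `overall` (`E[Y | A=0]`), `mean_z1`, `mean_z0`
#'   (per-stratum unexposed means) and `weight_z1`, `weight_z0`
#'   (`P(Z = z | A = 0)`).
#' @examples
#' pooled_unexposed_mean(build_joint(scenario_preset("instrument")))
#' @export
pooled_unexposed_mean <- function(data) {
  d <- .as_weighted(data)
  d <- d[d$A == 0, , drop = FALSE]
  if (nrow(d) == 0 || sum(d$w) == 0)
    stop("no unexposed individuals in the data")
  wmean <- function(sel) {
    denom <- sum(d$w[sel])
    if (denom == 0) NA_real_ else sum(d$w[sel & d$Y == 1]) / denom
  }
  total <- sum(d$w)
  w1 <- sum(d$w[d$male == 0]) / total
  list(
    overall = wmean(rep(TRUE, nrow(d))),
    mean_z1 = wmean(d$male == 0),
    mean_z0 = wmean(d$male == 1),
    weight_z1 = w1,
    weight_z0 = 1 - w1
  )
}

#' Compare unexposed means across exposure-potential strata
#'
#' Computes `E[Y | A=0, Z=1] - E[Y | A=0, Z=0]`, the observable contrast
#' behind the partial exchangeability assumption `Y^{a=0} independent of Z`.
#' The contrast is a valid test of that assumption only when there is no
#' open backdoor path between exposure and outcome: conditioning on `A = 0`
#' makes the exposure a collider, so with residual confounding the contrast
#' can be nonzero even when partial exchangeability holds by construction
#' (unexposed women are depleted of the confounder relative to men, who are
#' all unexposed). Whether a backdoor path is open is structural knowledge
#' the caller must supply; it is not inferred from data.
#'
#' @param data an `eprr_cohort` or `eprr_joint`.
#' @param backdoor_open is there an open (unadjusted) backdoor path between
#'   exposure and outcome?
#' @return A list with `difference` and `interpretable` (`FALSE` when the
#'   backdoor path is open, meaning the difference does not test partial
#'   exchangeability).
#' @examples
#' jt <- build_joint(scenario_preset("instrument"))
#' partial_exchangeability_check(jt, backdoor_open = TRUE)
#' @export
partial_exchangeability_check <- function(data, backdoor_open) {
  stopifnot(is.logical(backdoor_open), length(backdoor_open) == 1)
  dec <- pooled_unexposed_mean(data)
  if (is.na(dec$mean_z1) || is.na(dec$mean_z0))
    stop("both exposure-potential strata must contain unexposed individuals")
  list(difference = dec$mean_z1 - dec$mean_z0,
       interpretable = !backdoor_open)
}

#' Positivity report over an adjustment set
#'
#' Exposure prevalence (propensity) per joint level of the adjustment
#' variables, flagging strata with zero prevalence. Positivity is violated
#' only when sex is in the adjustment set — then the male strata are
#' structural zero cells, since men have no exposure potential; adjusting
#' for the confounder alone leaves every stratum with exposed members.
#'
#' @param data an `eprr_cohort` or `eprr_joint`.
#' @param adjustment_set subset of `c("C", "sex")` (may be empty).
#' @return An object of class `eprr_positivity`: list with `strata` (a data
#'   frame of covariate pattern, exposure prevalence and count/mass),
#'   `zero_cells` (patterns with prevalence 0) and `target_population_note`.
#' @examples
#' positivity_report(build_joint(scenario_preset("confounder")), "sex")
#' @export
positivity_report <- function(data, adjustment_set = character(0)) {
  adjustment_set <- as.character(adjustment_set)
  extra <- setdiff(adjustment_set, c("C", "sex"))
  if (length(extra))
    stop("adjustment_set must be a subset of {C, sex}")
  d <- .as_weighted(data)
  d$sex <- d$male
  if (length(adjustment_set)) {
    key <- interaction(d[adjustment_set], drop = FALSE, sep = ", ")
    labs <- paste(rep(adjustment_set, each = nlevels(key)),
                  do.call(rbind, strsplit(levels(key), ", ")), sep = " = ")
    labs <- apply(matrix(labs, nrow = nlevels(key)), 1, paste,
                  collapse = ", ")
  } else {
    key <- factor(rep("all", nrow(d)))
    labs <- "all"
  }
  prev <- vapply(levels(key), function(l) {
    sel <- key == l
    tot <- sum(d$w[sel])
    if (tot == 0) NA_real_ else sum(d$w[sel & d$A == 1]) / tot
  }, numeric(1))
  count <- vapply(levels(key), function(l) sum(d$w[key == l]), numeric(1))
  strata <- data.frame(pattern = labs, exposure_prevalence = unname(prev),
                       count = unname(count), stringsAsFactors = FALSE)
  strata <- strata[!is.na(strata$exposure_prevalence), , drop = FALSE]
  note <- if ("sex" %in% adjustment_set)
    paste("Positivity is violated: sex is in the adjustment set and the male",
          "strata have zero exposure prevalence. The only valid target",
          "population is the exposure-potential stratum (women).")
  else
    paste("Positivity holds over this adjustment set: no stratum has zero",
          "exposure prevalence, because exposed women exist in every",
          "confounder stratum.")
  structure(list(strata = strata,
                 zero_cells = strata$pattern[strata$exposure_prevalence == 0],
                 target_population_note = note),
            class = "eprr_positivity")
}

#' @export
print.eprr_positivity <- function(x, digits = 4, ...) {
  cat("Positivity report\n")
  out <- x$strata
  out$exposure_prevalence <- signif(out$exposure_prevalence, digits)
  print.data.frame(out, row.names = FALSE)
  if (length(x$zero_cells))
    cat("Zero cells:", paste(x$zero_cells, collapse = "; "), "\n")
  cat(strwrap(x$target_population_note, width = 76), sep = "\n")
  invisible(x)
}

.restriction_verdicts <- list(
  confounder_clean = "Restriction on Z will prevent bias caused by Z",
  confounder_residual = paste("Restriction on Z will prevent bias caused by",
                              "Z; the residual bias will remain"),
  instrument_clean = paste("Restriction on Z will not affect bias but can",
                           "decrease precision"),
  instrument_residual = "Restriction on Z will amplify the residual bias"
)

#' Classify how restriction on the exposure-potential indicator affects bias
#'
#' The four-scenario taxonomy: the effect of restricting on `Z` (the reason
#' for no exposure potential) depends on whether `Z` is itself a confounder
#' and whether residual bias (e.g. uncontrolled confounding by `C`) is
#' present. When `Z` is not a confounder it is an instrumental variable, and
#' restricting on it amplifies any residual bias.
#'
#' @param z_is_confounder is `Z` a confounder of the exposure-outcome
#'   relation?
#' @param residual_bias_present is residual bias (uncontrolled confounding)
#'   present?
#' @return The matching verdict, as a character string.
#' @examples
#' classify_restriction_effect(FALSE, TRUE)
#' @export
classify_restriction_effect <- function(z_is_confounder,
                                        residual_bias_present) {
  stopifnot(is.logical(z_is_confounder), is.logical(residual_bias_present))
  key <- paste0(if (z_is_confounder) "confounder" else "instrument",
                if (residual_bias_present) "_residual" else "_clean")
  .restriction_verdicts[[key]]
}
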
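#' Summarize Monte Carlo estimates against the truth
#'
#' Given per-iteration log risk ratio estimates and the true conditional log
#' risk ratio, computes the reporting columns: mean log RR, empirical SE
#' (sample SD of the estimates), bias (mean minus truth), MSE (mean squared
#' deviation from truth, so `mse = bias^2 + population variance` exactly),
#' and the exponentiated point estimate with a normal-theory interval
#' `exp(mean +/- 1.96 * SE)`.
#'
#' @param estimates numeric vector of at least two per-iteration log RR
#'   estimates.
#' @param truth_log_rr true conditional log risk ratio.
#' @return A named list with `mean_log_rr`, `se_empirical`, `bias`, `mse`,
#'   `rr_point`, `rr_ci_low`, `rr_ci_high`, `n_iterations_used`.
#' @examples
#' summarize_estimates(c(0.2, 0.3), 0.25)
#' @export
summarize_estimates <- function(estimates, truth_log_rr) {
  estimates <- estimates[is.finite(estimates)]
  if (length(estimates) < 2)
    stop("need at least two estimates to summarize")
  m <- mean(estimates)
  s <- stats::sd(estimates)
  list(
    mean_log_rr = m,
    se_empirical = s,
    bias = m - truth_log_rr,
    mse = mean((estimates - truth_log_rr)^2),
    rr_point = exp(m),
    rr_ci_low = exp(m - 1.96 * s),
    rr_ci_high = exp(m + 1.96 * s),
    n_iterations_used = length(estimates)
  )
}

#' Run one scenario across analysis plans
#'
#' For each iteration a single cohort is sampled and every plan is evaluated
#' on it (shared cohorts make between-plan contrasts exact and less noisy).
#' Nonconverged or failed fits are dropped from the summaries and counted;
#' a plan whose drop rate reaches 50% aborts the run, since that signals a
#' mis-specified scenario rather than occasional boundary trouble.
#'
#' @param spec a valid `eprr_scenario`.
#' @param plans list of [analysis_plan()]s (default [canonical_plans()]).
#' @param iterations number of Monte Carlo replicates (default
#'   `spec$iterations`).
#' @param progress print a progress message every 100 iterations?
#' @return An object of class `eprr_sim`: list with `summary` (one row per
#'   plan with the [summarize_estimates()] columns plus `n_dropped`),
#'   `estimates` (iterations x plans matrix of per-iteration log RRs, `NA`
#'   where dropped), `spec`, `plans` and `truth_log_rr`.
#' @examples
#' spec <- scenario_preset("instrument", n = 1000L, iterations = 20L, seed = 9L)
#' run_scenario(spec, list(analysis_plan("Adjusted for C", "C")))
#' @export
run_scenario <- function(spec, plans = canonical_plans(),
                         iterations = spec$iterations, progress = FALSE) {
  stopifnot(inherits(spec, "eprr_scenario"), length(plans) >= 1)
  iterations <- as.integer(iterations)
  if (iterations < 1) stop("iterations must be >= 1")
  bad <- validate_spec(spec)
  if (length(bad)) stop("invalid scenario: ", paste(bad, collapse = "; "))

  labels <- vapply(plans, function(p) .as_plan(p)$label, character(1))
  est <- matrix(NA_real_, iterations, length(plans),
                dimnames = list(NULL, labels))
  for (i in seq_len(iterations)) {
    cohort <- sample_cohort(spec, i)
    for (j in seq_along(plans)) {
      e <- tryCatch(estimate_effect(cohort, plans[[j]]),
                    error = function(err) NULL)
      if (!is.null(e) && e$converged) est[i, j] <- e$log_rr
    }
    if (progress && i %% 100 == 0)
      message(sprintf("  iteration %d / %d", i, iterations))
  }

  truth <- true_log_rr(spec)
  rows <- lapply(seq_along(plans), function(j) {
    kept <- est[, j][!is.na(est[, j])]
    dropped <- iterations - length(kept)
    if (dropped / iterations >= 0.5)
      stop(sprintf("plan '%s': %d of %d fits dropped; scenario/plan looks mis-specified",
                   labels[j], dropped, iterations))
    s <- summarize_estimates(kept, truth)
    data.frame(plan_label = labels[j], mean_log_rr = s$mean_log_rr,
               se_empirical = s$se_empirical, bias = s$bias, mse = s$mse,
               rr_point = s$rr_point, rr_ci_low = s$rr_ci_low,
               rr_ci_high = s$rr_ci_high,
               n_iterations_used = s$n_iterations_used, n_dropped = dropped,
               stringsAsFactors = FALSE)
  })
  structure(list(summary = do.call(rbind, rows), estimates = est,
                 spec = spec, plans = plans, truth_log_rr = truth),
            class = "eprr_sim")
}

#' @export
print.eprr_sim <- function(x, digits = 3, ...) {
  lab <- if (is.null(x$spec$label)) "scenario" else x$spec$label
  cat(sprintf("Monte Carlo summary: %s (n = %d, %d iterations, true log RR %.4f)\n",
              lab, x$spec$n, nrow(x$estimates), x$truth_log_rr))
  out <- x$summary
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) signif(v, digits))
  print.data.frame(out, row.names = FALSE)
  invisible(x)
}

#' Bias bar chart of a simulation run
#'
#' @param x an `eprr_sim` or `eprr_table2`.
#' @param ... passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot.eprr_sim <- function(x, ...) {
  graphics::barplot(x$summary$bias, names.arg = x$summary$plan_label,
                    las = 2, ylab = "bias (log RR scale)",
                    cex.names = 0.7, ...)
}

.scenario_section_labels <- c(
  confounder = "Sex as a confounder",
  instrument = "Sex as an instrumental variable"
)

#' Run the full 12-cell simulation grid
#'
#' Evaluates the six canonical plans under the confounder scenario and the
#' instrument scenario (12 cells), sharing cohorts across plans within an
#' iteration.
#'
#' @param confounder_spec,instrument_spec the two scenarios (defaults: the
#'   packaged presets).
#' @param iterations optional override of both scenarios' iteration counts.
#' @param progress print per-cell progress?
#' @return An `eprr_table2` data frame with columns `scenario`, `row`,
#'   `analysis`, `log_rr`, `se`, `bias`, `mse`, `rr`, `ci_low`, `ci_high`,
#'   `n_dropped`; the two underlying `eprr_sim` runs are attached as
#'   attribute `"runs"` (for per-iteration access).
#' @examples
#' \donttest{
#' grid <- run_table2(iterations = 50L)
#' grid
#' }
#' @export
run_table2 <- function(confounder_spec = scenario_preset("confounder"),
                       instrument_spec = scenario_preset("instrument"),
                       iterations = NULL, progress = FALSE) {
  plans <- canonical_plans()
  specs <- list(confounder = confounder_spec, instrument = instrument_spec)
  runs <- list()
  pieces <- list()
  row0 <- 0L
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    its <- if (is.null(iterations)) spec$iterations else as.integer(iterations)
    if (progress) message("Scenario: ", .scenario_section_labels[[nm]])
    run <- run_scenario(spec, plans, iterations = its, progress = progress)
    runs[[nm]] <- run
    s <- run$summary
    pieces[[nm]] <- data.frame(
      scenario = .scenario_section_labels[[nm]],
      row = row0 + seq_len(nrow(s)),
      analysis = s$plan_label,
      log_rr = s$mean_log_rr, se = s$se_empirical, bias = s$bias,
      mse = s$mse, rr = s$rr_point, ci_low = s$rr_ci_low,
      ci_high = s$rr_ci_high, n_dropped = s$n_dropped,
      stringsAsFactors = FALSE)
    row0 <- row0 + nrow(s)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "runs") <- runs
  class(out) <- c("eprr_table2", "data.frame")
  out
}

#' @export
print.eprr_table2 <- function(x, ...) {
  cat("Monte Carlo bias and error of six analysis plans under two scenarios\n\n")
  fmt <- data.frame(
    row = x$row, analysis = x$analysis,
    log_rr = sprintf("%.2f", x$log_rr), se = sprintf("%.2f", x$se),
    bias = sprintf("%.2f", x$bias), mse = sprintf("%.3f", x$mse),
    rr = sprintf("%.2f (%.2f-%.2f)", x$rr, x$ci_low, x$ci_high),
    dropped = x$n_dropped, stringsAsFactors = FALSE)
  for (sc in unique(x$scenario)) {
    cat(sc, "\n")
    print.data.frame(fmt[x$scenario == sc, ], row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' @rdname plot.eprr_sim
#' @export
plot.eprr_table2 <- function(x, ...) {
  graphics::barplot(x$bias, names.arg = paste(x$row, x$analysis), las = 2,
                    ylab = "bias (log RR scale)", cex.names = 0.6,
                    col = ifelse(grepl("confounder", x$scenario), "grey40",
                                 "grey75"), ...)
}

#' Write a simulation grid report to CSV
#'
#' Columns exactly: scenario, row, analysis, log_rr, se, bias, mse, rr,
#' ci_low, ci_high, n_dropped.
#'
#' @param report an `eprr_table2`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eprr_table2"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Asymptotic limits for the 12-cell grid
#'
#' The exact-oracle counterpart of [run_table2()]: each cell's limiting log
#' risk ratio from a population-level fit on the joint table, with the
#' implied asymptotic bias.
#'
#' @inheritParams run_table2
#' @return A data frame with columns `scenario`, `analysis`, `log_rr`,
#'   `bias`.
#' @export
oracle_table <- function(confounder_spec = scenario_preset("confounder"),
                         instrument_spec = scenario_preset("instrument")) {
  plans <- canonical_plans()
  specs <- list(confounder = confounder_spec, instrument = instrument_spec)
  out <- do.call(rbind, lapply(names(specs), function(nm) {
    spec <- specs[[nm]]
    jt <- build_joint(spec)
    truth <- true_log_rr(spec)
    lim <- vapply(plans, function(p) asymptotic_effect(jt, p), numeric(1))
    data.frame(scenario = .scenario_section_labels[[nm]],
               analysis = vapply(plans, `[[`, character(1), "label"),
               log_rr = lim, bias = lim - truth, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
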
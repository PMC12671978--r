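test_that("the A + sex model is saturated on its three observed categories", {
  # with terms {A, sex} the three observed patterns (exposed woman, unexposed
  # woman, unexposed man) each get their own fitted mean, so the exposure
  # coefficient is the closed-form female cell contrast
  cohort <- sample_cohort(scenario_preset("confounder", seed = 12L), 1L)
  fit <- fit_log_binomial(cohort, c("A", "sex"))
  women <- cohort[cohort$sex == 0, ]
  closed_form <- log(mean(women$Y[women$A == 1]) /
                       mean(women$Y[women$A == 0]))
  expect_equal(unname(coef(fit)["A"]), closed_form, tolerance = 1e-10)
  # and each fitted probability reproduces its category mean
  men_mean <- mean(cohort$Y[cohort$sex == 1])
  expect_equal(unname(predict(fit, data.frame(A = 0, sex = 1))), men_mean,
               tolerance = 1e-10)
})

test_that("adjusting for sex and restricting on sex give identical exposure coefficients per cohort", {
  adj <- analysis_plan("Adjusted for sex", "sex")
  restr <- analysis_plan("Restriction on sex", restrict = TRUE)
  for (it in 1:5) {
    cohort <- sample_cohort(small_instrument(), it)
    e1 <- estimate_effect(cohort, adj)
    e2 <- estimate_effect(cohort, restr)
    expect_equal(e1$log_rr, e2$log_rr, tolerance = 1e-10)
  }
})

test_that("degenerate inputs are refused with informative errors", {
  d <- data.frame(A = c(0, 1, 0, 1), C = c(0, 0, 1, 1), Y = c(0, 0, 0, 0))
  expect_error(fit_log_binomial(d, "A"), "no variation in outcome")
  d$Y <- c(1, 0, 1, 0)
  d$A <- 0
  expect_error(fit_log_binomial(d, "A"), "no variation in covariate 'A'")
  expect_error(fit_log_binomial(d, c("A", "Z")), "not found")
  expect_error(fit_log_binomial(data.frame(A = 0:1, Y = c(0.5, 1)), "A"),
               "binary")
  expect_error(fit_log_binomial(data.frame(A = 0:1, Y = 0:1), "A",
                                weights = c(-1, 2)), "non-negative")
})

test_that("a boundary maximum is reported as nonconverged, never silently", {
  # every exposed subject has the outcome: the MLE pushes the exposed fitted
  # risk to 1 (boundary of the log-binomial parameter space)
  d <- data.frame(A = c(1, 0, 0), Y = c(1, 1, 0), w = c(10, 2, 8))
  fit <- fit_log_binomial(d, "A", weights = d$w)
  expect_false(fit$converged)
  expect_true(fit$boundary)
})

test_that("the population-weighted fit on the instrument table recovers the true risk ratio", {
  jt <- build_joint(scenario_preset("instrument"))
  dat <- as.data.frame(jt)
  dat$sex <- as.integer(dat$sex == "male")
  dat <- dat[dat$probability > 0, ]
  fit <- fit_log_binomial(dat, c("A", "C"), weights = dat$probability)
  expect_equal(unname(coef(fit)["A"]), log(1.3), tolerance = 1e-8)
})

test_that("the damped IRLS fit agrees with glm's log-binomial fit", {
  cohort <- sample_cohort(scenario_preset("confounder", seed = 8L), 1L)
  fit <- fit_log_binomial(cohort, c("A", "C", "sex"))
  expect_true(fit$converged)
  ref <- stats::glm(Y ~ A + C + sex, data = cohort,
                    family = stats::binomial(link = "log"),
                    start = coef(fit))
  expect_equal(unname(coef(fit)), unname(stats::coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-4)
})

test_that("model-based standard errors track the empirical sampling spread", {
  spec <- scenario_preset("instrument", n = 10000L, seed = 55L)
  plan <- analysis_plan("Adjusted for C", "C")
  fits <- lapply(1:150, function(i)
    estimate_effect(sample_cohort(spec, i), plan))
  log_rrs <- vapply(fits, `[[`, numeric(1), "log_rr")
  model_se <- mean(vapply(fits, `[[`, numeric(1), "se_model"))
  expect_lt(abs(model_se - sd(log_rrs)) / sd(log_rrs), 0.20)
})

test_that("restricting before estimation equals estimating with the restriction flag", {
  cohort <- sample_cohort(small_confounder(), 2L)
  via_flag <- estimate_effect(cohort, analysis_plan("flagged", "C",
                                                    restrict = TRUE))
  via_subset <- estimate_effect(restrict_cohort(cohort),
                                analysis_plan("subset", "C"))
  expect_equal(via_flag$log_rr, via_subset$log_rr, tolerance = 1e-12)
  expect_equal(via_flag$n_used, via_subset$n_used)
})

test_that("analysis plans reject incoherent recipes", {
  expect_error(analysis_plan("bad", c("C", "sex"), restrict = TRUE),
               "incompatible")
  expect_error(analysis_plan("bad", "age"), "subset")
})
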
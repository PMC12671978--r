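test_that("the pooled unexposed mean decomposes exactly into per-stratum means and weights", {
  # exact table and a sampled cohort: reconstruction identity to 1e-12
  jt <- build_joint(scenario_preset("instrument"))
  cohort <- sample_cohort(small_confounder(), 1L)
  for (data in list(jt, cohort)) {
    d <- pooled_unexposed_mean(data)
    expect_equal(d$overall,
                 d$mean_z1 * d$weight_z1 + d$mean_z0 * d$weight_z0,
                 tolerance = 1e-12)
    expect_equal(d$weight_z1 + d$weight_z0, 1, tolerance = 1e-12)
  }
})

test_that("the decomposition arithmetic matches hand-built data", {
  # women: 2 unexposed with means 0.2; men: 2 unexposed with mean 0.1,
  # equal weights -> overall 0.15
  d <- data.frame(sex = c(0, 0, 1, 1, 0), C = 0,
                  A = c(0, 0, 0, 0, 1),
                  Y = c(0, 1, 0, 1, 1))
  d$Y[1:2] <- c(0, 1)   # mean 0.5 among unexposed women
  d$Y[3:4] <- c(0, 0)   # mean 0 among men
  dec <- pooled_unexposed_mean(d)
  expect_equal(dec$mean_z1, 0.5)
  expect_equal(dec$mean_z0, 0)
  expect_equal(dec$overall, 0.25)

  equal_means <- data.frame(sex = c(0, 1), C = 0, A = 0, Y = c(0, 0))
  equal_means$Y <- c(1, 1)
  expect_equal(pooled_unexposed_mean(equal_means)$overall, 1)

  expect_error(pooled_unexposed_mean(data.frame(sex = 0, C = 0, A = 1,
                                                Y = 1)), "no unexposed")
})

test_that("unexposed means differ across strata only through direct effects or collider paths", {
  # no C->A arrow and no direct sex effect: nothing connects sex to the
  # unexposed outcome, so the exact-table contrast vanishes
  clean <- scenario_spec(rr_C_on_A = 1, rr_sex_on_Y = 1)
  chk <- partial_exchangeability_check(build_joint(clean),
                                       backdoor_open = FALSE)
  expect_equal(chk$difference, 0, tolerance = 1e-12)
  expect_true(chk$interpretable)

  # direct sex effect: contrast nonzero and interpretable once the backdoor
  # path through C is closed by design knowledge
  conf <- partial_exchangeability_check(build_joint(scenario_preset("confounder")),
                                        backdoor_open = FALSE)
  expect_gt(abs(conf$difference), 0.01)

  # instrument scenario: partial exchangeability holds by construction, yet
  # the observable contrast is nonzero because conditioning on A = 0 opens a
  # collider path (unexposed women are depleted of C); flagged uninterpretable
  inst <- partial_exchangeability_check(build_joint(scenario_preset("instrument")),
                                        backdoor_open = TRUE)
  expect_gt(abs(inst$difference), 0.01)
  expect_false(inst$interpretable)
})

test_that("positivity reports flag male strata only when sex is adjusted for", {
  jt <- build_joint(scenario_preset("confounder"))

  rep_sex <- positivity_report(jt, "sex")
  expect_true(any(grepl("sex = 1", rep_sex$zero_cells)))
  expect_match(rep_sex$target_population_note, "violated")

  rep_c <- positivity_report(jt, "C")
  expect_length(rep_c$zero_cells, 0)
  expect_match(rep_c$target_population_note, "holds")

  rep_none <- positivity_report(jt)
  expect_length(rep_none$zero_cells, 0)
  expect_equal(rep_none$strata$exposure_prevalence, 0.345,
               tolerance = 1e-12)  # 0.69 x 0.5 women

  # on a cohort the same structure appears empirically
  cohort <- sample_cohort(small_confounder(), 1L)
  rep_cohort <- positivity_report(cohort, c("C", "sex"))
  expect_true(all(grepl("sex = 1",
                        rep_cohort$zero_cells)))
})

test_that("the four-scenario restriction taxonomy matches the exact-table asymptotics", {
  expect_match(classify_restriction_effect(TRUE, FALSE), "prevent bias")
  expect_match(classify_restriction_effect(TRUE, TRUE), "residual bias will remain")
  expect_match(classify_restriction_effect(FALSE, FALSE),
               "not affect bias but can decrease precision")
  expect_match(classify_restriction_effect(FALSE, TRUE), "amplify")

  truth <- log(1.3)
  jt_conf <- build_joint(scenario_preset("confounder"))
  jt_inst <- build_joint(scenario_preset("instrument"))
  restr_c <- analysis_plan("restricted, C adjusted", "C", restrict = TRUE)
  restr <- analysis_plan("restricted only", restrict = TRUE)
  crude <- analysis_plan("crude")
  adj_c <- analysis_plan("C adjusted", "C")

  # confounder, no residual: restriction removes the bias entirely
  expect_gt(abs(asymptotic_effect(jt_conf, adj_c) - truth), 0.05)
  expect_lt(abs(asymptotic_effect(jt_conf, restr_c) - truth), 1e-8)

  # confounder, residual present: restriction helps but C bias remains --
  # and the remaining bias equals the instrument scenario's restricted bias,
  # because after restriction the female-only data coincide
  expect_lt(abs(asymptotic_effect(jt_conf, restr) - truth),
            abs(asymptotic_effect(jt_conf, crude) - truth))
  expect_gt(abs(asymptotic_effect(jt_conf, restr) - truth), 0.05)
  expect_equal(asymptotic_effect(jt_conf, restr),
               asymptotic_effect(jt_inst, restr), tolerance = 1e-10)

  # instrument, no residual: restriction leaves the (zero) bias unchanged
  expect_lt(abs(asymptotic_effect(jt_inst, adj_c) - truth), 1e-8)
  expect_lt(abs(asymptotic_effect(jt_inst, restr_c) - truth), 1e-8)

  # instrument, residual present: restriction amplifies the crude bias
  expect_gt(abs(asymptotic_effect(jt_inst, restr) - truth),
            abs(asymptotic_effect(jt_inst, crude) - truth))
})
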
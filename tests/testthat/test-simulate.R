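test_that("identical seeds give identical cohorts; different seeds differ", {
  p <- cohort_sim_params(n_participants = 400, seed = 21)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a, b)
  c_ <- simulate_cohort(cohort_sim_params(n_participants = 400, seed = 22))
  expect_false(identical(a$participants, c_$participants))
})

test_that("invalid cohort parameters are rejected with the field named", {
  expect_error(cohort_sim_params(carrier_prevalence = 1.2), "carrier_prevalence")
  expect_error(cohort_sim_params(female_fraction = -0.1), "female_fraction")
  expect_error(cohort_sim_params(true_carrier_or = 0), "true_carrier_or")
  expect_error(cohort_sim_params(age_sd = -1), "age_sd")
  expect_error(cohort_sim_params(baseline_ihd_logit = Inf), "baseline_ihd_logit")
  expect_error(
    cohort_sim_params(lipid_sds = list(carrier = c(tc = -1, ldl = 1, hdl = 1, tg = 1),
                                       non_carrier = c(tc = 1, ldl = 1, hdl = 1, tg = 1))),
    "lipid_sds")
})

test_that("generated cohorts honour their parameters", {
  sim <- simulate_cohort(cohort_sim_params(n_participants = 1e5, seed = 5))
  # empirical carrier prevalence within the binomial 99.9% CI of the target
  p0 <- 86 / 4856
  se <- sqrt(p0 * (1 - p0) / 1e5)
  expect_lt(abs(mean(sim$participants$carrier) - p0), 3.29 * se)
  # ages respect the truncation bounds
  expect_true(all(sim$participants$age >= 18 & sim$participants$age <= 100))
  # back-correction recovers the pre-treatment LDL truth exactly
  corrected <- correct_pretreatment_ldl(sim$participants$max_ldl_observed,
                                        sim$participants$therapy)
  expect_equal(corrected, sim$truth$ldl_true, tolerance = 1e-12)
  # untreated participants are unmodified
  untreated <- sim$participants$therapy == "none"
  expect_identical(sim$participants$max_ldl_observed[untreated],
                   sim$truth$ldl_true[untreated])
})

test_that("a null carrier effect yields a null logistic estimate", {
  sim <- simulate_cohort(cohort_sim_params(n_participants = 10000,
                                           true_carrier_or = 1.0,
                                           carrier_prevalence = 0.05,
                                           seed = 31))
  fit <- fit_logistic_or(sim$participants, "ihd", "carrier", c("sex", "age"))
  est <- log(fit$result$estimate)
  se <- summary(fit$fit)$coefficients[fit$exposure_term, "Std. Error"]
  expect_lt(abs(est), 3 * se)
})

test_that("a carrier-free cohort makes the carrier comparison degenerate", {
  sim <- simulate_cohort(cohort_sim_params(n_participants = 500,
                                           carrier_prevalence = 0, seed = 2))
  expect_equal(sum(sim$participants$carrier), 0)
  expect_error(fit_logistic_or(sim$participants, "ihd", "carrier", c("sex", "age")),
               "constant")
})

test_that("annotation generator is seeded, rejects bad mixes, and covers edge mixes", {
  p <- annotation_sim_params(n_variants = 50, seed = 4)
  expect_identical(simulate_annotations(p), simulate_annotations(p))
  expect_error(annotation_sim_params(branch_mix = c(A_pathogenic = 0.5)),
               "sum to 1")
  expect_error(annotation_sim_params(branch_mix = c(nonsense = 1)), "strata")

  # concentrated on the concordant-pathogenic stratum: all ground truth P
  all_p <- simulate_annotations(annotation_sim_params(
    n_variants = 25, branch_mix = c(A_pathogenic = 1), seed = 6))
  expect_true(all(all_p$truth$true_class == "Pathogenic"))
  res <- classify_variants(all_p$annotations)
  expect_true(all(res$classified$final_class == "Pathogenic"))

  # all-common MAF stratum: everything excluded by the MAF filter
  common <- simulate_annotations(annotation_sim_params(
    n_variants = 25, branch_mix = c(excl_maf = 1), seed = 6))
  out <- filter_candidates(common$annotations)
  expect_true(all(!out$candidate))
  expect_true(all(out$exclusion_reason == "maf"))
})
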
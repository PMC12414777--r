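# independent oracle: two-sided Fisher p by explicit enumeration of all
# tables with the observed margins, probabilities from choose()
fisher_oracle_p <- function(a, b, c_, d) {
  n1 <- a + b; n2 <- c_ + d; k <- a + c_
  N <- n1 + n2
  support <- max(0, k - n2):min(n1, k)
  prob <- exp(lchoose(n1, support) + lchoose(n2, k - support) - lchoose(N, k))
  p_obs <- prob[support == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

test_that("fisher_2x2 reproduces the closed-form OR and exact p", {
  # carrier/non-carrier IHD table from the study fixture margins
  r <- fisher_2x2(60, 16, 2551, 2219)
  expect_equal(r$odds_ratio, (60 * 2219) / (16 * 2551))
  expect_equal(r$odds_ratio, 3.262, tolerance = 1e-3)
  expect_equal(r$p_two_sided, fisher_oracle_p(60, 16, 2551, 2219),
               tolerance = 1e-10)
  expect_equal(r$p_two_sided,
               stats::fisher.test(matrix(c(60, 16, 2551, 2219), 2, byrow = TRUE))$p.value,
               tolerance = 1e-10)

  sym <- fisher_2x2(1, 1, 1, 1)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_two_sided, 1)

  # zero cell: sentinel OR plus Haldane companion, exact tail p
  z <- fisher_2x2(0, 5, 5, 0)
  expect_equal(z$odds_ratio, 0)
  expect_equal(z$odds_ratio_haldane, (0.5 * 0.5) / (5.5 * 5.5))
  expect_equal(z$p_two_sided, fisher_oracle_p(0, 5, 5, 0))

  expect_error(fisher_2x2(0, 0, 3, 4), "degenerate")
  expect_error(fisher_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("fisher_2x2 agrees with enumeration for every table up to N = 16 and sampled tables to N = 60", {
  # exhaustive over all non-degenerate tables with N <= 16
  for (N in 2:16) {
    for (a in 0:N) for (b in 0:(N - a)) for (c_ in 0:(N - a - b)) {
      d <- N - a - b - c_
      if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
      expect_equal(fisher_2x2(a, b, c_, d)$p_two_sided,
                   fisher_oracle_p(a, b, c_, d), tolerance = 1e-12)
    }
  }
  # random sample of larger tables up to N = 60, cross-checked against both
  # the enumeration oracle and stats::fisher.test
  set.seed(17)
  for (i in 1:200) {
    cells <- as.vector(stats::rmultinom(1, sample(17:60, 1), runif(4, 0.05, 1)))
    if (any(cells[1] + cells[2] == 0, cells[3] + cells[4] == 0,
            cells[1] + cells[3] == 0, cells[2] + cells[4] == 0)) next
    p <- fisher_2x2(cells[1], cells[2], cells[3], cells[4])$p_two_sided
    expect_equal(p, fisher_oracle_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-8)
  }
})

test_that("mann_whitney matches exact enumeration and the U distribution", {
  # identical multisets: no evidence
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_two_sided, 1)

  # small instances: exact enumeration over all 70 assignments (4 vs 4),
  # cross-checked against wilcox.test's exact distribution (tie-free)
  set.seed(7)
  for (i in 1:25) {
    x <- round(rnorm(4), 6); y <- round(rnorm(4) + 0.5, 6)
    got <- mann_whitney(x, y)
    expect_equal(got$method, "exact enumeration")
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-12)
  }

  # large samples: tie-corrected normal approximation equals wilcox.test
  # without continuity correction
  set.seed(8)
  x <- sample(1:8, 60, replace = TRUE)  # heavy ties
  y <- sample(2:9, 50, replace = TRUE)
  got <- mann_whitney(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-12)

  # stochastically larger sample detected at n = 200
  set.seed(9)
  big <- mann_whitney(rnorm(200, 0.5), rnorm(200))
  expect_lt(big$p_two_sided, 0.05)

  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  # all values identical across both groups: degenerate, p = 1
  expect_equal(mann_whitney(rep(1, 20), rep(1, 20))$p_two_sided, 1)
})

test_that("logistic OR with a lone binary exposure equals the sample 2x2 OR", {
  set.seed(12)
  n <- 600
  x <- runif(n) < 0.4
  y <- as.integer(runif(n) < stats::plogis(-0.3 + 0.8 * x))
  fit <- fit_logistic_or(tibble::tibble(y = y, x = x), "y", "x")
  a <- sum(y & x); b <- sum(!y & x); c_ <- sum(y & !x); d <- sum(!y & !x)
  expect_equal(fit$result$estimate, (a * d) / (b * c_), tolerance = 1e-6)
  # Wald interval brackets the estimate
  expect_lte(fit$result$ci_low, fit$result$estimate)
  expect_gte(fit$result$ci_high, fit$result$estimate)
})

test_that("separation and degenerate inputs raise informative errors", {
  two_points <- tibble::tibble(y = c(0, 1), x = c(0, 1))
  expect_error(fit_logistic_or(two_points, "y", "x"), "separation")
  expect_error(fit_logistic_or(tibble::tibble(y = c(1, 1, 1), x = c(0, 1, 0)),
                               "y", "x"), "degenerate")
  expect_error(fit_logistic_or(tibble::tibble(y = 0:1, x = 0:1), "y", "x",
                               covariates = "x"), "duplicated")
  expect_error(fit_logistic_or(tibble::tibble(y = 0:1), "y", "x"), "missing model column")
})

test_that("tidy and glance expose broom-style fit tables", {
  sim <- simulate_cohort(cohort_sim_params(n_participants = 3000, seed = 14))
  fit <- fit_logistic_or(sim$participants, "ihd", "carrier", c("sex", "age"))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("term", "estimate", "p.value", "conf.low", "conf.high")
                  %in% names(td)))
  expect_equal(nrow(td), 4)  # intercept + carrier + sex + age
  gl <- glance(fit)
  expect_equal(gl$nobs, 3000)
  expect_true(gl$converged)
})

test_that("lipid models detect a generated shift and skip tiny groups", {
  set.seed(15)
  sim <- simulate_cohort(cohort_sim_params(
    n_participants = 6000, carrier_prevalence = 0.05, seed = 15,
    lipid_means = list(
      carrier = c(tc = 5.6, ldl = 3.3, hdl = 1.2, tg = 1.3),
      non_carrier = c(tc = 4.2, ldl = 2.3, hdl = 1.2, tg = 1.3)),
    lipid_sds = list(
      carrier = c(tc = 1.0, ldl = 1.0, hdl = 0.3, tg = 0.6),
      non_carrier = c(tc = 1.0, ldl = 1.0, hdl = 0.3, tg = 0.6))))
  dat <- sim$participants
  # minimal carrier set: every carrier eligible, all labelled LDLR PV/LP
  cs <- tibble::tibble(
    participant_id = dat$participant_id[dat$carrier],
    n_variants = 1L, multi_variant = FALSE,
    exclusion_reason = "none", analysis_eligible = TRUE,
    gene = "LDLR", class = "Pathogenic", subgroup = "LDLR_PVLP"
  )
  res <- suppressMessages(suppressWarnings(lipid_or_models(dat, cs)))
  ldl_all <- res[res$group == "all" & res$lipid == "ldl", ]
  expect_gt(ldl_all$estimate, 1)
  expect_gt(ldl_all$ci_low, 1)
  hdl_all <- res[res$group == "all" & res$lipid == "hdl", ]
  expect_gt(hdl_all$p_value, 0.001)  # no HDL shift generated
  # groups below the size floor are skipped with a warning (one per group)
  warns <- testthat::capture_warnings(
    suppressMessages(lipid_or_models(dat, cs[0, ])))
  expect_true(all(grepl("fewer than", warns)))
  expect_length(warns, 5)
})
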
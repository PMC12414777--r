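test_that("LDL back-correction multiplies by the shipped factor", {
  tab <- ldl_correction_table()
  expect_true(all(tab$factor >= 1))
  expect_equal(tab$factor[tab$therapy == "none"], 1)
  # identity without therapy
  expect_equal(correct_pretreatment_ldl(3.5, "none"), 3.5)
  # oracle: direct lookup in the packaged table
  for (i in seq_len(nrow(tab))) {
    expect_equal(correct_pretreatment_ldl(2.0, tab$therapy[i]),
                 2.0 * tab$factor[i])
  }
  # vectorized with NA therapy treated as untreated
  expect_equal(correct_pretreatment_ldl(c(1, 2), c(NA, "statin_high")),
               c(1, 2 * tab$factor[tab$therapy == "statin_high"]))
  expect_error(correct_pretreatment_ldl(-1, "none"), "non-negative")
  expect_error(correct_pretreatment_ldl(2, "aspirin"), "aspirin")
})

test_that("penetrance matches direct counting and is monotone in the threshold", {
  fx <- study_fixture()
  cs <- study_carriers()
  pen <- penetrance(cs, fx$participants)
  all_row <- pen[pen$group == "all", ]
  expect_equal(all_row$n, 76)
  # monotone non-increasing in the threshold
  expect_lte(all_row$n_ge_4_9, all_row$n_ge_4_0)
  for (g in unique(pen$group)) {
    row <- pen[pen$group == g, ]
    expect_lte(row$pen_4_9, row$pen_4_0)
    expect_lte(row$n_above_threshold, row$n)
    expect_gte(row$penetrance, 0); expect_lte(row$penetrance, 1)
  }
  # LDLR splits add up
  expect_equal(pen$n_ge_4_0[pen$group == "LDLR"],
               sum(pen$n_ge_4_0[pen$group %in% c("LDLR_PVLP", "LDLR_VUSdel")]))
})

test_that("correcting LDL then thresholding equals pre-scaling the threshold", {
  # for a uniform therapy group with factor f: x*f >= t  <=>  x >= t/f
  tab <- ldl_correction_table()
  f <- tab$factor[tab$therapy == "statin_high"]
  x <- seq(0.5, 6, by = 0.07)
  lhs <- correct_pretreatment_ldl(x, "statin_high") >= 4.0
  rhs <- x >= 4.0 / f
  expect_identical(lhs, rhs)
})

test_that("exclusion rules are idempotent", {
  fx <- study_fixture()
  cs <- study_carriers()
  again <- apply_exclusions(cs, fx$cascade_ids, fx$q4494del_variant_ids)
  expect_identical(as.data.frame(again), as.data.frame(cs))
})

test_that("DLCNS totals, categories and missing handling follow the point table", {
  # nothing positive, normal LDL: 0 points, unlikely
  s0 <- dlcns_score(ldl_mmol = 2.0)
  expect_equal(s0$total, 0)
  expect_equal(s0$category, "unlikely")
  expect_equal(s0$total, sum(s0$components))

  # oracle: packaged point table — top LDL band + DNA criterion
  pt <- dlcn_point_table()
  s1 <- dlcns_score(ldl_mmol = 9.0, dna_causal_mutation = TRUE)
  expect_equal(unname(s1$components["ldl"]), pt$ldl_bands$points[1])
  expect_equal(unname(s1$components["dna"]), unname(pt$dna["causal_mutation"]))
  expect_equal(s1$total, pt$ldl_bands$points[1] + pt$dna[["causal_mutation"]])
  expect_equal(s1$category, "definite")
  expect_equal(s1$category_without_dna, "probable")

  # within-group maximum, not a sum
  s2 <- dlcns_score(ldl_mmol = 1, family_premature_cvd = TRUE,
                    family_xanthoma_or_child_high_ldl = TRUE)
  expect_equal(s2$total, 2)

  # category is monotone in the total across LDL bands
  totals <- vapply(c(1, 4.2, 5.5, 7, 9), function(l) dlcns_score(l)$total,
                   numeric(1))
  expect_identical(totals, sort(totals))

  # missing inputs score zero and are reported
  s3 <- dlcns_score(ldl_mmol = NA, tendon_xanthoma = NA)
  expect_equal(s3$total, 0)
  expect_setequal(s3$missing_components, c("ldl_mmol", "tendon_xanthoma"))
  expect_error(dlcns_score(ldl_mmol = -1), "non-negative")
})

test_that("the records-based screen flags the constrained fixture carriers", {
  fx <- study_fixture()
  cs <- study_carriers()
  eligible <- cs[cs$analysis_eligible, ]
  screened_ids <- eligible$participant_id[eligible$subgroup %in%
                                            c("LDLR_PVLP", "APOB")]
  dat <- fx$participants |>
    dplyr::filter(participant_id %in% screened_ids) |>
    dplyr::mutate(ldl_mmol = correct_pretreatment_ldl(max_ldl_observed, therapy))
  res <- fh_criteria_screen(dat)
  expect_equal(sum(!is.na(res$dlcns_total)), 51)
  expect_equal(sum(res$meets_fh_criteria, na.rm = TRUE), 12)
})
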
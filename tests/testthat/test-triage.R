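test_that("candidate filter keeps rare exonic panel variants and reports first failing rule", {
  cases <- list(
    # unreported in gnomAD: kept
    list(ann = make_annotation(gnomad_maf = NA_real_), candidate = TRUE, reason = NA_character_),
    list(ann = make_annotation(gnomad_maf = 5e-5), candidate = TRUE, reason = NA_character_),
    # common variant: MAF rule (0.005 >= 1e-4)
    list(ann = make_annotation(gnomad_maf = 0.005), candidate = FALSE, reason = "maf"),
    # boundary: "below 0.01%" is strict
    list(ann = make_annotation(gnomad_maf = 1e-4), candidate = FALSE, reason = "maf"),
    # ClinVar benign excluded even when rare
    list(ann = make_annotation(gene = "APOB", gnomad_maf = 5e-5, clinvar_class = "LB"),
         candidate = FALSE, reason = "benign_in_clinvar"),
    # off-panel gene fails first even if also common
    list(ann = make_annotation(gene = "APOE", gnomad_maf = 0.05),
         candidate = FALSE, reason = "gene_not_in_panel"),
    list(ann = make_annotation(region = "other"), candidate = FALSE, reason = "region"),
    list(ann = make_annotation(region = "splice_site", consequence = "splice"),
         candidate = TRUE, reason = NA_character_)
  )
  for (cs in cases) {
    out <- filter_candidates(cs$ann)
    expect_identical(out$candidate, cs$candidate)
    expect_identical(out$exclusion_reason, cs$reason)
  }
})

test_that("annotation validation reports all malformed rows with indices", {
  bad <- dplyr::bind_rows(
    make_annotation(),
    make_annotation(clinvar_class = "bogus"),
    make_annotation(gnomad_maf = 1.5)
  )
  expect_error(validate_annotations(bad), "clinvar_class.*rows 2")
  expect_error(validate_annotations(bad), "gnomad_maf.*rows 3")
  expect_error(validate_annotations(bad[, -1]), "missing required column")
})

test_that("in-silico consensus counts agreeing predictors with a quorum of three", {
  all_pass <- insilico_consensus(list(sift = 0.01, polyphen2_hdiv = 0.99,
                                      mutation_assessor = 2.5, m_cap = 0.03,
                                      cadd = 24))
  expect_equal(all_pass$n_agree, 5)
  expect_true(all_pass$supports_lp)
  expect_true(all_pass$evaluable)

  two_present <- insilico_consensus(list(sift = 0.01, polyphen2_hdiv = 0.99))
  expect_equal(two_present$n_agree, 2)
  expect_false(two_present$supports_lp)
  expect_false(two_present$evaluable)

  exactly_three <- insilico_consensus(list(sift = 0.01, polyphen2_hdiv = 0.99,
                                           mutation_assessor = 3, m_cap = 0.001,
                                           cadd = 2))
  expect_equal(exactly_three$n_agree, 3)
  expect_true(exactly_three$supports_lp)

  # thresholds at the boundary: SIFT strict, CADD inclusive
  expect_equal(insilico_consensus(list(sift = 0.05))$n_agree, 0)
  expect_equal(insilico_consensus(list(cadd = 15))$n_agree, 1)
  expect_equal(insilico_consensus(list())$n_agree, 0)
})

test_that("REVEL/MetaLR tie-break needs both scores present and above cutoff", {
  expect_true(tiebreak_inconclusive(list(revel = 0.8, metalr = 0.6)))
  expect_false(tiebreak_inconclusive(list(revel = 0.8, metalr = 0.4)))
  expect_false(tiebreak_inconclusive(list(metalr = 0.6)))
  expect_false(tiebreak_inconclusive(list(revel = 0.75, metalr = 0.6)))
})

test_that("decision branches produce the documented classes", {
  # branch A: concordant strong-review pathogenic assertion stands
  a <- classify_variant(make_annotation(clinvar_class = "P",
                                        clinvar_review = "multiple_submitters",
                                        intervar_class = "LP"))
  expect_equal(a$final_class, "Pathogenic")
  expect_equal(a$fired_branch, "A")

  # branch B: ClinVar P + InterVar VUS falls to review; consensus upgrades
  b_pass <- classify_variant(make_annotation(clinvar_class = "P",
                                             clinvar_review = "multiple_submitters",
                                             intervar_class = "VUS",
                                             sift = 0.01, polyphen2_hdiv = 0.99,
                                             mutation_assessor = 3, m_cap = 0.2,
                                             cadd = 25))
  expect_equal(b_pass$final_class, "LikelyPathogenic")
  expect_equal(b_pass$fired_branch, "B")
  b_fail <- classify_variant(make_annotation(clinvar_class = "LP",
                                             clinvar_review = "multiple_submitters",
                                             intervar_class = "VUS",
                                             sift = 0.9, polyphen2_hdiv = 0.1,
                                             mutation_assessor = 0, m_cap = 0.001,
                                             cadd = 3))
  expect_equal(b_fail$final_class, "VUS")

  # branch C: single-submitter P needs clinical support plus corroboration
  c_unsupported <- classify_variant(make_annotation(
    clinvar_class = "P", clinvar_review = "single_submitter",
    intervar_class = "LP", clinical_case_support = FALSE,
    sift = 0.9, polyphen2_hdiv = 0.1, mutation_assessor = 0, m_cap = 0.001,
    cadd = 3))
  expect_false(c_unsupported$final_class == "Pathogenic")
  expect_equal(c_unsupported$fired_branch, "C")
  c_supported <- classify_variant(make_annotation(
    clinvar_class = "P", clinvar_review = "single_submitter",
    intervar_class = "LP", clinical_case_support = TRUE))
  expect_equal(c_supported$final_class, "Pathogenic")

  # tie-break applies when the consensus cannot be evaluated
  d_tiebreak <- classify_variant(make_annotation(
    clinvar_class = "LP", clinvar_review = "single_submitter",
    intervar_class = "LP", revel = 0.9, metalr = 0.8))
  expect_equal(d_tiebreak$final_class, "LikelyPathogenic")
  expect_equal(d_tiebreak$fired_branch, "D")

  # branch E: expert-panel InterVar P with ClinVar VUS stands
  e <- classify_variant(make_annotation(clinvar_class = "VUS",
                                        clinvar_review = "expert_panel",
                                        intervar_class = "P"))
  expect_equal(e$final_class, "Pathogenic")
  expect_equal(e$fired_branch, "E")

  # branch F: rare LDLR missense with MetaLR+MetaSVM deleterious
  f_del <- classify_variant(make_annotation(metalr = 0.8, metasvm = 0.6))
  expect_equal(f_del$final_class, "VUS_deleterious")
  expect_equal(f_del$fired_branch, "F")
  f_vus <- classify_variant(make_annotation(metalr = 0.8, metasvm = -0.2))
  expect_equal(f_vus$final_class, "VUS")
  # MAF at/above the rare-missense bound blocks the promotion
  f_maf <- classify_variant(make_annotation(gnomad_maf = 5e-4, metalr = 0.8,
                                            metasvm = 0.6))
  expect_equal(f_maf$final_class, "VUS")
  # non-LDLR missense never reaches F
  f_apob <- classify_variant(make_annotation(gene = "APOB", metalr = 0.8,
                                             metasvm = 0.6))
  expect_equal(f_apob$final_class, "VUS")
  expect_equal(f_apob$fired_branch, "E")

  # conflicting ClinVar assertions are flagged and treated as uncertain
  conf <- classify_variant(make_annotation(clinvar_class = "conflicting",
                                           clinvar_review = "none"))
  expect_match(conf$evidence_summary, "conflicting")
  expect_true(conf$final_class %in% c("VUS", "VUS_deleterious"))
})

test_that("triage engine reproduces generator ground truth on every stratum", {
  sim <- simulate_annotations(annotation_sim_params(n_variants = 300, seed = 11))
  res <- classify_variants(sim$annotations)
  expect_equal(as.character(res$classified$final_class), sim$truth$true_class)
  # every stratum (hence every decision branch) reachable under defaults
  expect_setequal(unique(sim$truth$stratum), fhtriage:::.annotation_strata)
})

test_that("classification is total, deterministic and order-independent", {
  sim <- simulate_annotations(annotation_sim_params(n_variants = 120, seed = 3))
  res1 <- classify_variants(sim$annotations)
  res2 <- classify_variants(sim$annotations)
  expect_identical(res1$classified, res2$classified)
  # every candidate fires exactly one branch A..F
  cand <- res1$classified[is.na(res1$classified$exclusion_reason), ]
  expect_true(all(cand$fired_branch %in% LETTERS[1:6]))
  # excluded rows always carry a reason, and vice versa
  excl <- res1$classified$final_class == "Excluded"
  expect_identical(excl, !is.na(res1$classified$exclusion_reason))
  # shuffling rows leaves the per-variant result unchanged
  shuffled <- sim$annotations[rev(seq_len(nrow(sim$annotations))), ]
  res3 <- classify_variants(shuffled)
  expect_identical(
    dplyr::arrange(res1$classified, variant_id),
    dplyr::arrange(res3$classified, variant_id)
  )
})

test_that("strengthening evidence never downgrades a classification", {
  rank <- function(cls) match(cls, c("VUS", "VUS_deleterious",
                                     "LikelyPathogenic", "Pathogenic"))
  sim <- simulate_annotations(annotation_sim_params(n_variants = 150, seed = 9))
  cand <- filter_candidates(sim$annotations)
  cand <- cand[cand$candidate, ]
  for (i in seq_len(nrow(cand))) {
    base <- classify_variant(cand[i, ])
    stronger <- cand[i, ]
    stronger$clinical_case_support <- TRUE
    stronger$sift <- 0.001; stronger$polyphen2_hdiv <- 1
    stronger$mutation_assessor <- 3.5; stronger$m_cap <- 0.3; stronger$cadd <- 30
    up <- classify_variant(stronger)
    expect_gte(rank(up$final_class), rank(base$final_class))
  }
})

test_that("vectorized classification handles empty and single-bucket inputs", {
  empty <- make_annotation()[0, ]
  res <- classify_variants(empty)
  expect_equal(nrow(res$classified), 0)
  expect_true(all(res$summary$n == 0))

  pcsk9_benign <- dplyr::bind_rows(
    make_annotation(variant_id = "chr1:55039001:A:G", gene = "PCSK9",
                    clinvar_class = "B", gnomad_maf = 5e-5),
    make_annotation(variant_id = "chr1:55039002:A:G", gene = "PCSK9",
                    clinvar_class = "LB", gnomad_maf = 2e-5)
  )
  res2 <- classify_variants(pcsk9_benign)
  expect_true(all(res2$classified$final_class == "Excluded"))
  n_pcsk9_kept <- res2$summary |>
    dplyr::filter(gene == "PCSK9", final_class != "Excluded") |>
    dplyr::pull(n) |> sum()
  expect_equal(n_pcsk9_kept, 0)
})
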
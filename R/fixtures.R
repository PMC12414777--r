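# sorted values of length n whose type-7 quartiles equal q1/med/q3 exactly;
# interior points are linear interpolation, endpoints lo/hi
.quartile_constrained <- function(n, q1, med, q3, lo, hi) {
  stopifnot(lo < q1, q1 <= med, med <= q3, q3 < hi, n >= 8)
  x <- numeric(n)
  pin <- function(p) {
    h <- (n - 1) * p + 1
    c(floor(h), ceiling(h))
  }
  i1 <- pin(0.25); i2 <- pin(0.5); i3 <- pin(0.75)
  x[i1[1]:i1[2]] <- q1
  x[i2[1]:i2[2]] <- med
  x[i3[1]:i3[2]] <- q3
  fill <- function(from, to, a, b) {
    if (to >= from) {
      k <- to - from + 1
      x[from:to] <<- seq(a, b, length.out = k + 2)[2:(k + 1)]
    }
  }
  fill(1, i1[1] - 1, lo, q1)
  fill(i1[2] + 1, i2[1] - 1, q1, med)
  fill(i2[2] + 1, i3[1] - 1, med, q3)
  fill(i3[2] + 1, n, q3, hi)
  x
}

# assign k TRUE flags to positions offset+1 .. offset+k (mod n), so different
# rows overlap in a fixed but varied pattern
.flag_block <- function(n, k, offset = 0) {
  out <- rep(FALSE, n)
  if (k > 0) out[(offset + seq_len(k) - 1) %% n + 1] <- TRUE
  out
}

# annotation row recipes used by the fixture variants
.ann_row <- function(variant_id, gene, recipe) {
  base <- tibble(
    variant_id = variant_id, gene = gene, region = "exonic",
    variant_type = "SNV", consequence = "missense", gnomad_maf = NA_real_,
    clinvar_class = "VUS", clinvar_review = "single_submitter",
    intervar_class = "VUS", sift = NA_real_, polyphen2_hdiv = NA_real_,
    mutation_assessor = NA_real_, m_cap = NA_real_, cadd = NA_real_,
    revel = NA_real_, metalr = NA_real_, metasvm = NA_real_,
    clinical_case_support = FALSE
  )
  switch(recipe,
    pathogenic_A = base |> mutate(clinvar_class = "P",
                                  clinvar_review = "multiple_submitters",
                                  intervar_class = "P"),
    likely_pathogenic_A = base |> mutate(clinvar_class = "LP",
                                         clinvar_review = "multiple_submitters",
                                         intervar_class = "LP"),
    vus_deleterious_F = base |> mutate(gnomad_maf = 2e-5, metalr = 0.8,
                                       metasvm = 0.5),
    benign = base |> mutate(clinvar_class = "B",
                            clinvar_review = "multiple_submitters",
                            intervar_class = "B", gnomad_maf = 5e-5)
  )
}

#' Deterministic study fixture constrained to the published table marginals
#'
#' Reconstructs an individual-level dataset whose marginal counts equal the
#' published cohort tables: 4,856 participants of whom 86 carry a reportable
#' variant; exclusions (4 two-variant carriers, 2 cascade-screened proband
#' relatives, 4 APOB p.Gln4494del carriers) leaving 76 analysis carriers
#' split 37 LDLR PV/LP + 24 LDLR VUS-deleterious + 15 APOB; the cohort
#' table's per-row counts and median \[Q1; Q3\] summaries for the 76 carriers
#' and 4,770 non-carriers; and the clinical table's per-subgroup FH-diagnosis,
#' IHD and LDL-threshold counts. Individual values are synthesized only where
#' a count or quantile is printed; everything else is a documented convention
#' (see the fixture manifest written by [write_fixture_files()]).
#'
#' The carrier arithmetic (86 - 76 = 10, with cascade relatives counted as 2)
#' and the 51-record denominator for the FH-diagnosis screen (one APOB PV/LP
#' carrier's records marked unavailable) are reconciliations of ambiguous
#' published totals, chosen once and documented — synthetic assumptions, not
#' published facts.
#'
#' @return list: `annotations` (46 variants: 44 reportable in LDLR/APOB plus
#'   2 benign PCSK9), `genotypes`, `participants`, `cascade_ids`,
#'   `q4494del_variant_ids`.
#' @export
#' @examples
#' fx <- fh_study_fixture()
#' nrow(fx$participants)
fh_study_fixture <- function() {
  # ---- variants: 21 LDLR PV/LP + 21 LDLR VUS-deleterious + 2 APOB (= 44
  # reportable) + 2 benign PCSK9 that must be filtered out
  ldlr_pvlp_ids <- sprintf("chr19:%d:C:T", 11100000 + seq_len(21))
  ldlr_vusd_ids <- sprintf("chr19:%d:G:A", 11110000 + seq_len(21))
  apob_r3527q <- "chr2:21006288:C:T"   # p.Arg3527Gln
  apob_q4494del <- "chr2:21001429:TCTG:T" # p.Gln4494del
  pcsk9_ids <- sprintf("chr1:%d:A:G", 55039000 + 1:2)

  annotations <- bind_rows(
    map(ldlr_pvlp_ids[1:11], ~ .ann_row(.x, "LDLR", "pathogenic_A")) |> list_rbind(),
    map(ldlr_pvlp_ids[12:21], ~ .ann_row(.x, "LDLR", "likely_pathogenic_A")) |> list_rbind(),
    map(ldlr_vusd_ids, ~ .ann_row(.x, "LDLR", "vus_deleterious_F")) |> list_rbind(),
    .ann_row(apob_r3527q, "APOB", "pathogenic_A"),
    .ann_row(apob_q4494del, "APOB", "likely_pathogenic_A") |>
      mutate(variant_type = "indel", consequence = "inframe_del"),
    map(pcsk9_ids, ~ .ann_row(.x, "PCSK9", "benign")) |> list_rbind()
  )

  # ---- carriers: ids encode the analysis subgroups
  # E01..E37 LDLR PV/LP singles, E38..E61 LDLR VUS-del singles, E62..E76 APOB
  # X01..X04 two-variant carriers, X05 (PV/LP) and X06 (VUS-del) cascade
  # relatives, X07..X10 p.Gln4494del carriers
  e_ids <- sprintf("E%02d", 1:76)
  x_ids <- sprintf("X%02d", 1:10)
  n_ids <- sprintf("N%04d", 1:4770)

  gt <- function(pid, vid) tibble(participant_id = pid, variant_id = vid,
                                  genotype = "0/1")
  genotypes <- bind_rows(
    gt(e_ids[1:37], rep_len(ldlr_pvlp_ids, 37)),
    gt(e_ids[38:61], rep_len(ldlr_vusd_ids, 24)),
    gt(e_ids[62:76], apob_r3527q),
    gt(x_ids[1:4], ldlr_pvlp_ids[1]),
    gt(x_ids[1:4], ldlr_pvlp_ids[2]),
    gt(x_ids[5], ldlr_pvlp_ids[3]),
    gt(x_ids[6], ldlr_vusd_ids[3]),
    gt(x_ids[7:10], apob_q4494del)
  )

  # ---- eligible-carrier phenotypes (n = 76), table-constrained
  nE <- 76
  is_pvlp <- 1:76 %in% 1:37
  is_vusd <- 1:76 %in% 38:61
  is_apob <- 1:76 %in% 62:76
  sex <- ifelse(1:76 <= 41, "male", "female")                  # 41 men / 35 women
  ihd <- rep(FALSE, nE)
  ihd[1:30] <- TRUE    # 30 of 37 LDLR PV/LP
  ihd[38:55] <- TRUE   # 18 of 24 LDLR VUS-deleterious
  ihd[62:74] <- TRUE   # 13 of 15 APOB
  # 61 IHD carriers; 60 carry a principal I20-I25 code (one by history only)
  ihd_code <- ihd; ihd_code[74] <- FALSE
  stopifnot(sum(ihd) == 61, sum(ihd_code) == 60)

  # diagnosis code lists: rows of the characteristics table are overlapping
  # multi-code counts, so blocks are placed at fixed offsets; participants the
  # blocks miss simply have no recorded circulatory diagnosis. The "other"
  # block sits on participants with no other codes so the all-other count is
  # exact.
  icd_codes <- map(ihd_code, ~ if (.x) "I21" else character())
  add_codes <- function(codes_list, flag, code) {
    map2(codes_list, flag, ~ if (.y) c(.x, code) else .x)
  }
  icd_codes <- icd_codes |>
    add_codes(.flag_block(nE, 54, 5), "I10") |>     # hypertensive (6..59)
    add_codes(.flag_block(nE, 3, 0), "I27") |>      # pulmonary
    add_codes(.flag_block(nE, 10, 12), "I35") |>    # endocarditis/valve
    add_codes(.flag_block(nE, 1, 25), "I42") |>     # cardiomyopathy
    add_codes(.flag_block(nE, 26, 30), "I48") |>    # arrhythmia
    add_codes(.flag_block(nE, 1, 60), "I50") |>     # heart failure
    add_codes(.flag_block(nE, 2, 74), "Z03")        # other-only (75..76)

  # per-subgroup maximum pre-treatment (corrected) LDL targets
  assign_ldl <- function(n, k49, k40) {
    # k49 values >= 4.9, then k40 - k49 in [4.0, 4.9), rest below 4.0
    c(rep(5.5, k49), rep(4.3, k40 - k49), rep(3.2, n - k40))
  }
  ldl_corrected <- c(assign_ldl(37, 24, 29), assign_ldl(24, 4, 12),
                     assign_ldl(15, 12, 14))
  treated <- .flag_block(nE, 52, 7)                 # 52 on lipid-lowering drugs
  therapy <- ifelse(treated, "statin_moderate", "none")
  fct <- ldl_correction_table()
  fac <- fct$factor[match(therapy, fct$therapy)]
  max_ldl_observed <- ldl_corrected / fac

  # current lipid panel / age: quartile-constrained synthetic values in a
  # fixed scrambled order
  perm <- c(seq(2, nE, by = 2), seq(1, nE, by = 2))
  qvals <- function(q1, med, q3, lo, hi) .quartile_constrained(nE, q1, med, q3, lo, hi)[order(perm)]
  carriers <- tibble(
    participant_id = e_ids,
    sex = sex,
    age = qvals(56, 65, 73, 32, 92),
    bmi_category = rep(c("healthy", "overweight", "obesity_1", "obesity_2"),
                       times = c(20, 36, 15, 5)),
    smoking = ifelse(.flag_block(nE, 8, 50), "dependent", "never_former"),
    diabetes = .flag_block(nE, 17, 22),
    alcohol_audit_c = {
      a <- rep(2L, nE); a[.flag_block(nE, 43, 0)] <- 0L
      a[.flag_block(nE, 11, 43)] <- 4L; a
    },
    icd10_primary = icd_codes,
    ihd = ihd,
    tc = qvals(3.70, 4.61, 6.18, 2.2, 9.5),
    ldl = qvals(1.775, 2.59, 3.975, 0.8, 7.8),
    hdl = qvals(0.9375, 1.205, 1.43, 0.5, 2.4),
    glucose = qvals(4.8875, 5.125, 5.8, 3.8, 11),
    tg = qvals(0.8775, 1.19, 1.785, 0.4, 4.8),
    max_ldl_observed = max_ldl_observed,
    on_lipid_lowering = treated,
    therapy = therapy,
    antiplatelet = .flag_block(nE, 42, 10),
    anticoagulant = .flag_block(nE, 16, 33),
    beta_blocker = .flag_block(nE, 48, 18),
    antihypertensive = .flag_block(nE, 45, 27),
    dyslipidemia = .flag_block(nE, 23, 14),
    prior_fh_diagnosis = 1:76 %in% 1:8,        # 8 prior diagnoses, all LDLR PV/LP
    tendon_xanthoma = 1:76 %in% c(9:14, 62:67), # 12 meet DLCN criteria post hoc
    records_available = 1:76 != 76,            # one APOB PV/LP record set missing
    carrier = TRUE
  )
  carriers$bmi <- c(healthy = 22, overweight = 27, obesity_1 = 32,
                    obesity_2 = 37)[carriers$bmi_category]

  # ---- excluded carriers (n = 10): unconstrained conventional values
  excluded <- tibble(
    participant_id = x_ids,
    sex = rep(c("male", "female"), 5),
    age = seq(40, 76, length.out = 10),
    bmi_category = "overweight", bmi = 27,
    smoking = "never_former", diabetes = FALSE, alcohol_audit_c = 0L,
    icd10_primary = as.list(rep("I10", 10)),
    ihd = FALSE,
    tc = 5.0, ldl = c(rep(8.5, 4), 3.0, 3.0, rep(3.0, 4)),
    hdl = 1.2, glucose = 5.2, tg = 1.3,
    max_ldl_observed = c(rep(9.0, 4), 4.5, 4.2, rep(3.2, 4)),
    on_lipid_lowering = c(rep(TRUE, 4), FALSE, FALSE, rep(FALSE, 4)),
    therapy = c(rep("statin_high", 4), rep("none", 6)),
    antiplatelet = FALSE, anticoagulant = FALSE, beta_blocker = FALSE,
    antihypertensive = FALSE, dyslipidemia = c(rep(TRUE, 4), rep(FALSE, 6)),
    prior_fh_diagnosis = c(TRUE, TRUE, rep(FALSE, 8)),
    tendon_xanthoma = FALSE, records_available = TRUE,
    carrier = TRUE
  )

  # ---- non-carriers (n = 4,770), cohort-table-constrained
  nN <- 4770
  permN <- c(seq(2, nN, by = 2), seq(1, nN, by = 2))
  qN <- function(q1, med, q3, lo, hi) .quartile_constrained(nN, q1, med, q3, lo, hi)[order(permN)]
  icdN <- map(1:nN, function(i) character())
  icdN <- icdN |>
    add_codes(.flag_block(nN, 2551, 1899), "I21") |>
    add_codes(.flag_block(nN, 3492, 600), "I10") |>
    add_codes(.flag_block(nN, 232, 100), "I27") |>
    add_codes(.flag_block(nN, 11, 350), "I31") |>
    add_codes(.flag_block(nN, 278, 400), "I35") |>
    add_codes(.flag_block(nN, 177, 700), "I42") |>
    add_codes(.flag_block(nN, 2484, 900), "I48") |>
    add_codes(.flag_block(nN, 116, 3400), "I50") |>
    add_codes(.flag_block(nN, 258, 4100), "Z03")   # other-only (4101..4358)
  bmi_cat_N <- c(rep(c("underweight", "healthy", "overweight", "obesity_1",
                       "obesity_2", "obesity_3"),
                     times = c(38, 1058, 1852, 1245, 421, 155)), NA)
  non_carriers <- tibble(
    participant_id = n_ids,
    sex = ifelse(1:nN <= 2721, "male", "female"),
    age = qN(58, 66, 74, 19, 97),
    bmi_category = bmi_cat_N,
    smoking = ifelse(.flag_block(nN, 655, 4200), "dependent", "never_former"),
    diabetes = .flag_block(nN, 1049, 4000),
    alcohol_audit_c = {
      a <- rep(2L, nN); a[.flag_block(nN, 2693, 0)] <- 0L
      a[.flag_block(nN, 754, 2693)] <- 4L; a
    },
    icd10_primary = icdN,
    ihd = .flag_block(nN, 2551, 1899),
    tc = qN(3.48, 4.19, 5.14, 1.9, 10.2),
    ldl = qN(1.73, 2.30, 3.11, 0.6, 8.4),
    hdl = qN(0.98, 1.17, 1.41, 0.4, 2.6),
    glucose = qN(4.89, 5.3, 6, 3.5, 14),
    tg = qN(0.98, 1.32, 1.81, 0.3, 6.1),
    on_lipid_lowering = .flag_block(nN, 3063, 500),
    antiplatelet = .flag_block(nN, 2360, 150),
    anticoagulant = .flag_block(nN, 1736, 1100),
    beta_blocker = .flag_block(nN, 2963, 250),
    antihypertensive = .flag_block(nN, 3361, 800),
    dyslipidemia = .flag_block(nN, 1716, 1400),
    prior_fh_diagnosis = FALSE,
    tendon_xanthoma = FALSE, records_available = TRUE,
    carrier = FALSE
  )
  non_carriers$therapy <- ifelse(non_carriers$on_lipid_lowering,
                                 "statin_moderate", "none")
  non_carriers$max_ldl_observed <- non_carriers$ldl
  bmi_map <- c(underweight = 17.5, healthy = 22, overweight = 27,
               obesity_1 = 32, obesity_2 = 37, obesity_3 = 42)
  non_carriers$bmi <- unname(bmi_map[non_carriers$bmi_category])

  participants <- bind_rows(carriers, excluded, non_carriers)
  list(
    annotations = annotations,
    genotypes = genotypes,
    participants = participants,
    cascade_ids = c("X05", "X06"),
    q4494del_variant_ids = apob_q4494del
  )
}

#' Write the study fixture to plain-text files with a manifest
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_fixture_files <- function(dir) {
  fx <- fh_study_fixture()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(fx$annotations, p("annotations.tsv"))
  readr::write_tsv(fx$genotypes, p("genotypes.tsv"))
  part <- fx$participants |>
    mutate(icd10_primary = map_chr(.data$icd10_primary,
                                   ~ paste(.x, collapse = ";")))
  readr::write_csv(part, p("participants.csv"))
  writeLines(c(
    "Synthetic study fixture: individual-level data reconstructed from printed table marginals.",
    "Constrained cells (exact): carrier counts 86/76 and subgroup sizes 37/24/15;",
    "sex, BMI-category, smoking, alcohol, diagnosis-bucket, medication, diabetes and",
    "dyslipidemia counts per group; quartiles of age and lipid panel per group;",
    "per-subgroup IHD, prior-FH, post-hoc-FH and LDL-threshold counts.",
    "Everything else (pairings of traits within a participant, exact values between",
    "quartile pins, which participants overlap across rows) is a deterministic",
    "convention of this generator and carries no information.",
    "Assumptions (not printed facts): 2 cascade-screened relatives; one APOB PV/LP",
    "carrier's records unavailable (FH-screen denominator 51).",
    "",
    "Files: annotations.tsv, genotypes.tsv, participants.csv",
    "participants.csv: icd10_primary is ';'-separated."
  ), p("MANIFEST.txt"))
  invisible(c(p("annotations.tsv"), p("genotypes.tsv"), p("participants.csv"),
              p("MANIFEST.txt")))
}
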
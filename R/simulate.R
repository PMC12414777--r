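# inverse-CDF truncated normal: exact, vectorized, no rejection loop
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  stats::qnorm(runif(n, p_lo, p_hi), mean, sd)
}

.check_fraction <- function(x, field) {
  if (!is_scalar_double(x) && !is_scalar_integerish(x)) {
    abort(paste0(field, " must be a single number"))
  }
  if (!is.finite(x) || x < 0 || x > 1) {
    abort(paste0(field, " must be a fraction in [0, 1]"))
  }
  invisible(x)
}

.check_positive <- function(x, field) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0(field, " must be positive and finite"))
  }
  invisible(x)
}

#' Cohort simulation parameters
#'
#' Parameters of the synthetic inpatient cohort generator. Defaults describe
#' the cardiology cohort the analysis targets: 4,856 inpatients, 43% women,
#' median age in the mid-60s, carrier prevalence 1.77%, ischaemic heart
#' disease generated from a logistic model whose carrier odds ratio defaults
#' to 1.31 (the adjusted effect the analysis is built to recover), and lipid
#' levels centred on the carrier / non-carrier group summaries (treated
#' participants' observed LDL-C is deflated by the shipped therapy correction
#' factors, so back-correction is exactly invertible).
#'
#' @param n_participants cohort size.
#' @param carrier_prevalence fraction carrying a reportable variant.
#' @param female_fraction fraction of women.
#' @param age_mean,age_sd years; ages are truncated-normal on \[18, 100\].
#' @param baseline_ihd_logit IHD log-odds for a non-carrier woman of mean age
#'   (default -0.1, giving a non-carrier IHD prevalence near the observed 53%
#'   under the default sex/age effects).
#' @param true_carrier_or generative carrier odds ratio for IHD (> 0).
#' @param sex_or,age_or_per_sd generative odds ratios for male sex and for one
#'   standard deviation of age.
#' @param lipid_means,lipid_sds lists with elements `carrier` and
#'   `non_carrier`, each a named numeric (`tc`, `ldl`, `hdl`, `tg`), mmol/L.
#' @param treated_fraction fraction on lipid-lowering therapy.
#' @param seed integer; identical seeds give byte-identical cohorts.
#' @return list of class `fh_cohort_params`.
#' @export
cohort_sim_params <- function(n_participants = 4856,
                              carrier_prevalence = 86 / 4856,
                              female_fraction = 0.43,
                              age_mean = 65,
                              age_sd = 12.5,
                              baseline_ihd_logit = -0.1,
                              true_carrier_or = 1.31,
                              sex_or = 1.5,
                              age_or_per_sd = 1.3,
                              lipid_means = list(
                                carrier = c(tc = 4.61, ldl = 2.59, hdl = 1.205, tg = 1.19),
                                non_carrier = c(tc = 4.19, ldl = 2.30, hdl = 1.17, tg = 1.32)
                              ),
                              lipid_sds = list(
                                carrier = c(tc = 1.84, ldl = 1.63, hdl = 0.37, tg = 0.67),
                                non_carrier = c(tc = 1.23, ldl = 1.02, hdl = 0.32, tg = 0.62)
                              ),
                              treated_fraction = 0.645,
                              seed = 1L) {
  if (!is_scalar_integerish(n_participants) || n_participants < 1) {
    abort("n_participants must be a positive integer")
  }
  .check_fraction(carrier_prevalence, "carrier_prevalence")
  .check_fraction(female_fraction, "female_fraction")
  .check_fraction(treated_fraction, "treated_fraction")
  .check_positive(age_sd, "age_sd")
  if (!is.finite(baseline_ihd_logit)) abort("baseline_ihd_logit must be finite")
  .check_positive(true_carrier_or, "true_carrier_or")
  .check_positive(sex_or, "sex_or")
  .check_positive(age_or_per_sd, "age_or_per_sd")
  for (grp in c("carrier", "non_carrier")) {
    if (!all(c("tc", "ldl", "hdl", "tg") %in% names(lipid_means[[grp]]))) {
      abort(paste0("lipid_means$", grp, " must name tc, ldl, hdl, tg"))
    }
    .check_positive(lipid_sds[[grp]], paste0("lipid_sds$", grp))
  }
  structure(
    list(n_participants = as.integer(n_participants),
         carrier_prevalence = carrier_prevalence,
         female_fraction = female_fraction,
         age_mean = age_mean, age_sd = age_sd,
         baseline_ihd_logit = baseline_ihd_logit,
         true_carrier_or = true_carrier_or,
         sex_or = sex_or, age_or_per_sd = age_or_per_sd,
         lipid_means = lipid_means, lipid_sds = lipid_sds,
         treated_fraction = treated_fraction,
         seed = as.integer(seed)),
    class = "fh_cohort_params"
  )
}

.bmi_category <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 18.5, 25, 30, 35, 40, Inf), right = FALSE,
      labels = c("underweight", "healthy", "overweight",
                 "obesity_1", "obesity_2", "obesity_3")) |>
    as.character()
}

# therapy mix among treated participants: mostly moderate/high-intensity
# statins, as in a cardiology inpatient population
.therapy_levels <- c("statin_moderate", "statin_high", "statin_low",
                     "statin_high_ezetimibe")
.therapy_probs <- c(0.45, 0.30, 0.15, 0.10)

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a participant table with carrier status, demographics, an IHD
#' indicator from a logistic model (carrier log-odds `log(true_carrier_or)`
#' plus sex and standardized-age terms), lipid panels per carrier status, and
#' lipid-lowering therapy whose effect deflates the observed LDL-C by the
#' shipped correction factor for the assigned therapy class. The pre-treatment
#' LDL-C truth is returned so back-correction is testable.
#'
#' @param params a [cohort_sim_params()].
#' @return list: `participants` (tibble, one row each), `truth` (the params
#'   plus per-participant `ldl_true` and linear predictor).
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_sim_params(n_participants = 500, seed = 7))
#' dplyr::count(sim$participants, carrier)
simulate_cohort <- function(params = cohort_sim_params()) {
  if (!inherits(params, "fh_cohort_params")) {
    abort("params must come from cohort_sim_params()")
  }
  set.seed(params$seed)
  n <- params$n_participants
  sex <- ifelse(runif(n) < params$female_fraction, "female", "male")
  age <- .rtruncnorm(n, params$age_mean, params$age_sd, 18, 100)
  age_z <- (age - params$age_mean) / params$age_sd
  carrier <- runif(n) < params$carrier_prevalence
  eta <- params$baseline_ihd_logit +
    log(params$true_carrier_or) * carrier +
    log(params$sex_or) * (sex == "male") +
    log(params$age_or_per_sd) * age_z
  ihd <- runif(n) < stats::plogis(eta)

  draw_lipid <- function(nm, floor_at) {
    mu <- ifelse(carrier, params$lipid_means$carrier[[nm]],
                 params$lipid_means$non_carrier[[nm]])
    sg <- ifelse(carrier, params$lipid_sds$carrier[[nm]],
                 params$lipid_sds$non_carrier[[nm]])
    pmax(floor_at, rnorm(n, mu, sg))
  }
  tc <- draw_lipid("tc", 1.0)
  ldl_true <- draw_lipid("ldl", 0.3)
  hdl <- draw_lipid("hdl", 0.3)
  tg <- draw_lipid("tg", 0.2)

  treated <- runif(n) < params$treated_fraction
  therapy <- ifelse(treated,
                    sample(.therapy_levels, n, replace = TRUE,
                           prob = .therapy_probs),
                    "none")
  factors <- ldl_correction_table()
  f <- factors$factor[match(therapy, factors$therapy)]
  ldl_obs <- ldl_true / f
  tc_obs <- pmax(0.5, tc - (ldl_true - ldl_obs))

  bmi <- .rtruncnorm(n, 28, 5, 15, 60)
  smoking <- ifelse(runif(n) < 0.137, "dependent", "never_former")
  diabetes <- runif(n) < 0.22
  audit <- sample(0:6, n, replace = TRUE, prob = c(0.56, 0.1, 0.12, 0.08, 0.08, 0.04, 0.02))
  ihd_codes <- c("I20", "I21", "I25")
  other_codes <- c("I10", "I48", "I50", "I35", "I42")
  icd <- ifelse(ihd, sample(ihd_codes, n, replace = TRUE),
                sample(other_codes, n, replace = TRUE))

  participants <- tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    sex = sex,
    age = age,
    bmi = bmi,
    bmi_category = .bmi_category(bmi),
    smoking = smoking,
    diabetes = diabetes,
    alcohol_audit_c = audit,
    carrier = carrier,
    ihd = ihd,
    icd10_primary = as.list(icd),
    tc = tc_obs,
    ldl = ldl_obs,
    hdl = hdl,
    tg = tg,
    max_ldl_observed = ldl_obs,
    on_lipid_lowering = treated,
    therapy = therapy,
    prior_fh_diagnosis = FALSE
  )
  list(
    participants = participants,
    truth = list(params = params, ldl_true = ldl_true, linear_predictor = eta)
  )
}

# triage-branch strata with deterministic ground-truth classes; each entry is
# a recipe for annotation fields that force the named decision path
.annotation_strata <- c(
  "A_pathogenic", "A_likely_pathogenic", "B_consensus_pass", "B_fail",
  "C_supported", "C_unsupported", "D_review_pass", "E_expert_intervar",
  "E_review_pass", "F_deleterious", "F_vus",
  "excl_maf", "excl_benign", "excl_region", "excl_gene"
)

#' Annotation simulation parameters
#'
#' @param n_variants total variants to generate.
#' @param branch_mix named probabilities over the triage-branch strata (see
#'   `fhtriage:::.annotation_strata`); must sum to 1 and by default is uniform
#'   so every decision branch is reachable.
#' @param maf_rare_range MAF interval for candidate (rare) strata; its upper
#'   end must stay below the candidate MAF threshold.
#' @param maf_common_range MAF interval for the MAF-excluded stratum.
#' @param prob_maf_missing chance a rare variant has no gnomAD record.
#' @param seed integer.
#' @return list of class `fh_annotation_params`.
#' @export
annotation_sim_params <- function(n_variants = 60,
                                  branch_mix = NULL,
                                  maf_rare_range = c(0, 9e-5),
                                  maf_common_range = c(1e-3, 1e-2),
                                  prob_maf_missing = 0.3,
                                  seed = 1L) {
  if (is.null(branch_mix)) {
    branch_mix <- setNames(rep(1 / length(.annotation_strata),
                               length(.annotation_strata)),
                           .annotation_strata)
  }
  if (!all(names(branch_mix) %in% .annotation_strata)) {
    abort("branch_mix names must be triage-branch strata")
  }
  if (abs(sum(branch_mix) - 1) > 1e-8) abort("branch_mix must sum to 1")
  .check_fraction(prob_maf_missing, "prob_maf_missing")
  structure(
    list(n_variants = as.integer(n_variants), branch_mix = branch_mix,
         maf_rare_range = maf_rare_range, maf_common_range = maf_common_range,
         prob_maf_missing = prob_maf_missing, seed = as.integer(seed)),
    class = "fh_annotation_params"
  )
}

# passing / failing predictor score draws for the five-predictor consensus
.scores_pass <- function() {
  c(sift = runif(1, 0, 0.04), polyphen2_hdiv = runif(1, 0.95, 1),
    mutation_assessor = runif(1, 2, 4), m_cap = runif(1, 0.03, 0.4),
    cadd = runif(1, 15, 35))
}
.scores_fail <- function() {
  c(sift = runif(1, 0.2, 1), polyphen2_hdiv = runif(1, 0, 0.5),
    mutation_assessor = runif(1, 0, 1.5), m_cap = runif(1, 0, 0.02),
    cadd = runif(1, 0, 10))
}

#' Generate a branch-covering annotation table with ground truth
#'
#' Each generated variant is built to travel one specific path of the triage
#' decision tree and is tagged with the class the engine must output, so the
#' engine can be checked for exact agreement.
#'
#' @param params an [annotation_sim_params()].
#' @return list: `annotations` (tibble in the [validate_annotations()] schema)
#'   and `truth` (tibble: `variant_id`, `stratum`, `true_class`,
#'   `true_excluded`).
#' @export
simulate_annotations <- function(params = annotation_sim_params()) {
  if (!inherits(params, "fh_annotation_params")) {
    abort("params must come from annotation_sim_params()")
  }
  set.seed(params$seed)
  strata <- sample(names(params$branch_mix), params$n_variants, replace = TRUE,
                   prob = params$branch_mix)
  gene_pos <- list(LDLR = c("chr19", 11089000), APOB = c("chr2", 21001429),
                   PCSK9 = c("chr1", 55039000))
  rare_maf <- function() {
    if (runif(1) < params$prob_maf_missing) NA_real_
    else runif(1, params$maf_rare_range[1], params$maf_rare_range[2])
  }
  rows <- imap(strata, function(stratum, i) {
    gene <- if (stratum %in% c("F_deleterious", "F_vus")) "LDLR"
            else if (stratum == "excl_gene") "APOE"
            else sample(c("LDLR", "APOB", "PCSK9"), 1)
    base <- list(
      variant_id = sprintf("%s:%d:%s:%s",
                           gene_pos[[if (gene == "APOE") "LDLR" else gene]][1],
                           as.integer(gene_pos[[if (gene == "APOE") "LDLR" else gene]][2]) + i,
                           "A", "G"),
      gene = gene, region = "exonic", variant_type = "SNV",
      consequence = "missense", gnomad_maf = rare_maf(),
      clinvar_class = "VUS", clinvar_review = "single_submitter",
      intervar_class = "VUS",
      sift = NA_real_, polyphen2_hdiv = NA_real_, mutation_assessor = NA_real_,
      m_cap = NA_real_, cadd = NA_real_, revel = NA_real_, metalr = NA_real_,
      metasvm = NA_real_, clinical_case_support = FALSE
    )
    pass <- .scores_pass(); fail <- .scores_fail()
    apply_scores <- function(base, s) {
      base[names(s)] <- as.list(s); base
    }
    truth <- switch(stratum,
      A_pathogenic = {
        base$clinvar_class <- "P"
        base$clinvar_review <- sample(c("expert_panel", "multiple_submitters"), 1)
        base$intervar_class <- sample(c("P", "LP"), 1)
        "Pathogenic"
      },
      A_likely_pathogenic = {
        base$clinvar_class <- "LP"
        base$clinvar_review <- sample(c("expert_panel", "multiple_submitters"), 1)
        base$intervar_class <- "LP"
        "LikelyPathogenic"
      },
      B_consensus_pass = {
        base$clinvar_class <- sample(c("P", "LP"), 1)
        base$clinvar_review <- "multiple_submitters"
        base$intervar_class <- "VUS"
        base <- apply_scores(base, pass)
        "LikelyPathogenic"
      },
      B_fail = {
        base$clinvar_class <- sample(c("P", "LP"), 1)
        base$clinvar_review <- "multiple_submitters"
        base$intervar_class <- "VUS"
        base <- apply_scores(base, fail)
        "VUS"
      },
      C_supported = {
        base$clinvar_class <- "P"
        base$clinvar_review <- "single_submitter"
        base$intervar_class <- "LP"
        base$clinical_case_support <- TRUE
        "Pathogenic"
      },
      C_unsupported = {
        base$clinvar_class <- "P"
        base$clinvar_review <- "single_submitter"
        base$intervar_class <- sample(c("LP", "not_available"), 1)
        base <- apply_scores(base, fail)
        "VUS"
      },
      D_review_pass = {
        base$clinvar_class <- "LP"
        base$clinvar_review <- "single_submitter"
        base$intervar_class <- "LP"
        base <- apply_scores(base, pass)
        "LikelyPathogenic"
      },
      E_expert_intervar = {
        base$clinvar_class <- sample(c("VUS", "not_reported"), 1)
        base$clinvar_review <- "expert_panel"
        base$intervar_class <- "P"
        "Pathogenic"
      },
      E_review_pass = {
        base$clinvar_class <- "not_reported"
        base$clinvar_review <- "none"
        base$intervar_class <- "LP"
        base <- apply_scores(base, pass)
        "LikelyPathogenic"
      },
      F_deleterious = {
        base$metalr <- runif(1, 0.55, 1)
        base$metasvm <- runif(1, 0.1, 1)
        "VUS_deleterious"
      },
      F_vus = {
        base$metalr <- runif(1, 0, 0.45)
        base$metasvm <- runif(1, -1, -0.1)
        "VUS"
      },
      excl_maf = {
        base$gnomad_maf <- runif(1, params$maf_common_range[1],
                                 params$maf_common_range[2])
        "Excluded"
      },
      excl_benign = {
        base$clinvar_class <- sample(c("B", "LB"), 1)
        "Excluded"
      },
      excl_region = {
        base$region <- "other"
        base$consequence <- "other"
        "Excluded"
      },
      excl_gene = "Excluded"
    )
    c(base, list(stratum = stratum, true_class = truth))
  })
  tab <- rows |> map(as_tibble) |> list_rbind()
  annotations <- tab |> select(all_of(.annotation_cols))
  truth <- tab |>
    transmute(variant_id, stratum = .data$stratum,
              true_class = .data$true_class,
              true_excluded = .data$true_class == "Excluded")
  list(annotations = annotations, truth = truth)
}
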
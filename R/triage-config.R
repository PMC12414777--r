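#' Triage configuration
#'
#' Thresholds and panel definition for the variant triage engine. Defaults
#' follow standard FH screening practice: panel restricted to the three
#' autosomal-dominant FH genes, candidate variants limited to exonic/splice
#' SNVs and indels with gnomAD MAF below 0.01% (or absent from gnomAD), and
#' the in-silico predictor cutoffs used for the likely-pathogenic consensus.
#'
#' @param panel_genes character vector of genes considered FH-causal.
#' @param maf_threshold candidate variants must have gnomAD MAF strictly below
#'   this value (or no gnomAD record). Default 1e-4, i.e. 0.01%.
#' @param rare_missense_maf_threshold MAF bound (strict) for the rare LDLR
#'   missense rule that can promote a VUS to "VUS predicted to be deleterious".
#' @param sift_max,polyphen2_hdiv_min,mutation_assessor_min,m_cap_min,cadd_min
#'   cutoffs for the five primary predictors. SIFT is damaging below its
#'   cutoff (strict); M-CAP is damaging strictly above; PolyPhen-2 HDIV,
#'   MutationAssessor and CADD at-or-above.
#' @param consensus_min_agree number of primary predictors that must agree for
#'   in-silico support of likely-pathogenic status (default 3 of 5).
#' @param revel_min,metalr_min tie-breaker cutoffs applied to inconclusive
#'   interpretations: REVEL strictly above `revel_min` AND MetaLR strictly
#'   above `metalr_min`.
#' @param metasvm_min MetaSVM calls a variant deleterious when its score is
#'   strictly above this value (published cutoff 0: positive scores are
#'   deleterious). Used with MetaLR (> `metalr_min`) in the rare-missense rule.
#' @param clinvar_multi_pick how to collapse coexisting P and LP assertions
#'   from multiple submitters before triage: `"most_severe"` (default) or
#'   `"least_severe"`. Annotation tables carry a single class; this documents
#'   the upstream collapse the engine assumes.
#'
#' @return a list of class `fh_triage_config`.
#' @export
#' @examples
#' cfg <- triage_config()
#' cfg$maf_threshold
triage_config <- function(panel_genes = c("LDLR", "APOB", "PCSK9"),
                          maf_threshold = 1e-4,
                          rare_missense_maf_threshold = 5e-4,
                          sift_max = 0.05,
                          polyphen2_hdiv_min = 0.95,
                          mutation_assessor_min = 2,
                          m_cap_min = 0.025,
                          cadd_min = 15,
                          consensus_min_agree = 3,
                          revel_min = 0.75,
                          metalr_min = 0.5,
                          metasvm_min = 0,
                          clinvar_multi_pick = c("most_severe", "least_severe")) {
  stopifnot(maf_threshold > 0, rare_missense_maf_threshold > 0,
            consensus_min_agree >= 1, consensus_min_agree <= 5)
  structure(
    list(
      panel_genes = panel_genes,
      maf_threshold = maf_threshold,
      rare_missense_maf_threshold = rare_missense_maf_threshold,
      sift_max = sift_max,
      polyphen2_hdiv_min = polyphen2_hdiv_min,
      mutation_assessor_min = mutation_assessor_min,
      m_cap_min = m_cap_min,
      cadd_min = cadd_min,
      consensus_min_agree = consensus_min_agree,
      revel_min = revel_min,
      metalr_min = metalr_min,
      metasvm_min = metasvm_min,
      clinvar_multi_pick = match.arg(clinvar_multi_pick)
    ),
    class = "fh_triage_config"
  )
}

# controlled vocabularies shared by the triage engine and validators
.clinvar_classes  <- c("P", "LP", "VUS", "B", "LB", "conflicting", "not_reported")
.clinvar_reviews  <- c("expert_panel", "multiple_submitters", "single_submitter",
                       "criteria_not_provided", "none")
.intervar_classes <- c("P", "LP", "VUS", "B", "LB", "not_available")
.regions          <- c("exonic", "splice_site", "other")
.variant_types    <- c("SNV", "indel")
.consequences     <- c("missense", "nonsense", "frameshift", "inframe_del",
                       "splice", "synonymous", "other")
.final_classes    <- c("Pathogenic", "LikelyPathogenic", "VUS_deleterious",
                       "VUS", "Excluded")
.score_cols       <- c("sift", "polyphen2_hdiv", "mutation_assessor", "m_cap",
                       "cadd", "revel", "metalr", "metasvm")

.annotation_cols <- c(
  "variant_id", "gene", "region", "variant_type", "consequence", "gnomad_maf",
  "clinvar_class", "clinvar_review", "intervar_class", .score_cols,
  "clinical_case_support"
)

#' Validate a variant annotation table
#'
#' Checks the column contract and controlled vocabularies of a per-variant
#' annotation table. All violations are collected and reported together with
#' row indices, never truncated at the first failure.
#'
#' @param annotations a data frame of variant annotations (one row per variant).
#' @return the table as a tibble, invisibly validated.
#' @export
validate_annotations <- function(annotations) {
  annotations <- as_tibble(annotations)
  missing_cols <- setdiff(.annotation_cols, names(annotations))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  problems <- character()
  bad_row <- function(idx, what) {
    if (any(idx)) {
      problems <<- c(problems, paste0(what, " (rows ",
                                      paste(which(idx), collapse = ", "), ")"))
    }
  }
  bad_row(!annotations$clinvar_class %in% .clinvar_classes, "unknown clinvar_class")
  bad_row(!annotations$clinvar_review %in% .clinvar_reviews, "unknown clinvar_review")
  bad_row(!annotations$intervar_class %in% .intervar_classes, "unknown intervar_class")
  bad_row(!annotations$region %in% .regions, "unknown region")
  bad_row(!annotations$variant_type %in% .variant_types, "unknown variant_type")
  bad_row(!annotations$consequence %in% .consequences, "unknown consequence")
  maf <- annotations$gnomad_maf
  bad_row(!is.na(maf) & (maf < 0 | maf > 1 | !is.finite(maf)), "malformed gnomad_maf")
  if (length(problems) > 0) {
    abort(paste0("annotation validation failed:\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }
  annotations
}
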
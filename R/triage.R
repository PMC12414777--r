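#' Partition variants into triage candidates and exclusions
#'
#' Applies the study's candidate filter: panel-gene variants located in exons
#' or splice sites, of type SNV or indel, with gnomAD MAF strictly below the
#' configured threshold (variants absent from gnomAD are kept), and not
#' asserted benign/likely benign in ClinVar. Each excluded row carries the
#' first failing rule in the fixed order gene, region, type, MAF, benign.
#'
#' @param annotations annotation table (see [validate_annotations()]).
#' @param config a [triage_config()].
#' @return the input tibble with two added columns: `candidate` (logical) and
#'   `exclusion_reason` (`NA` for candidates; otherwise one of
#'   `"gene_not_in_panel"`, `"region"`, `"variant_type"`, `"maf"`,
#'   `"benign_in_clinvar"`).
#' @export
#' @examples
#' ann <- simulate_annotations(annotation_sim_params(n_variants = 30, seed = 1))
#' filter_candidates(ann$annotations, triage_config()) |> dplyr::count(exclusion_reason)
filter_candidates <- function(annotations, config = triage_config()) {
  annotations <- validate_annotations(annotations)
  reason <- rep(NA_character_, nrow(annotations))
  fail <- function(reason_now, idx, label) {
    ifelse(is.na(reason_now) & idx, label, reason_now)
  }
  reason <- fail(reason, !annotations$gene %in% config$panel_genes, "gene_not_in_panel")
  reason <- fail(reason, !annotations$region %in% c("exonic", "splice_site"), "region")
  reason <- fail(reason, !annotations$variant_type %in% c("SNV", "indel"), "variant_type")
  maf_ok <- is.na(annotations$gnomad_maf) | annotations$gnomad_maf < config$maf_threshold
  reason <- fail(reason, !maf_ok, "maf")
  reason <- fail(reason, annotations$clinvar_class %in% c("B", "LB"), "benign_in_clinvar")
  annotations |>
    mutate(candidate = is.na(reason), exclusion_reason = reason)
}

#' In-silico predictor consensus
#'
#' Counts how many of the five primary predictors (SIFT, PolyPhen-2 HDIV,
#' MutationAssessor, M-CAP, CADD) are present and call the variant damaging at
#' the configured cutoffs. Agreement of three or more is treated as in-silico
#' evidence of likely-pathogenic status. Missing scores never contribute and
#' never error.
#'
#' @param scores a one-row data frame or named list with (optionally missing)
#'   elements `sift`, `polyphen2_hdiv`, `mutation_assessor`, `m_cap`, `cadd`.
#' @param config a [triage_config()].
#' @return list with `n_agree`, `supports_lp` (n_agree >= quorum) and
#'   `evaluable` (at least quorum scores present at all).
#' @export
insilico_consensus <- function(scores, config = triage_config()) {
  g <- function(nm) {
    v <- scores[[nm]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  calls <- c(
    sift              = g("sift") < config$sift_max,
    polyphen2_hdiv    = g("polyphen2_hdiv") >= config$polyphen2_hdiv_min,
    mutation_assessor = g("mutation_assessor") >= config$mutation_assessor_min,
    m_cap             = g("m_cap") > config$m_cap_min,
    cadd              = g("cadd") >= config$cadd_min
  )
  n_present <- sum(!is.na(calls))
  n_agree <- sum(calls, na.rm = TRUE)
  list(
    n_agree = n_agree,
    supports_lp = n_agree >= config$consensus_min_agree,
    evaluable = n_present >= config$consensus_min_agree
  )
}

#' Tie-break for inconclusive interpretations
#'
#' When the primary consensus is not evaluable (too few scores) the engine
#' falls back to REVEL and MetaLR: both must be present and both must exceed
#' their cutoffs. A missing score is not evidence.
#'
#' @inheritParams insilico_consensus
#' @return single logical.
#' @export
tiebreak_inconclusive <- function(scores, config = triage_config()) {
  revel <- scores[["revel"]]
  metalr <- scores[["metalr"]]
  isTRUE(!is.null(revel) && !is.null(metalr) &&
           !is.na(revel) && !is.na(metalr) &&
           revel > config$revel_min && metalr > config$metalr_min)
}

# shared manual-review outcome: likely pathogenic on consensus or clinical
# evidence; tie-breaker only when the consensus could not be evaluated at all
.review_path <- function(consensus, tiebreak, clinical_support) {
  if (consensus$supports_lp || isTRUE(clinical_support)) return("LikelyPathogenic")
  if (!consensus$evaluable && tiebreak) return("LikelyPathogenic")
  "VUS"
}

.map_clinvar <- function(cls) c(P = "Pathogenic", LP = "LikelyPathogenic")[[cls]]

#' Classify one candidate variant
#'
#' Assigns the final class by the study's decision procedure, which integrates
#' the ClinVar assertion and its review status, an InterVar-style automated
#' interpretation, predictor consensus and (for single-submitter pathogenic
#' assertions) external clinical-case evidence. The decision path taken is
#' recorded for audit:
#'
#' * **A** ClinVar P/LP with expert-panel or multiple-submitter review,
#'   confirmed P/LP by InterVar: the ClinVar class stands.
#' * **B** ClinVar P/LP but InterVar VUS: manual-review path (consensus or
#'   clinical evidence upgrades to likely pathogenic, tie-breaker when the
#'   consensus is not evaluable, else VUS).
#' * **C** ClinVar P with single-submitter / criteria-not-provided review:
#'   pathogenic only when clinical-case evidence plus InterVar or consensus
#'   support it; otherwise the review-path outcome.
#' * **D** ClinVar LP with weak review status: review path.
#' * **E** ClinVar VUS / unreported / conflicting: InterVar P/LP with
#'   expert-panel review stands; InterVar P/LP otherwise goes to the review
#'   path; InterVar VUS proceeds to the rare-missense rule for LDLR.
#' * **F** rare LDLR missense (MAF below the rare-missense bound or absent)
#'   called deleterious by both MetaLR and MetaSVM: "VUS predicted to be
#'   deleterious"; otherwise VUS.
#'
#' Branches are tried in order A..F; the first match fires.
#'
#' @param annotation one-row data frame or named list for a candidate variant.
#' @param config a [triage_config()].
#' @return list: `final_class`, `fired_branch`, `evidence_summary`.
#' @export
classify_variant <- function(annotation, config = triage_config()) {
  cv <- annotation[["clinvar_class"]]
  rv <- annotation[["clinvar_review"]]
  iv <- annotation[["intervar_class"]]
  clinical <- isTRUE(annotation[["clinical_case_support"]])
  consensus <- insilico_consensus(annotation, config)
  tb <- tiebreak_inconclusive(annotation, config)
  notes <- character()

  if (cv == "conflicting") {
    # conflicting submitters are not resolved here: treated as uncertain and
    # routed through the ClinVar-VUS arm, flagged for manual review
    notes <- c(notes, "conflicting ClinVar interpretations treated as VUS; flagged for manual review")
    cv <- "VUS"
  }

  pathogenic_tier <- cv %in% c("P", "LP")
  strong_review <- rv %in% c("expert_panel", "multiple_submitters")

  finish <- function(class, branch) {
    list(
      final_class = class,
      fired_branch = branch,
      evidence_summary = paste(
        c(sprintf("clinvar=%s/%s intervar=%s consensus=%d/5%s%s",
                  annotation[["clinvar_class"]], rv, iv, consensus$n_agree,
                  if (clinical) " clinical_support" else "",
                  if (tb) " tiebreak_pass" else ""),
          notes),
        collapse = "; ")
    )
  }

  if (pathogenic_tier && strong_review && iv %in% c("P", "LP")) {
    return(finish(.map_clinvar(cv), "A"))
  }
  if (pathogenic_tier && iv == "VUS") {
    return(finish(.review_path(consensus, tb, clinical), "B"))
  }
  if (cv == "P") {
    # weak review status: single submitter / criteria not provided / none
    supported <- clinical && (consensus$supports_lp || iv %in% c("P", "LP"))
    if (supported) return(finish("Pathogenic", "C"))
    return(finish(.review_path(consensus, tb, clinical), "C"))
  }
  if (cv == "LP") {
    return(finish(.review_path(consensus, tb, clinical), "D"))
  }
  # cv is VUS or not_reported from here on
  if (iv %in% c("P", "LP")) {
    if (rv == "expert_panel") {
      return(finish(c(P = "Pathogenic", LP = "LikelyPathogenic")[[iv]], "E"))
    }
    return(finish(.review_path(consensus, tb, clinical), "E"))
  }
  # InterVar uncertain (or benign-leaning / unavailable): only the rare LDLR
  # missense rule can promote the variant further
  if (annotation[["gene"]] == "LDLR" && annotation[["consequence"]] == "missense") {
    maf <- annotation[["gnomad_maf"]]
    rare <- is.na(maf) || maf < config$rare_missense_maf_threshold
    metalr <- annotation[["metalr"]]
    metasvm <- annotation[["metasvm"]]
    both_deleterious <- isTRUE(!is.na(metalr) && !is.na(metasvm) &&
                                 metalr > config$metalr_min &&
                                 metasvm > config$metasvm_min)
    if (rare && both_deleterious) return(finish("VUS_deleterious", "F"))
    return(finish("VUS", "F"))
  }
  finish("VUS", "E")
}

#' Classify all variants in an annotation table
#'
#' Runs [filter_candidates()] then [classify_variant()] over every candidate.
#'
#' @inheritParams filter_candidates
#' @return list with `classified` (tibble: `variant_id`, `gene`, `final_class`,
#'   `fired_branch`, `exclusion_reason`, `evidence_summary`; one row per input
#'   variant, excluded rows classed `"Excluded"`) and `summary` (counts per
#'   gene and final class).
#' @export
#' @examples
#' sim <- simulate_annotations(annotation_sim_params(n_variants = 40, seed = 7))
#' res <- classify_variants(sim$annotations)
#' res$summary
classify_variants <- function(annotations, config = triage_config()) {
  flt <- filter_candidates(annotations, config)
  rows <- seq_len(nrow(flt))
  out <- map(rows, function(i) {
    row <- flt[i, ]
    if (!row$candidate) {
      return(list(final_class = "Excluded",
                  fired_branch = "filter",
                  evidence_summary = paste0("excluded: ", row$exclusion_reason)))
    }
    tryCatch(
      classify_variant(row, config),
      error = function(e) abort(paste0("classification failed at row ", i, ": ",
                                       conditionMessage(e)))
    )
  })
  classified <- flt |>
    mutate(
      final_class = factor(map_chr(out, "final_class"), levels = .final_classes),
      fired_branch = map_chr(out, "fired_branch"),
      evidence_summary = map_chr(out, "evidence_summary")
    ) |>
    select(variant_id, gene, final_class, fired_branch, exclusion_reason,
           evidence_summary)
  summary <- classified |>
    count(gene, final_class, .drop = FALSE, name = "n") |>
    filter(gene %in% config$panel_genes | n > 0)
  list(classified = classified, summary = summary)
}
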
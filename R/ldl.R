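#' Default LDL-C treatment correction-factor table
#'
#' Multiplicative factors used to back-correct an on-treatment LDL-C
#' measurement to its estimated pre-treatment value, following the
#' correction-factor approach used in specialist FH services (factor applied
#' to the observed value; untreated patients get the identity factor). The
#' shipped values are derived from the canonical average percent LDL-C
#' reductions by therapy intensity class, `factor = 1 / (1 - reduction)`:
#'
#' | therapy | assumed reduction | factor |
#' |---|---|---|
#' | none | 0% | 1.00 |
#' | ezetimibe | 18% | 1.22 |
#' | statin_low | 30% | 1.43 |
#' | statin_moderate | 38% | 1.61 |
#' | statin_high | 50% | 2.00 |
#' | statin_moderate_ezetimibe | 48% | 1.92 |
#' | statin_high_ezetimibe | 60% | 2.50 |
#'
#' This table is pure configuration: supply your own (same two columns) to use
#' drug/dose-specific published factors.
#'
#' @return tibble with columns `therapy` and `factor` (all factors >= 1,
#'   identity for `"none"`).
#' @export
#' @examples
#' ldl_correction_table()
ldl_correction_table <- function() {
  tibble(
    therapy = c("none", "ezetimibe", "statin_low", "statin_moderate",
                "statin_high", "statin_moderate_ezetimibe",
                "statin_high_ezetimibe"),
    factor = c(1, 1 / 0.82, 1 / 0.70, 1 / 0.62, 1 / 0.50, 1 / 0.52, 1 / 0.40)
  )
}

#' Back-correct observed LDL-C to its pre-treatment value
#'
#' Multiplies each observed LDL-C by the correction factor for the therapy the
#' patient was on when the value was recorded. No therapy means no change.
#'
#' @param observed numeric vector of observed LDL-C, mmol/L (must be >= 0).
#' @param therapy character vector (recycled if length 1) of therapy labels
#'   matching `correction_table$therapy`; `NA` is treated as `"none"`.
#' @param correction_table two-column table, see [ldl_correction_table()].
#' @return numeric vector of corrected LDL-C values, mmol/L.
#' @export
#' @examples
#' correct_pretreatment_ldl(c(3.5, 2.0), c("none", "statin_high"))
correct_pretreatment_ldl <- function(observed, therapy,
                                     correction_table = ldl_correction_table()) {
  if (any(!is.na(observed) & observed < 0)) {
    abort("observed LDL-C must be non-negative")
  }
  if (any(correction_table$factor < 1)) {
    abort("correction factors must be >= 1")
  }
  therapy <- rep_len(as.character(therapy), length(observed))
  therapy[is.na(therapy)] <- "none"
  unknown <- setdiff(unique(therapy), correction_table$therapy)
  if (length(unknown) > 0) {
    abort(paste0("therapy label(s) not in correction table: ",
                 paste(unknown, collapse = ", ")))
  }
  factors <- correction_table$factor[match(therapy, correction_table$therapy)]
  observed * factors
}

# carrier subgroup labels used throughout penetrance / association reporting;
# mirrors the published table layout: all carriers, all LDLR, LDLR split by
# final class, and APOB
.penetrance_groups <- c("all", "LDLR", "LDLR_PVLP", "LDLR_VUSdel", "APOB")

.subgroup_members <- function(carriers, group) {
  switch(group,
    all = rep(TRUE, nrow(carriers)),
    LDLR = carriers$gene == "LDLR",
    LDLR_PVLP = carriers$subgroup == "LDLR_PVLP",
    LDLR_VUSdel = carriers$subgroup == "LDLR_VUSdel",
    APOB = carriers$gene == "APOB"
  )
}

#' Per-group variant penetrance from maximum corrected LDL-C
#'
#' Penetrance is the fraction of analysis-eligible carriers whose maximum
#' recorded LDL-C, back-corrected for lipid-lowering therapy, reaches the
#' gene-appropriate threshold: >= 4.0 mmol/L for LDLR variants and
#' >= 4.9 mmol/L for APOB variants. Both fixed thresholds are also reported
#' for every group so the output mirrors the published clinical table.
#'
#' @param carrier_set analysis carrier set from [apply_exclusions()].
#' @param participants participant table with `participant_id`,
#'   `max_ldl_observed` and `therapy` columns.
#' @param thresholds named numeric, gene -> threshold (mmol/L).
#' @param correction_table see [ldl_correction_table()].
#' @return tibble of class `fh_penetrance`: one row per carrier group with
#'   `n`, counts/fractions at 4.0 and 4.9 mmol/L, and the gene-rule
#'   `n_above_threshold` / `penetrance` (threshold chosen per carried gene).
#'   Carriers with no recorded maximum LDL-C are dropped with a message.
#' @export
penetrance <- function(carrier_set, participants,
                       thresholds = c(LDLR = 4.0, APOB = 4.9),
                       correction_table = ldl_correction_table()) {
  eligible <- carrier_set |> filter(.data$analysis_eligible)
  if (nrow(eligible) == 0) {
    warn("no analysis-eligible carriers; penetrance is undefined")
    return(structure(tibble(group = character(), n = integer()),
                     class = c("fh_penetrance", class(tibble()))))
  }
  dat <- eligible |>
    inner_join(participants |>
                 select("participant_id", "max_ldl_observed", "therapy"),
               by = "participant_id")
  n_missing <- sum(is.na(dat$max_ldl_observed))
  if (n_missing > 0) {
    inform(paste0(n_missing, " carrier(s) without a recorded maximum LDL-C excluded from penetrance"))
    dat <- dat |> filter(!is.na(.data$max_ldl_observed))
  }
  dat <- dat |>
    mutate(
      ldl_corrected = correct_pretreatment_ldl(.data$max_ldl_observed,
                                               .data$therapy, correction_table),
      gene_threshold = unname(thresholds[.data$gene])
    )
  if (any(is.na(dat$gene_threshold))) {
    abort("no penetrance threshold supplied for at least one carried gene")
  }
  out <- map(.penetrance_groups, function(g) {
    sub <- dat[.subgroup_members(dat, g), ]
    tibble(
      group = g,
      n = nrow(sub),
      n_ge_4_0 = sum(sub$ldl_corrected >= 4.0),
      pen_4_0 = ifelse(nrow(sub) > 0, sum(sub$ldl_corrected >= 4.0) / nrow(sub), NA_real_),
      n_ge_4_9 = sum(sub$ldl_corrected >= 4.9),
      pen_4_9 = ifelse(nrow(sub) > 0, sum(sub$ldl_corrected >= 4.9) / nrow(sub), NA_real_),
      n_above_threshold = sum(sub$ldl_corrected >= sub$gene_threshold),
      penetrance = ifelse(nrow(sub) > 0,
                          sum(sub$ldl_corrected >= sub$gene_threshold) / nrow(sub),
                          NA_real_)
    )
  }) |> list_rbind()
  structure(out, class = c("fh_penetrance", class(out)))
}
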
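#' Assign carrier status from genotypes and classified variants
#'
#' A participant is a carrier of every reportable variant (final class
#' Pathogenic, LikelyPathogenic or "VUS predicted to be deleterious") for
#' which they have at least one alternate allele. Genotypes referencing
#' variant ids absent from the classified table are an error.
#'
#' @param genotypes tibble with `participant_id`, `variant_id` and `genotype`
#'   (`"0/1"`, `"1/1"`, `"0|1"`, ... or an integer alternate-allele count;
#'   half-calls like `"./1"` are treated as missing with a warning).
#' @param classified_variants the `classified` tibble from
#'   [classify_variants()] (or any table with `variant_id`, `gene`,
#'   `final_class`).
#' @return tibble of class `fh_carrier_set`: one row per carrier with
#'   `participant_id`, `n_variants`, list-columns `variant_ids`, `genes`,
#'   `classes`, and `multi_variant` flag.
#' @export
assign_carriers <- function(genotypes, classified_variants) {
  genotypes <- as_tibble(genotypes)
  unknown <- setdiff(unique(genotypes$variant_id),
                     classified_variants$variant_id)
  if (length(unknown) > 0) {
    abort(paste0("genotypes reference unknown variant id(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  gt <- as.character(genotypes$genotype)
  half <- (str_detect(gt, "^\\.[/|][0-9]") | str_detect(gt, "^[0-9][/|]\\.$"))
  half <- half & !gt %in% c("./.", ".|.")
  if (any(half, na.rm = TRUE)) {
    warn(paste0(sum(half, na.rm = TRUE),
                " half-call genotype(s) treated as missing"))
  }
  n_alt <- ifelse(
    half | is.na(gt) | gt %in% c("./.", ".|.", "."),
    NA_integer_,
    ifelse(str_detect(gt, "^[0-9.]+[/|][0-9.]+$"),
           str_count_alt(gt),
           suppressWarnings(as.integer(gt)))
  )
  reportable <- classified_variants |>
    filter(as.character(.data$final_class) %in%
             c("Pathogenic", "LikelyPathogenic", "VUS_deleterious")) |>
    select("variant_id", "gene", class = "final_class")
  carried <- genotypes |>
    mutate(n_alt = n_alt) |>
    filter(!is.na(.data$n_alt), .data$n_alt > 0) |>
    inner_join(reportable, by = "variant_id")
  out <- carried |>
    group_by(.data$participant_id) |>
    summarise(
      n_variants = n(),
      variant_ids = list(.data$variant_id),
      genes = list(.data$gene),
      classes = list(as.character(.data$class)),
      .groups = "drop"
    ) |>
    mutate(multi_variant = .data$n_variants > 1)
  structure(out, class = c("fh_carrier_set", class(out)))
}

# alt-allele count from a diploid GT string (missing alleles already screened)
str_count_alt <- function(gt) {
  alleles <- str_split(gt, "[/|]")
  map_dbl(alleles, function(a) sum(a != "0" & a != "."))
}

#' Apply the cohort exclusion rules to a carrier set
#'
#' Reproduces the study's analysis-population rules: carriers of two variants,
#' proband relatives hospitalised through family cascade screening (supplied
#' externally), and carriers of the APOB p.Gln4494del variant (whose carriers
#' showed no FH phenotype) are removed from the association population.
#' Exclusion precedence: two variants, then cascade relative, then
#' p.Gln4494del. The operation is idempotent.
#'
#' @param carrier_set from [assign_carriers()].
#' @param cascade_ids participant ids flagged as cascade-screened proband
#'   relatives.
#' @param q4494del_variant_ids variant id(s) of APOB p.Gln4494del in this
#'   annotation set (empty if absent).
#' @return the carrier set with `exclusion_reason` (`"none"`,
#'   `"two_variants"`, `"cascade_proband_relative"`, `"q4494del_carrier"`),
#'   `analysis_eligible`, and for eligible single-variant carriers scalar
#'   `gene`, `class` and `subgroup` (`LDLR_PVLP`, `LDLR_VUSdel`, `APOB`).
#' @export
apply_exclusions <- function(carrier_set, cascade_ids = character(),
                             q4494del_variant_ids = character()) {
  out <- carrier_set |>
    mutate(
      has_q4494del = map_lgl(.data$variant_ids,
                             ~ any(.x %in% q4494del_variant_ids)),
      exclusion_reason = case_when(
        multi_variant ~ "two_variants",
        participant_id %in% cascade_ids ~ "cascade_proband_relative",
        has_q4494del ~ "q4494del_carrier",
        TRUE ~ "none"
      ),
      analysis_eligible = .data$exclusion_reason == "none",
      gene = ifelse(.data$analysis_eligible, map_chr(.data$genes, 1), NA),
      class = ifelse(.data$analysis_eligible, map_chr(.data$classes, 1), NA),
      subgroup = case_when(
        !analysis_eligible ~ NA_character_,
        gene == "LDLR" & class %in% c("Pathogenic", "LikelyPathogenic") ~ "LDLR_PVLP",
        gene == "LDLR" & class == "VUS_deleterious" ~ "LDLR_VUSdel",
        gene == "APOB" ~ "APOB",
        TRUE ~ "other"
      )
    ) |>
    select(-"has_q4494del")
  if (sum(out$analysis_eligible) == 0) {
    warn("no carriers remain after exclusions; downstream comparisons are degenerate")
  }
  class(out) <- unique(c("fh_carrier_set", class(out)))
  out
}

#' Exclusion counts for a carrier set
#'
#' @param carrier_set an excluded carrier set from [apply_exclusions()].
#' @return tibble of exclusion reasons and counts.
#' @export
exclusion_counts <- function(carrier_set) {
  carrier_set |> count(.data$exclusion_reason, name = "n")
}
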
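#' Dutch Lipid Clinic Network point table
#'
#' The standard published DLCN point scheme. Within each criterion group only
#' the highest applicable item scores; the total is the sum over groups.
#'
#' @return list with per-group point values, LDL-C band edges (mmol/L) and the
#'   category cut-points (unlikely < 3, possible 3-5, probable 6-8,
#'   definite > 8).
#' @export
dlcn_point_table <- function() {
  list(
    family = c(relative_premature_cvd_or_high_ldl = 1,
               relative_xanthoma_arcus_or_child_high_ldl = 2),
    clinical = c(premature_cad = 2, premature_cerebral_peripheral = 1),
    physical = c(tendon_xanthoma = 6, arcus_cornealis_under_45 = 4),
    # band lower edges (mmol/L) -> points
    ldl_bands = tibble(
      lower = c(8.5, 6.5, 5.0, 4.0),
      points = c(8L, 5L, 3L, 1L)
    ),
    dna = c(causal_mutation = 8),
    categories = tibble(
      category = c("unlikely", "possible", "probable", "definite"),
      min_points = c(-Inf, 3, 6, 9)
    )
  )
}

.dlcn_ldl_points <- function(ldl, bands) {
  idx <- which(ldl >= bands$lower)
  if (length(idx) == 0) 0L else bands$points[min(idx)]
}

.dlcn_category <- function(total, categories) {
  categories$category[max(which(total >= categories$min_points))]
}

#' Dutch Lipid Clinic Network score for one participant
#'
#' Computes DLCNS component points and category from clinical inputs and an
#' (ideally pre-treatment-corrected) LDL-C value. Missing inputs (`NA`) score
#' zero and are listed in `missing_components`. Because it can be ambiguous
#' whether the genetic criterion was available when a clinical diagnosis was
#' made, totals and categories are reported both with and without the DNA
#' component.
#'
#' @param ldl_mmol corrected LDL-C, mmol/L (>= 0).
#' @param family_premature_cvd first-degree relative with premature
#'   coronary/vascular disease or LDL-C above the 95th percentile (1 point).
#' @param family_xanthoma_or_child_high_ldl first-degree relative with tendon
#'   xanthomata / arcus cornealis, or a child under 18 with high LDL-C
#'   (2 points; supersedes the 1-point family item).
#' @param premature_cad personal premature coronary artery disease (2 points).
#' @param premature_cerebral_peripheral personal premature cerebral or
#'   peripheral vascular disease (1 point).
#' @param tendon_xanthoma tendon xanthomata (6 points).
#' @param arcus_cornealis_under_45 arcus cornealis before age 45 (4 points).
#' @param dna_causal_mutation molecular confirmation of a causal LDLR / APOB /
#'   PCSK9 variant (8 points).
#' @param point_table see [dlcn_point_table()].
#' @return list of class `fh_dlcns`: component points, `total`,
#'   `total_without_dna`, `category`, `category_without_dna`,
#'   `missing_components`.
#' @export
#' @examples
#' dlcns_score(ldl_mmol = 9.1, dna_causal_mutation = TRUE)$category
dlcns_score <- function(ldl_mmol,
                        family_premature_cvd = FALSE,
                        family_xanthoma_or_child_high_ldl = FALSE,
                        premature_cad = FALSE,
                        premature_cerebral_peripheral = FALSE,
                        tendon_xanthoma = FALSE,
                        arcus_cornealis_under_45 = FALSE,
                        dna_causal_mutation = FALSE,
                        point_table = dlcn_point_table()) {
  if (is.na(ldl_mmol)) {
    missing_ldl <- TRUE
    ldl_mmol <- 0
  } else {
    missing_ldl <- FALSE
    if (ldl_mmol < 0) abort("ldl_mmol must be non-negative")
  }
  flags <- list(
    family_premature_cvd = family_premature_cvd,
    family_xanthoma_or_child_high_ldl = family_xanthoma_or_child_high_ldl,
    premature_cad = premature_cad,
    premature_cerebral_peripheral = premature_cerebral_peripheral,
    tendon_xanthoma = tendon_xanthoma,
    arcus_cornealis_under_45 = arcus_cornealis_under_45,
    dna_causal_mutation = dna_causal_mutation
  )
  missing <- names(flags)[map_lgl(flags, is.na)]
  if (missing_ldl) missing <- c("ldl_mmol", missing)
  flags <- map(flags, isTRUE)

  pt <- point_table
  family <- max(0, if (flags$family_xanthoma_or_child_high_ldl)
    pt$family[["relative_xanthoma_arcus_or_child_high_ldl"]] else 0,
    if (flags$family_premature_cvd)
      pt$family[["relative_premature_cvd_or_high_ldl"]] else 0)
  clinical <- max(0, if (flags$premature_cad) pt$clinical[["premature_cad"]] else 0,
                  if (flags$premature_cerebral_peripheral)
                    pt$clinical[["premature_cerebral_peripheral"]] else 0)
  physical <- max(0, if (flags$tendon_xanthoma) pt$physical[["tendon_xanthoma"]] else 0,
                  if (flags$arcus_cornealis_under_45)
                    pt$physical[["arcus_cornealis_under_45"]] else 0)
  ldl <- .dlcn_ldl_points(ldl_mmol, pt$ldl_bands)
  dna <- if (flags$dna_causal_mutation) pt$dna[["causal_mutation"]] else 0

  total <- family + clinical + physical + ldl + dna
  total_wo <- total - dna
  structure(
    list(
      components = c(family = family, clinical = clinical, physical = physical,
                     ldl = ldl, dna = dna),
      total = total,
      total_without_dna = total_wo,
      category = .dlcn_category(total, pt$categories),
      category_without_dna = .dlcn_category(total_wo, pt$categories),
      missing_components = missing
    ),
    class = "fh_dlcns"
  )
}

#' @export
print.fh_dlcns <- function(x, ...) {
  cat("DLCNS:", x$total, "points (", x$category, "); without DNA criterion:",
      x$total_without_dna, "points (", x$category_without_dna, ")\n")
  invisible(x)
}

#' Screen undiagnosed carriers against the DLCN FH criteria
#'
#' Scores every carrier row and flags those meeting the clinical FH criteria
#' (DLCNS category probable or definite, i.e. total >= 6). The screen is run
#' on medical-record data, so rows with `records_available = FALSE` are left
#' out of the denominator.
#'
#' @param data tibble with one row per carrier: corrected `ldl_mmol`, the
#'   DLCN flag columns of [dlcns_score()] (absent columns default to `FALSE`),
#'   optionally `records_available` and `prior_fh_diagnosis`.
#' @param use_dna_component score with the genetic criterion included
#'   (default `FALSE`: the screen emulates a records-based clinical assessment
#'   made without the sequencing result).
#' @return tibble with `dlcns_total`, `dlcns_category` and `meets_fh_criteria`
#'   appended; screened-out rows carry `NA`.
#' @export
fh_criteria_screen <- function(data, use_dna_component = FALSE) {
  data <- as_tibble(data)
  flag_cols <- c("family_premature_cvd", "family_xanthoma_or_child_high_ldl",
                 "premature_cad", "premature_cerebral_peripheral",
                 "tendon_xanthoma", "arcus_cornealis_under_45")
  for (col in flag_cols) if (!col %in% names(data)) data[[col]] <- FALSE
  if (!"records_available" %in% names(data)) data$records_available <- TRUE
  dna <- if (use_dna_component) TRUE else FALSE
  res <- pmap(data[c("ldl_mmol", flag_cols, "records_available")], function(
    ldl_mmol, family_premature_cvd, family_xanthoma_or_child_high_ldl,
    premature_cad, premature_cerebral_peripheral, tendon_xanthoma,
    arcus_cornealis_under_45, records_available) {
    if (!isTRUE(records_available)) {
      return(list(total = NA_real_, category = NA_character_))
    }
    s <- dlcns_score(
      ldl_mmol = ldl_mmol,
      family_premature_cvd = family_premature_cvd,
      family_xanthoma_or_child_high_ldl = family_xanthoma_or_child_high_ldl,
      premature_cad = premature_cad,
      premature_cerebral_peripheral = premature_cerebral_peripheral,
      tendon_xanthoma = tendon_xanthoma,
      arcus_cornealis_under_45 = arcus_cornealis_under_45,
      dna_causal_mutation = dna
    )
    list(total = s$total, category = s$category)
  })
  data |>
    mutate(
      dlcns_total = map_dbl(res, "total"),
      dlcns_category = map_chr(res, "category"),
      meets_fh_criteria = .data$dlcns_category %in% c("probable", "definite")
    ) |>
    mutate(meets_fh_criteria = ifelse(is.na(.data$dlcns_total), NA,
                                      .data$meets_fh_criteria))
}
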
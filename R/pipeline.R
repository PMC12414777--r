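#' Read a variant annotation table from TSV
#'
#' @param path TSV file with the [validate_annotations()] column dictionary.
#' @return validated annotation tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_annotations(tab)
}

#' Read a participant phenotype table from CSV
#'
#' `icd10_primary` may hold several codes separated by `";"`; it is expanded
#' to a list-column.
#'
#' @param path CSV file.
#' @param required columns that must be present.
#' @return participant tibble.
#' @export
read_phenotypes <- function(path,
                            required = c("participant_id", "sex", "age")) {
  if (!file.exists(path)) abort(paste0("phenotype file not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("phenotype table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if ("icd10_primary" %in% names(tab) && is.character(tab$icd10_primary)) {
    tab$icd10_primary <- map(str_split(tab$icd10_primary %||% "", ";"),
                             ~ .x[nzchar(.x)])
  }
  tab
}

#' Read carrier genotypes from a VCF
#'
#' Parses a VCF (v4.2) with GT calls via Bioconductor's VariantAnnotation and
#' returns a long genotype table keyed by `chrom:pos:ref:alt`. Any
#' non-reference genotype makes the sample a carrier of that allele;
#' half-calls are handled downstream as missing.
#'
#' @param path VCF file.
#' @return tibble: `participant_id`, `variant_id`, `genotype`.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("reading VCFs requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  ids <- sprintf("%s:%d:%s:%s",
                 as.character(GenomeInfoDb::seqnames(rr)),
                 BiocGenerics::start(rr),
                 as.character(rr$REF),
                 vapply(rr$ALT, function(a) as.character(a)[1], character(1)))
  tibble(
    participant_id = rep(colnames(gt), each = nrow(gt)),
    variant_id = rep(ids, times = ncol(gt)),
    genotype = as.vector(gt)
  )
}

#' Write a minimal GT-only VCF v4.2 for a genotype table
#'
#' Variant ids must be `chrom:pos:ref:alt`. Participants without a row for a
#' variant are written as `0/0`.
#'
#' @param genotypes tibble with `participant_id`, `variant_id`, `genotype`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_minimal_vcf <- function(genotypes, path) {
  parts <- str_match(genotypes$variant_id, "^([^:]+):(\\d+):([A-Za-z]+):([A-Za-z]+)$")
  if (any(is.na(parts[, 1]))) {
    abort("variant ids must be chrom:pos:ref:alt to write a VCF")
  }
  samples <- sort(unique(genotypes$participant_id))
  variants <- genotypes |>
    distinct(.data$variant_id) |>
    mutate(chrom = parts[match(variant_id, genotypes$variant_id), 2],
           pos = as.integer(parts[match(variant_id, genotypes$variant_id), 3]),
           ref = parts[match(variant_id, genotypes$variant_id), 4],
           alt = parts[match(variant_id, genotypes$variant_id), 5]) |>
    arrange(.data$chrom, .data$pos)
  gt_wide <- matrix("0/0", nrow(variants), length(samples),
                    dimnames = list(variants$variant_id, samples))
  gt_wide[cbind(match(genotypes$variant_id, variants$variant_id),
                match(genotypes$participant_id, samples))] <-
    as.character(genotypes$genotype)
  header <- c(
    "##fileformat=VCFv4.2",
    "##reference=GRCh38",
    sprintf("##contig=<ID=%s>", unique(variants$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i], variants$variant_id[i],
            variants$ref[i], variants$alt[i], ".", "PASS", ".", "GT",
            gt_wide[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Run the full carrier analysis pipeline
#'
#' Orchestrates variant triage, carrier assignment, exclusion rules,
#' penetrance, the DLCN FH-criteria screen, and carrier association models
#' into one reproducible report. Stage counts are conserved (every variant
#' and carrier is either retained or carries an exclusion reason).
#'
#' @param annotations annotation table (or path to a TSV).
#' @param genotypes genotype table (`participant_id`, `variant_id`,
#'   `genotype`).
#' @param participants phenotype table (or path to a CSV).
#' @param config [triage_config()].
#' @param cascade_ids,q4494del_variant_ids see [apply_exclusions()].
#' @param thresholds,correction_table see [penetrance()].
#' @param out_dir if non-NULL, stage outputs are written there as TSV plus a
#'   JSON report.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return object of class `fh_report`: stage counts, classified variants,
#'   carrier set, penetrance table, FH-diagnosis summary, association tables,
#'   and a provenance manifest (config hash, seed, package version).
#' @export
run_fh_pipeline <- function(annotations, genotypes, participants,
                            config = triage_config(),
                            cascade_ids = character(),
                            q4494del_variant_ids = character(),
                            thresholds = c(LDLR = 4.0, APOB = 4.9),
                            correction_table = ldl_correction_table(),
                            out_dir = NULL,
                            seed = 1L) {
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  if (is.character(participants)) participants <- read_phenotypes(participants)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  triage <- stage("triage", classify_variants(annotations, config))
  carriers <- stage("carrier assignment",
                    assign_carriers(genotypes, triage$classified))
  carriers <- stage("exclusions",
                    apply_exclusions(carriers, cascade_ids,
                                     q4494del_variant_ids))
  pen <- stage("penetrance",
               penetrance(carriers, participants, thresholds, correction_table))

  eligible <- carriers |> filter(.data$analysis_eligible)
  n_all <- nrow(participants)

  # FH-diagnosis screen on PV/LP carriers (LDLR PV/LP + APOB), corrected LDL
  screen_ids <- eligible$participant_id[eligible$subgroup %in% c("LDLR_PVLP", "APOB")]
  screen_dat <- participants |>
    filter(.data$participant_id %in% screen_ids) |>
    mutate(ldl_mmol = correct_pretreatment_ldl(.data$max_ldl_observed,
                                               .data$therapy, correction_table))
  screen <- stage("fh screen", fh_criteria_screen(screen_dat))
  n_records <- sum(!is.na(screen$dlcns_total))
  prior_flags <- if ("prior_fh_diagnosis" %in% names(participants)) {
    participants$participant_id[participants$prior_fh_diagnosis]
  } else character()
  fh_summary <- tibble(
    n_pvlp_carriers = length(screen_ids),
    n_with_records = n_records,
    n_prior_fh = sum(screen$participant_id %in% prior_flags),
    n_meets_criteria = sum(screen$meets_fh_criteria, na.rm = TRUE),
    prior_fh_frac_all = sum(eligible$participant_id %in% prior_flags) /
      max(1, nrow(eligible)),
    prior_fh_frac_records = n_prior_fh / max(1, n_records),
    meets_criteria_frac_records = n_meets_criteria / max(1, n_records)
  )

  assoc_dat <- participants |>
    filter(!.data$participant_id %in%
             carriers$participant_id[!carriers$analysis_eligible]) |>
    mutate(carrier = .data$participant_id %in% eligible$participant_id)
  run_model <- function(covs) {
    tryCatch(
      suppressMessages(fit_logistic_or(assoc_dat, "ihd", "carrier", covs)),
      error = function(e) {
        warn(paste0("IHD model skipped: ", conditionMessage(e)))
        NULL
      })
  }
  ihd_model1 <- if ("ihd" %in% names(assoc_dat)) run_model(c("sex", "age")) else NULL
  ihd_model2 <- if ("ihd" %in% names(assoc_dat))
    run_model(c("sex", "age", "bmi", "diabetes", "smoking")) else NULL
  lipid_table <- tryCatch(
    suppressMessages(suppressWarnings(lipid_or_models(participants, carriers))),
    error = function(e) {
      warn(paste0("lipid models skipped: ", conditionMessage(e)))
      NULL
    })
  summary_tab <- tryCatch(
    suppressMessages(group_summary(assoc_dat)),
    error = function(e) {
      warn(paste0("group summary skipped: ", conditionMessage(e)))
      NULL
    })

  counts <- list(
    variants_in = nrow(annotations),
    variants_candidates = sum(is.na(triage$classified$exclusion_reason)),
    variants_excluded = sum(!is.na(triage$classified$exclusion_reason)),
    variants_by_class = table(triage$classified$final_class),
    carriers_found = nrow(carriers),
    carriers_excluded = sum(!carriers$analysis_eligible),
    carriers_eligible = nrow(eligible),
    exclusion_reasons = table(carriers$exclusion_reason),
    carrier_prevalence = nrow(carriers) / n_all,
    n_participants = n_all
  )
  manifest <- list(
    config_hash = hash(list(config = unclass(config), thresholds = thresholds,
                            correction_table = correction_table,
                            cascade_ids = cascade_ids,
                            q4494del_variant_ids = q4494del_variant_ids)),
    seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("fhtriage")),
    timestamp = NA_character_  # kept NA so identical runs hash identically
  )
  report <- structure(
    list(counts = counts, classified = triage$classified,
         triage_summary = triage$summary, carriers = carriers,
         penetrance = pen, fh_summary = fh_summary,
         ihd_model1 = ihd_model1, ihd_model2 = ihd_model2,
         lipid_table = lipid_table, group_summary = summary_tab,
         manifest = manifest),
    class = "fh_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.fh_report <- function(x, ...) {
  c_ <- x$counts
  cat("FH carrier analysis report\n")
  cat(sprintf("  participants: %d; carriers found: %d (prevalence %.2f%%)\n",
              c_$n_participants, c_$carriers_found,
              100 * c_$carrier_prevalence))
  cat(sprintf("  variants: %d in, %d candidates, %d excluded\n",
              c_$variants_in, c_$variants_candidates, c_$variants_excluded))
  cat(sprintf("  carriers: %d eligible after %d exclusions\n",
              c_$carriers_eligible, c_$carriers_excluded))
  if (!is.null(x$ihd_model1)) {
    r <- x$ihd_model1$result
    cat(sprintf("  IHD OR (sex/age-adjusted): %.2f [%.2f; %.2f], p = %.3g\n",
                r$estimate, r$ci_low, r$ci_high, r$p_value))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' @param report an `fh_report`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(report$classified, p("classified_variants.tsv"))
  readr::write_tsv(report$carriers |>
                     mutate(across(where(is.list),
                                   ~ map_chr(.x, paste, collapse = ";"))),
                   p("carriers.tsv"))
  readr::write_tsv(as_tibble(report$penetrance), p("penetrance.tsv"))
  if (!is.null(report$lipid_table)) {
    readr::write_tsv(report$lipid_table, p("lipid_odds_ratios.tsv"))
  }
  if (!is.null(report$group_summary)) {
    readr::write_tsv(report$group_summary, p("group_summary.tsv"))
  }
  json <- list(
    counts = report$counts[c("variants_in", "variants_candidates",
                             "variants_excluded", "carriers_found",
                             "carriers_excluded", "carriers_eligible",
                             "carrier_prevalence", "n_participants")],
    fh_summary = report$fh_summary,
    ihd_model1 = if (!is.null(report$ihd_model1)) report$ihd_model1$result,
    ihd_model2 = if (!is.null(report$ihd_model2)) report$ihd_model2$result,
    manifest = report$manifest
  )
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out_dir)
}
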
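# build the (deterministic) study fixture once per test run
study_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- fh_study_fixture()
    fx
  }
})

# classified variants + excluded carrier set for the study fixture
study_carriers <- local({
  cs <- NULL
  function() {
    if (is.null(cs)) {
      fx <- study_fixture()
      cl <- classify_variants(fx$annotations)
      cs <<- apply_exclusions(assign_carriers(fx$genotypes, cl$classified),
                              fx$cascade_ids, fx$q4494del_variant_ids)
    }
    cs
  }
})

# one-row annotation builder with sensible candidate defaults
make_annotation <- function(...) {
  defaults <- list(
    variant_id = "chr19:11100001:C:T", gene = "LDLR", region = "exonic",
    variant_type = "SNV", consequence = "missense", gnomad_maf = NA_real_,
    clinvar_class = "VUS", clinvar_review = "single_submitter",
    intervar_class = "VUS", sift = NA_real_, polyphen2_hdiv = NA_real_,
    mutation_assessor = NA_real_, m_cap = NA_real_, cadd = NA_real_,
    revel = NA_real_, metalr = NA_real_, metasvm = NA_real_,
    clinical_case_support = FALSE
  )
  args <- list(...)
  defaults[names(args)] <- args
  tibble::as_tibble(defaults)
}
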
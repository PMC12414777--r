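---
title: "Carrier analysis for familial hypercholesterolemia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carrier analysis for familial hypercholesterolemia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(fhtriage)
library(dplyr)
```

`fhtriage` turns two tabular inputs — a per-variant annotation table and a
per-participant phenotype table — into the three quantities an FH screening
study reports: carrier prevalence, variant penetrance, and carrier disease
risk. This vignette is the package's own account of the models and the design
choices behind them; every number shown here is computed by the code on the
page.

## 1. Variant triage

### The decision procedure

Candidate variants are restricted to *LDLR*, *APOB* and *PCSK9*; exonic or
splice-site; SNV or indel; gnomAD minor allele frequency strictly below
0.01% **or absent from gnomAD** (absence from a population reference is not
evidence of commonness); and not asserted benign/likely benign in ClinVar.
Exclusions record the first failing rule in the fixed order
gene → region → type → MAF → benign, so audit counts are stable.

Candidates then pass through a decision tree whose branches (A–F, recorded
per variant) integrate four evidence sources:

| branch | condition | outcome |
|---|---|---|
| A | ClinVar P/LP, expert-panel or multiple-submitter review, InterVar P/LP | ClinVar class stands |
| B | ClinVar P/LP but InterVar VUS | review path |
| C | ClinVar P with single-submitter / criteria-not-provided review | Pathogenic only with clinical-case support **and** InterVar or consensus support; else review path |
| D | ClinVar LP with weak review | review path |
| E | ClinVar VUS / unreported: InterVar P/LP with expert-panel review stands, otherwise review path; InterVar VUS falls through | kept / review / F |
| F | rare *LDLR* missense (MAF < 0.0005 or absent), MetaLR and MetaSVM deleterious | VUS predicted to be deleterious |

The *review path* upgrades to Likely Pathogenic when the in-silico consensus
supports it (≥ 3 of SIFT < 0.05, PolyPhen-2 HDIV ≥ 0.95, MutationAssessor ≥ 2,
M-CAP > 0.025, CADD ≥ 15) or clinical-case evidence exists; when fewer than
three scores are available at all, a REVEL > 0.75 & MetaLR > 0.5 tie-break is
consulted; otherwise the variant stays a VUS.

### Choices the sources left open

* **MetaLR/MetaSVM cutoffs for branch F.** The rare-missense rule names the
  tools but no cutoffs; we use their published deleterious thresholds
  (MetaLR > 0.5, MetaSVM score > 0) and expose both in `triage_config()`.
* **"Below 0.01%" is strict** (`maf < 1e-4`), likewise "below 0.0005" — a
  literal reading, configurable.
* **Conflicting ClinVar assertions** enter the ClinVar-VUS arm (branch E)
  with a manual-review note rather than being dropped: conservative and
  auditable.
* **Coexisting P and LP assertions** are assumed collapsed upstream to the
  most severe non-conflicting class (`clinvar_multi_pick`); the engine takes
  a single class per variant.
* **Branch C's "clinical test results and ACMG assessment"** is
  operationalized as the boolean `clinical_case_support` input plus
  InterVar/consensus support: the engine stays a pure function of its
  annotation row (InterVar's 18 ACMG criteria are consumed, not re-run).
* **Overlapping branch conditions** (e.g. ClinVar P, single submitter,
  InterVar VUS matches both B and C) are resolved by first match in order
  A–F; the outcomes agree, only the audit label differs.
* **Splice sites** are whatever the upstream annotation labelled
  `splice_site` (canonically ±2 bp); the engine does not recompute them
  from coordinates.

Two properties are enforced by tests: every candidate fires exactly one
branch, and strengthening evidence (adding a passing score or clinical
support) never demotes a variant.

## 2. Carriers, exclusions, penetrance

Any non-reference genotype for a Pathogenic / Likely Pathogenic /
VUS-deleterious variant makes a carrier. Three exclusion rules, applied in
precedence order, define the association population: carriers of two
variants (possible homozygous/compound FH), cascade-screened proband
relatives (ascertainment bias; supplied as external flags), and carriers of
*APOB* p.Gln4494del (whose carriers show no FH phenotype). The published
totals (86 carriers, 76 analysed) leave one count ambiguous — the listed
exclusions sum to 9 — so the study fixture treats the cascade relatives as
2; that is an assumption documented in the fixture manifest, not a printed
fact.

Penetrance is the fraction of carriers whose **maximum** recorded LDL-C,
after back-correction for lipid-lowering therapy, reaches the
gene-appropriate threshold: ≥ 4.0 mmol/L (*LDLR*) or ≥ 4.9 mmol/L (*APOB*).
Back-correction multiplies the observed value by a therapy-class factor
`1 / (1 − fractional LDL reduction)`; the cited drug/dose-specific factor
table is not reprinted in our sources, so the package ships a stand-in table
built from the canonical average percent reductions by intensity class
(e.g. high-intensity statin ≈ 50% → factor 2.0). It is pure configuration —
`correct_pretreatment_ldl()` accepts any two-column replacement — and all
tests assert against the shipped table's own values, never against
unverifiable published numbers. An unknown therapy label is an error, not a
silent identity. Because correction is multiplicative, thresholding a
corrected value is identical to pre-scaling the threshold for a uniform
therapy group; a test asserts this algebraic identity.

```{r}
pen <- penetrance(
  apply_exclusions(
    assign_carriers(fh_study_fixture()$genotypes,
                    classify_variants(fh_study_fixture()$annotations)$classified),
    cascade_ids = c("X05", "X06"),
    q4494del_variant_ids = "chr2:21001429:TCTG:T"),
  fh_study_fixture()$participants)
as.data.frame(pen)[, c("group", "n", "pen_4_0", "pen_4_9", "penetrance")]
```

### DLCN scoring

`dlcns_score()` implements the standard Dutch Lipid Clinic Network point
table (within-group maxima: family 2/1, clinical 2/1, physical 6/4, LDL-C
bands 8/5/3/1 at 8.5/6.5/5.0/4.0 mmol/L, DNA 8; categories unlikely < 3,
possible 3–5, probable 6–8, definite > 8). Whether a records-based
diagnosis was made with or without the genetic criterion is ambiguous in
practice, so totals and categories are always reported both with and
without the DNA component, and the `fh_criteria_screen()` default scores
**without** it (emulating a clinical assessment made before sequencing).
"Meets FH criteria" means probable or definite (total ≥ 6). Missing inputs
score zero and are listed, never silently imputed.

## 3. Association statistics

* `fisher_2x2()` computes the exact two-sided p as the sum of hypergeometric
  probabilities no greater than the observed table's, and reports the sample
  cross-product OR (`ad/bc`) with a Haldane–Anscombe companion when a zero
  cell makes it 0/∞. Tests verify it exhaustively against a `choose()`-based
  enumeration oracle for all tables with N ≤ 16 and against
  `stats::fisher.test` on sampled tables to N = 60.
* `mann_whitney()` uses exact enumeration of all group assignments when both
  groups have ≤ 8 observations (ties handled naturally) and a tie-corrected
  normal approximation otherwise, without continuity correction. The
  two-sided p is the symmetric-distance probability
  `P(|U − n₁n₂/2| ≥ |u − n₁n₂/2|)`, which equals the usual doubled tail for
  a tie-free null.
* `fit_logistic_or()` is a maximum-likelihood logistic fit reporting
  `exp(β̂)` with **Wald** 95% CI and two-sided Wald p (matching the
  CI format of standard GLM output; profile-likelihood intervals were the
  alternative and are deliberately not used). Perfect separation is detected
  on binary predictors before fitting and raised as an error naming the
  predictor; quasi-separation is caught by a coefficient cap of 15 on the
  logit scale; non-convergence after 100 IRLS iterations errors. Analysis is
  complete-case with a logged drop count.
* The two IHD models use exactly the covariate sets sex + age (model 1) and
  sex + age + BMI + diabetes + smoking (model 2). Lipid models regress
  carrier status on each **standardized** lipid (the published per-unit
  scale is unstated, so odds ratios are per SD — a documented, configurable
  assumption) adjusted for age, sex and lipid-lowering therapy of any class.
  Carrier groups smaller than 5 are skipped with a warning.
* Raw p-values are reported with no multiplicity correction, matching the
  source analysis; significance flags use strict `p < 0.05`.
* `group_summary()` mixes Fisher rows (categorical) and Mann–Whitney rows
  (continuous); because the published table's per-row adjustment method is
  not fully specified, both an unadjusted and a sex/age-adjusted logistic p
  are emitted per row (for age itself, sex-only adjusted).

## 4. The synthetic world

`simulate_cohort()` draws the cohort the analysis assumes, with defaults
fixed once to the stated study conditions: 4,856 participants, 43% women,
carrier prevalence 86/4856, ages truncated-normal on [18, 100] with mean 65
and SD 12.5 (the source reports only medians/IQRs; a truncated normal
matches those summaries without claiming the true distribution), lipid
means/SDs per carrier status from the group summaries (medians treated as
means, SD = IQR/1.349), and 64.5% on lipid-lowering therapy. IHD is
generated from a logistic model — carrier log-odds `ln(1.31)` plus male sex
`ln(1.5)` and `ln(1.3)` per SD of age, baseline −0.1 chosen so the
non-carrier IHD prevalence is near the observed 53% — because the fitted
analysis model must be a correctly specified model of its own generator for
parameter recovery to be well-defined. Treated participants' observed LDL-C
is deflated by the same correction factors the phenotype module ships, so
back-correction is exactly invertible in tests.

What the generator does **not** emulate: linkage structure, realistic
allele-frequency spectra, longitudinal lipid trajectories, correlated
comorbidities, or medians/IQRs exactly (only approximately, via the normal
parameterization). A green recovery test therefore establishes that the
estimation machinery is unbiased under its own assumptions — not that those
assumptions hold in any real cohort.

`simulate_annotations()` generates annotation rows stratified by triage
branch, each tagged with the class the engine must output; the default mix
is uniform over strata so every branch carries mass, and the engine is
required to agree with the generator on 100% of rows.

`fh_study_fixture()` is different in kind: a **deterministic**
reconstruction whose marginal counts and quartiles equal the published
tables exactly (type-7 quantile pins; counts placed as fixed blocks).
Individual-level pairings of traits are conventions, so model outputs on the
fixture (e.g. its IHD odds ratio) reflect the block structure and are not
calibrated quantities; the fixture's job is to reproduce counts, fractions
and medians. Two reconciliations of ambiguous published totals — cascade
relatives counted as 2, and one APOB PV/LP carrier's records marked
unavailable so the FH-diagnosis screen has 51 records (making 8/51 = 15.7%
and 12/51 = 23.5% alongside Table-level 8/76 = 10.5%) — are labelled as
assumptions in the fixture manifest.

## 5. Numerical details and degenerate inputs

* Probability comparisons in the Fisher p sum use a `1 + 1e-7` relative
  tolerance to absorb floating-point noise between equal-probability tables.
* A 2×2 table with an empty margin, an empty Mann–Whitney group, a
  constant predictor, an all-one-class outcome, or a carrier-free cohort
  each raise explicit errors (or, in grouped drivers, skip with a warning)
  rather than returning numbers.
* Half-call VCF genotypes (`./1`) are treated as missing with a warning;
  `./.` is missing without one.
* The pipeline is deterministic given its inputs; `run_fh_pipeline()`
  records a configuration hash and seed in its manifest, and reruns are
  byte-identical.
* Identical simulator seeds give byte-identical outputs; all randomness
  flows through the single `seed` parameter of each params object.

## 6. Known limitations

* InterVar's ACMG criteria, ClinVar queries and gnomAD lookups are inputs,
  not computations; the engine is only as good as its annotation table.
* The correction-factor table is an intensity-class stand-in for the cited
  drug/dose-specific table; users reproducing a specific clinical workflow
  should supply the published factors.
* Wald intervals undercover at very small case counts; with 15-carrier
  subgroups the lipid-model CIs are approximate.
* The DLCN screen uses whatever family-history and physical-sign columns
  exist; on data without them (like the shipped fixture's non-flagged rows)
  it reduces to the LDL band, which understates scores for patients whose
  signs were simply unrecorded.
* Homozygous-FH grading, pediatric criteria and survival analysis are out
  of scope.
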
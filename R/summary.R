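# ICD-10 circulatory-chapter buckets used in the cohort characteristics table
.icd_buckets <- data.frame(
  bucket = c("I10-I15 hypertensive", "I20-I25 ischemic heart",
             "I26-I28 pulmonary", "I30-I32 pericarditis",
             "I33-I39 endocarditis/valve", "I40-I43 myocarditis/cardiomyopathy",
             "I44-I49 arrhythmia/conduction", "I50 heart failure"),
  lo = c(10, 20, 26, 30, 33, 40, 44, 50),
  hi = c(15, 25, 28, 32, 39, 43, 49, 50)
)

#' Bucket ICD-10 codes into the circulatory-chapter ranges
#'
#' @param codes character vector of ICD-10 codes (e.g. `"I21.4"`).
#' @return character vector of bucket labels; codes outside the defined
#'   ranges (including non-I codes) map to `"other"`.
#' @export
icd10_bucket <- function(codes) {
  num <- suppressWarnings(as.numeric(str_match(codes, "^I(\\d+)")[, 2]))
  out <- rep("other", length(codes))
  for (i in seq_len(nrow(.icd_buckets))) {
    hit <- !is.na(num) & num >= .icd_buckets$lo[i] & num <= .icd_buckets$hi[i]
    out[hit] <- .icd_buckets$bucket[i]
  }
  out
}

# does any code in the list fall in bucket b?
.has_bucket <- function(code_list, b) {
  map_lgl(code_list, ~ any(icd10_bucket(as.character(.x)) == b))
}

.fmt_np <- function(k, n) sprintf("%d (%.2f%%)", k, 100 * k / n)
.fmt_med <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.3g [%.3g; %.3g]", q[2], q[1], q[3])
}

.adjusted_p_categorical <- function(data, flag_col, adjust) {
  tryCatch(
    suppressMessages(
      fit_logistic_or(data, outcome = flag_col, exposure = "carrier",
                      covariates = adjust)$result$p_value),
    error = function(e) NA_real_
  )
}

#' Carrier versus non-carrier cohort characteristics
#'
#' Builds a characteristics table in the layout of the study's cohort table:
#' categorical rows as N (%) per group with a Fisher exact p-value (and a
#' sex/age-adjusted logistic p-value when `adjust` is non-empty), continuous
#' rows as median \[Q1; Q3\] with a Mann-Whitney p-value (and an adjusted
#' logistic p of the standardized trait, sex-only adjusted for age itself).
#' Principal diagnoses are bucketed into the ICD-10 circulatory ranges.
#' Rows are emitted only for columns present in `participants`.
#'
#' @param participants participant table including a logical `carrier` column
#'   (analysis-eligible carriers versus non-carriers; drop excluded carriers
#'   beforehand).
#' @param adjust covariates for the adjusted p-value (default sex and age;
#'   empty vector disables adjustment).
#' @return tibble of class `fh_group_summary`: `parameter`, formatted
#'   `carriers` / `non_carriers`, raw counts or medians, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
group_summary <- function(participants, adjust = c("sex", "age")) {
  stopifnot("carrier" %in% names(participants))
  dat <- as_tibble(participants)
  if (all(dat$carrier) || !any(dat$carrier)) {
    warn("one comparison group is empty; p-values are undefined")
  }
  n1 <- sum(dat$carrier)
  n0 <- sum(!dat$carrier)
  rows <- list()

  add_categorical <- function(label, flag) {
    ok <- !is.na(flag)
    a <- sum(flag & dat$carrier, na.rm = TRUE)
    c_ <- sum(flag & !dat$carrier, na.rm = TRUE)
    p_un <- tryCatch(
      fisher_2x2(a, sum(ok & dat$carrier) - a,
                 c_, sum(ok & !dat$carrier) - c_)$p_two_sided,
      error = function(e) NA_real_)
    p_adj <- if (length(adjust) > 0 && n1 > 0 && n0 > 0) {
      d2 <- dat[ok, ]
      d2$..flag <- as.integer(flag[ok])
      .adjusted_p_categorical(d2, "..flag", adjust)
    } else NA_real_
    rows[[label]] <<- tibble(
      parameter = label, type = "categorical",
      carriers = .fmt_np(a, n1), non_carriers = .fmt_np(c_, n0),
      n_carriers = a, n_non_carriers = c_,
      p_unadjusted = p_un, p_adjusted = p_adj
    )
  }
  add_continuous <- function(label, col, adjust_row = adjust) {
    x <- dat[[col]][dat$carrier]
    y <- dat[[col]][!dat$carrier]
    p_un <- tryCatch(mann_whitney(x, y)$p_two_sided, error = function(e) NA_real_)
    p_adj <- if (length(adjust_row) > 0) {
      tryCatch(
        suppressMessages(
          fit_logistic_or(dat |> filter(!is.na(.data[[col]])),
                          outcome = "carrier", exposure = col,
                          covariates = adjust_row,
                          standardize = col)$result$p_value),
        error = function(e) NA_real_)
    } else NA_real_
    rows[[label]] <<- tibble(
      parameter = label, type = "continuous",
      carriers = .fmt_med(x), non_carriers = .fmt_med(y),
      n_carriers = NA_integer_, n_non_carriers = NA_integer_,
      p_unadjusted = p_un, p_adjusted = p_adj
    )
  }

  if ("sex" %in% names(dat)) {
    add_categorical("Men", dat$sex == "male")
    add_categorical("Women", dat$sex == "female")
  }
  if ("age" %in% names(dat)) {
    add_continuous("Age", "age", adjust_row = setdiff(adjust, "age"))
  }
  if ("bmi_category" %in% names(dat)) {
    for (lev in c("underweight", "healthy", "overweight",
                  "obesity_1", "obesity_2", "obesity_3")) {
      add_categorical(paste0("BMI: ", lev), dat$bmi_category == lev)
    }
  }
  if ("smoking" %in% names(dat)) {
    add_categorical("Nicotine dependence", dat$smoking == "dependent")
  }
  if ("alcohol_audit_c" %in% names(dat)) {
    add_categorical("Alcohol: never (AUDIT-C 0)", dat$alcohol_audit_c == 0)
  }
  if ("icd10_primary" %in% names(dat)) {
    for (b in c(.icd_buckets$bucket, "other")) {
      flag <- if (b == "other") {
        map_lgl(dat$icd10_primary,
                ~ length(.x) > 0 && all(icd10_bucket(as.character(.x)) == "other"))
      } else {
        .has_bucket(dat$icd10_primary, b)
      }
      add_categorical(paste0("Principal diagnosis: ", b), flag)
    }
  }
  if ("dyslipidemia" %in% names(dat)) {
    add_categorical("Dyslipidemia/hyperlipidemia", dat$dyslipidemia)
  }
  if ("diabetes" %in% names(dat)) {
    add_categorical("Diabetes mellitus", dat$diabetes)
  }
  lipid_labels <- c(tc = "Cholesterol", ldl = "LDL", hdl = "HDL",
                    glucose = "Glucose", tg = "Triglycerides")
  for (col in names(lipid_labels)) {
    if (col %in% names(dat)) add_continuous(lipid_labels[[col]], col)
  }
  med_labels <- c(antiplatelet = "Antiplatelet drug",
                  anticoagulant = "Oral anticoagulants",
                  beta_blocker = "Beta blockers",
                  on_lipid_lowering = "Statins and other lipid-lowering drugs",
                  antihypertensive = "Antihypertensive drugs")
  for (col in names(med_labels)) {
    if (col %in% names(dat)) add_categorical(med_labels[[col]], dat[[col]])
  }

  out <- list_rbind(unname(rows))
  class(out) <- unique(c("fh_group_summary", class(out)))
  out
}
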
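#' Covariate-adjusted odds ratio by logistic regression
#'
#' Maximum-likelihood logistic fit of a binary outcome on an exposure plus
#' covariates; the association is reported as the exponentiated exposure
#' coefficient with a Wald 95% confidence interval and two-sided Wald p-value.
#' Perfect separation on any binary predictor is detected and raised as an
#' error naming the predictor, as is non-convergence.
#'
#' The study's two IHD models are `covariates = c("sex", "age")` (model 1) and
#' additionally BMI, diabetes and smoking status (model 2).
#'
#' @param data data frame holding all model columns.
#' @param outcome name of the binary outcome column (logical or 0/1).
#' @param exposure name of the exposure column.
#' @param covariates character vector of covariate column names (must not
#'   repeat the exposure).
#' @param standardize character vector of continuous columns to z-score
#'   before fitting (applied to exposure and/or covariates).
#' @param conf_level confidence level for the Wald interval.
#' @param max_iter IRLS iteration cap.
#' @return object of class `fh_logistic`: the glm fit plus a one-row `result`
#'   tibble (`outcome`, `exposure`, `model`, `estimate` (OR), `ci_low`,
#'   `ci_high`, `p_value`, `n_cases`, `n_total`). Complete cases only; the
#'   number dropped is messaged.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_sim_params(n_participants = 2000, seed = 42))
#' fit <- fit_logistic_or(sim$participants, "ihd", "carrier", c("sex", "age"))
#' fit$result
fit_logistic_or <- function(data, outcome, exposure,
                            covariates = character(),
                            standardize = character(),
                            conf_level = 0.95,
                            max_iter = 100) {
  if (exposure %in% covariates) {
    abort("exposure must not be duplicated among covariates")
  }
  cols <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing model column(s): ", paste(missing_cols, collapse = ", ")))
  }
  dat <- as_tibble(data)[cols]
  cc <- complete.cases(dat)
  if (any(!cc)) {
    inform(paste0(sum(!cc), " row(s) dropped from model (missing values)"))
    dat <- dat[cc, ]
  }
  y <- dat[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) abort("outcome must be binary (logical or 0/1)")
  if (length(unique(y)) < 2) abort("degenerate outcome: only one class present")
  dat[[outcome]] <- y
  for (col in standardize) {
    v <- dat[[col]]
    if (sd(v) == 0) abort(paste0("cannot standardize constant column ", col))
    dat[[col]] <- (v - mean(v)) / sd(v)
  }
  # screen binary predictors for perfect separation before fitting
  for (col in c(exposure, covariates)) {
    v <- dat[[col]]
    if (length(unique(v)) < 2) {
      abort(paste0("predictor '", col, "' is constant in the analysis data"))
    }
    if (is.logical(v) || is.character(v) || is.factor(v) ||
        all(v %in% c(0, 1))) {
      tab <- table(factor(y, levels = c(0, 1)), v)
      if (ncol(tab) > 1 && any(rowSums(tab > 0) == 1) && all(colSums(tab) > 0)) {
        abort(paste0("perfect separation detected on predictor '", col, "'"))
      }
    }
  }
  fml <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- glm(fml, data = dat, family = binomial(),
             control = list(maxit = max_iter))
  if (!fit$converged) {
    abort(paste0("logistic fit did not converge within ", max_iter, " iterations"))
  }
  if (max(abs(coef(fit)), na.rm = TRUE) > 15) {
    abort("quasi-separation: a coefficient exceeded 15 on the logit scale")
  }
  cf <- summary(fit)$coefficients
  # the exposure term is the first non-intercept coefficient; factor/logical
  # exposures expand to a single contrast named with a level suffix
  term <- grep(paste0("^", exposure), rownames(cf), value = TRUE)[1]
  if (is.na(term)) abort(paste0("exposure term '", exposure, "' not in fit"))
  est <- cf[term, "Estimate"]
  se <- cf[term, "Std. Error"]
  zq <- qnorm(1 - (1 - conf_level) / 2)
  result <- tibble(
    outcome = outcome,
    exposure = exposure,
    model = paste0(outcome, " ~ ", exposure,
                   if (length(covariates) > 0)
                     paste0(" + ", paste(covariates, collapse = " + ")) else ""),
    estimate = exp(est),
    ci_low = exp(est - zq * se),
    ci_high = exp(est + zq * se),
    p_value = 2 * pnorm(-abs(est / se)),
    n_cases = sum(y == 1),
    n_total = length(y)
  )
  structure(list(fit = fit, result = result, exposure_term = term),
            class = "fh_logistic")
}

#' @export
print.fh_logistic <- function(x, ...) {
  r <- x$result
  cat(sprintf("%s\n  OR = %.3f [%.3f; %.3f], p = %.3g (n = %d, cases = %d)\n",
              r$model, r$estimate, r$ci_low, r$ci_high, r$p_value,
              r$n_total, r$n_cases))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a logistic association fit
#'
#' One row per model term, on the odds-ratio scale, broom style.
#'
#' @param x an `fh_logistic` object.
#' @param ... unused.
#' @return tibble: `term`, `estimate` (OR), `std.error` (logit scale),
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy fh_logistic
#' @export
tidy.fh_logistic <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  zq <- qnorm(0.975)
  tibble(
    term = rownames(cf),
    estimate = exp(cf[, "Estimate"]),
    std.error = cf[, "Std. Error"],
    statistic = cf[, "z value"],
    p.value = cf[, "Pr(>|z|)"],
    conf.low = exp(cf[, "Estimate"] - zq * cf[, "Std. Error"]),
    conf.high = exp(cf[, "Estimate"] + zq * cf[, "Std. Error"])
  )
}

#' Glance at a logistic association fit
#'
#' @param x an `fh_logistic` object.
#' @param ... unused.
#' @return one-row tibble of fit-level statistics.
#' @method glance fh_logistic
#' @export
glance.fh_logistic <- function(x, ...) {
  f <- x$fit
  tibble(
    null.deviance = f$null.deviance,
    df.null = f$df.null,
    deviance = f$deviance,
    df.residual = f$df.residual,
    AIC = stats::AIC(f),
    nobs = length(f$y),
    converged = f$converged
  )
}

#' Lipid odds-ratio models per carrier group
#'
#' For each carrier subgroup (all carriers, LDLR, LDLR PV/LP, LDLR
#' VUS-deleterious, APOB) and each lipid, fits a logistic model of carrier
#' status (subgroup members versus all non-carriers) on the standardized
#' lipid, adjusted for age, sex and lipid-lowering therapy of any class, and
#' reports the lipid odds ratio per standard deviation. Groups smaller than
#' `min_group` are skipped with a warning.
#'
#' @param participants participant table (needs the lipid columns plus `age`,
#'   `sex`, `on_lipid_lowering`).
#' @param carrier_set analysis carrier set from [apply_exclusions()].
#' @param lipids named character vector, display label -> column name.
#' @param covariates adjustment set.
#' @param min_group minimum carriers per group (default 5).
#' @return tibble of class `fh_assoc_table`: one row per group x lipid with
#'   OR, CI, p-value and sizes.
#' @export
lipid_or_models <- function(participants, carrier_set,
                            lipids = c(total_cholesterol = "tc", hdl = "hdl",
                                       ldl = "ldl", triglycerides = "tg"),
                            covariates = c("age", "sex", "on_lipid_lowering"),
                            min_group = 5) {
  eligible <- carrier_set |> filter(.data$analysis_eligible)
  non_carrier_ids <- setdiff(participants$participant_id,
                             carrier_set$participant_id)
  rows <- list()
  for (g in .penetrance_groups) {
    members <- eligible$participant_id[.subgroup_members(eligible, g)]
    if (length(members) < min_group) {
      warn(paste0("carrier group '", g, "' has fewer than ", min_group,
                  " members; skipped"))
      next
    }
    dat <- participants |>
      filter(.data$participant_id %in% c(members, non_carrier_ids)) |>
      mutate(carrier = .data$participant_id %in% members)
    for (lab in names(lipids)) {
      col <- lipids[[lab]]
      fit <- fit_logistic_or(dat, outcome = "carrier", exposure = col,
                             covariates = covariates, standardize = col)
      rows[[paste(g, lab)]] <- fit$result |>
        mutate(group = g, lipid = lab, .before = 1) |>
        select(-"outcome", -"exposure")
    }
  }
  out <- list_rbind(unname(rows))
  class(out) <- unique(c("fh_assoc_table", class(out)))
  out
}
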
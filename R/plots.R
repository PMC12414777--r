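#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot penetrance by carrier group
#'
#' Bar chart of the fraction of carriers whose corrected maximum LDL-C
#' reaches each threshold, by carrier group.
#'
#' @param object an `fh_penetrance` table.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fh_penetrance
#' @export
autoplot.fh_penetrance <- function(object, ...) {
  dat <- as_tibble(object) |>
    select("group", "pen_4_0", "pen_4_9") |>
    pivot_longer(-"group", names_to = "threshold", values_to = "penetrance") |>
    mutate(threshold = ifelse(.data$threshold == "pen_4_0",
                              ">= 4.0 mmol/L", ">= 4.9 mmol/L"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$penetrance,
                                    fill = .data$threshold)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Penetrance (corrected max LDL-C)",
                  fill = "Threshold") +
    ggplot2::theme_minimal()
}

#' Forest plot of per-group lipid odds ratios
#'
#' @param object an `fh_assoc_table` from [lipid_or_models()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fh_assoc_table
#' @export
autoplot.fh_assoc_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$estimate, y = .data$lipid)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = "Odds ratio per SD (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Lipid profiles by sex and carrier status
#'
#' Generic display of the cohort's lipid panel split by sex and carrier
#' status (boxplots).
#'
#' @param participants participant table with a `carrier` column and lipid
#'   columns `tc`, `ldl`, `hdl`, `tg`.
#' @return a ggplot.
#' @export
plot_lipid_profiles <- function(participants) {
  dat <- as_tibble(participants) |>
    select("sex", "carrier", tc = "tc", ldl = "ldl", hdl = "hdl", tg = "tg") |>
    pivot_longer(c("tc", "ldl", "hdl", "tg"),
                 names_to = "lipid", values_to = "value") |>
    mutate(carrier = ifelse(.data$carrier, "carrier", "non-carrier"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$lipid, y = .data$value,
                                    fill = .data$carrier)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sex)) +
    ggplot2::labs(x = NULL, y = "mmol/L", fill = NULL) +
    ggplot2::theme_minimal()
}
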
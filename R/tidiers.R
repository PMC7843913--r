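# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ROC curve
#'
#' @param x A `coma_roc` from [roc_curve()].
#' @param ... Unused.
#' @return Tibble with one row per threshold: `threshold`, `se`, `sp`.
#' @export
tidy.coma_roc <- function(x, ...) {
  tibble::tibble(
    scale = x$scale %||% NA_character_,
    threshold = x$thresholds, se = x$se_at, sp = x$sp_at
  )
}

#' @rdname tidy.coma_roc
#' @return For `glance()`: a one-row tibble with `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`.
#' @export
glance.coma_roc <- function(x, ...) {
  tibble::tibble(
    scale = x$scale %||% NA_character_, auc = x$auc,
    ci_low = x$ci95[1], ci_high = x$ci95[2],
    level = x$level, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @export
autoplot.coma_roc <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$sp, y = .data$se)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("%s: AUC %.3f (%.3f-%.3f)",
                      object$scale %||% "ROC", object$auc,
                      object$ci95[1], object$ci95[2])
    ) +
    ggplot2::theme_minimal()
}

#' Tidy a validation analysis
#'
#' @param x A `coma_validation` from [validate_scores()].
#' @param ... Unused.
#' @return The stacked pairwise comparisons (AUC and cut-off accuracy
#'   metrics), one row per scale pair and metric with `p_value` and the
#'   `alpha` it is judged against.
#' @export
tidy.coma_validation <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::select(x$auc_comparisons, "scale_a", "scale_b", "metric",
                  "method", prop_a = "auc_a", prop_b = "auc_b",
                  "statistic", "p_value", "alpha"),
    dplyr::select(x$accuracy_comparisons, "scale_a", "scale_b", "metric",
                  "method", "prop_a", "prop_b", "statistic", "p_value",
                  "alpha")
  )
}

#' @rdname tidy.coma_validation
#' @return For `glance()`: one row per scale with its AUC, confidence
#'   interval and Youden cut-off panel.
#' @export
glance.coma_validation <- function(x, ...) {
  aucs <- purrr::map(x$roc, glance) |> dplyr::bind_rows()
  dplyr::left_join(
    aucs,
    dplyr::select(x$cutoffs, "scale", cutoff = "threshold", "se", "sp",
                  "ppv", "npv", "cc", "balanced_accuracy", "youden_j"),
    by = "scale"
  )
}

#' @export
autoplot.coma_validation <- function(object, ...) {
  df <- purrr::map(object$roc, tidy) |> dplyr::bind_rows()
  labs <- purrr::map(object$roc, glance) |>
    dplyr::bind_rows() |>
    dplyr::mutate(lab = sprintf("%s %.3f", .data$scale, .data$auc))
  df <- dplyr::left_join(df, dplyr::select(labs, "scale", "lab"), by = "scale")
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$sp, y = .data$se,
                                   colour = .data$lab)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity", colour = "Scale (AUC)",
      title = sprintf("ROC, %s outcome, %d-h worst scores",
                      object$outcome, object$window)
    ) +
    ggplot2::theme_minimal()
}

#' Score distribution by outcome
#'
#' Violin/jitter plot of a cohort score column split by an outcome, a quick
#' visual of the score-outcome association.
#'
#' @param cohort Cohort tibble (or `coma_cohort`).
#' @param score Name of a score column, e.g. `"incns_72"`.
#' @param outcome `"unfavorable"`, `"nicu_death"` or `"3m_death"`.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(cohort, score = "incns_72",
                                    outcome = "unfavorable") {
  if (inherits(cohort, "coma_cohort")) cohort <- cohort$cohort
  df <- tibble::tibble(
    score = cohort[[score]],
    outcome = ifelse(cohort[[outcome_column(outcome)]], "positive", "negative")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$score)) +
    ggplot2::geom_violin(fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = outcome, y = score) +
    ggplot2::theme_minimal()
}
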
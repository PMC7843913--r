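# Full validation analysis of a cohort: per-scale ROC, Youden cut-offs and
# accuracy panels, and the pairwise comparison matrix.

outcome_column <- function(outcome) {
  switch(outcome,
    unfavorable = "outcome_unfavorable",
    nicu_death = "outcome_nicu_death",
    "3m_death" = ,
    m3_death = "outcome_3m_death",
    abort('`outcome` must be one of "unfavorable", "nicu_death", "3m_death"')
  )
}

#' Validate severity scales against an outcome
#'
#' Runs the full diagnostic-accuracy analysis on a cohort table for one
#' outcome and one scoring window: empirical ROC with DeLong AUC confidence
#' intervals per scale, all pairwise DeLong AUC tests at the
#' multiplicity-corrected level ([bonferroni_alpha()] over the number of
#' pairs), the Youden cut-off and its confusion panel per scale, and the
#' cut-off-based paired accuracy comparisons: McNemar for sensitivity,
#' specificity and correct classification, and the generalized score test
#' for PPV and NPV (alpha 0.05).
#'
#' @param cohort A cohort tibble from [build_cohort()] (the `coma_cohort`
#'   list is also accepted) with `<scale>_<window>` score columns and
#'   `outcome_*` columns.
#' @param outcome `"unfavorable"`, `"nicu_death"` or `"3m_death"`.
#' @param window 24 or 72 (hours).
#' @param scales Scales to analyze (default all four).
#' @param level Confidence level for AUC intervals.
#' @return Object of class `coma_validation`: per-scale `roc` objects,
#'   `cutoffs` tibble, `auc_comparisons` and `accuracy_comparisons` tibbles;
#'   `tidy()` stacks the comparisons, `glance()` the per-scale summary and
#'   `autoplot()` draws the ROC curves.
#' @export
validate_scores <- function(cohort, outcome = "unfavorable", window = 72,
                            scales = c("incns", "apache2", "four", "gcs"),
                            level = 0.95) {
  if (inherits(cohort, "coma_cohort")) cohort <- cohort$cohort
  cohort <- tibble::as_tibble(cohort)
  if (!window %in% c(24, 72)) abort("`window` must be 24 or 72")
  scales <- tolower(scales)
  labels <- check_binary_labels(cohort[[outcome_column(outcome)]])
  score_cols <- paste0(scales, "_", window)
  missing_cols <- setdiff(score_cols, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort lacks score column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  scores <- lapply(score_cols, function(cl) cohort[[cl]])
  names(scores) <- scales
  orientations <- scale_orientation(scales)
  names(orientations) <- scales

  roc <- purrr::imap(scores, function(s, sc) {
    roc_curve(s, labels, orientations[[sc]], level = level, scale = sc)
  })
  cutoffs <- purrr::imap(scores, function(s, sc) {
    dplyr::bind_cols(tibble::tibble(scale = sc),
                     youden_cutoff(s, labels, orientations[[sc]]))
  }) |>
    dplyr::bind_rows()

  pairs <- if (length(scales) > 1) utils::combn(scales, 2, simplify = FALSE) else list()
  alpha_roc <- if (length(pairs) > 0) bonferroni_alpha(length(pairs)) else 0.05
  auc_comparisons <- purrr::map(pairs, function(pr) {
    dplyr::bind_cols(
      tibble::tibble(scale_a = pr[1], scale_b = pr[2]),
      delong_paired_test(scores[[pr[1]]], scores[[pr[2]]], labels,
                         orientations[[pr[1]]], orientations[[pr[2]]],
                         alpha = alpha_roc)
    )
  }) |>
    dplyr::bind_rows()

  predict_at_cutoff <- function(sc) {
    thr <- cutoffs$threshold[cutoffs$scale == sc]
    if (orientations[[sc]] == "higher_is_positive") {
      scores[[sc]] >= thr
    } else {
      scores[[sc]] <= thr
    }
  }
  accuracy_comparisons <- purrr::map(pairs, function(pr) {
    pa <- predict_at_cutoff(pr[1])
    pb <- predict_at_cutoff(pr[2])
    res <- dplyr::bind_rows(
      mcnemar_paired(pa[labels], pb[labels], metric = "se"),
      mcnemar_paired(!pa[!labels], !pb[!labels], metric = "sp"),
      mcnemar_paired(pa == labels, pb == labels, metric = "cc"),
      dplyr::bind_rows(
        compare_predictive_values(pa, pb, labels, "ppv"),
        compare_predictive_values(pa, pb, labels, "npv")
      ) |>
        dplyr::rename(prop_a = "pv_a", prop_b = "pv_b")
    )
    dplyr::bind_cols(tibble::tibble(scale_a = pr[1], scale_b = pr[2]), res)
  }) |>
    dplyr::bind_rows()

  structure(
    list(
      outcome = outcome, window = window, scales = scales,
      n_pos = sum(labels), n_neg = sum(!labels),
      roc = roc, cutoffs = cutoffs,
      auc_comparisons = auc_comparisons,
      accuracy_comparisons = accuracy_comparisons,
      alpha_roc = alpha_roc
    ),
    class = "coma_validation"
  )
}

#' @export
print.coma_validation <- function(x, ...) {
  cat("<coma_validation> outcome:", x$outcome, " window:", x$window, "h  (",
      x$n_pos, "positive /", x$n_neg, "negative )\n")
  for (sc in x$scales) {
    r <- x$roc[[sc]]
    cat(sprintf("  %-8s AUC %.3f (%.3f-%.3f)\n", sc, r$auc, r$ci95[1], r$ci95[2]))
  }
  cat("  ROC comparisons at alpha", x$alpha_roc,
      "; accuracy comparisons at alpha 0.05\n")
  invisible(x)
}
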
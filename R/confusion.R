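# Confusion-matrix metrics, Youden cut-offs, reconstruction from printed
# summaries.

#' Confusion table with derived diagnostic metrics
#'
#' Builds the 2x2 table row and its derived rates: sensitivity,
#' specificity, predictive values, the fraction correctly classified (CC),
#' balanced accuracy `(Se + Sp) / 2` (the quantity reported as "predictive
#' accuracy" in worst-score validation studies) and Youden's J. All rates
#' are kept at full precision; round only at the reporting layer (see
#' [round_half_up()]).
#'
#' @param tp,fp,tn,fn Non-negative integer counts (vectorized).
#' @return Tibble with the counts and derived columns `n`, `se`, `sp`,
#'   `ppv`, `npv`, `cc`, `balanced_accuracy`, `youden_j`.
#' @examples
#' confusion_table(tp = 156, fp = 13, tn = 33, fn = 69)
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  counts <- cbind(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  n <- tp + fp + tn + fn
  if (any(n == 0)) abort("empty confusion table")
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  tibble::tibble(
    tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn),
    fn = as.integer(fn), n = as.integer(n),
    se = se, sp = sp,
    ppv = tp / (tp + fp), npv = tn / (tn + fn),
    cc = (tp + tn) / n,
    balanced_accuracy = (se + sp) / 2,
    youden_j = se + sp - 1
  )
}

#' Confusion table at a score threshold
#'
#' Predicted positive means score `>=` threshold for higher-adverse scales
#' (INCNS, APACHE II) and score `<=` threshold for lower-adverse scales
#' (GCS, FOUR). Vectorized over `threshold`.
#'
#' @inheritParams empirical_auc
#' @param threshold Numeric threshold(s).
#' @return Tibble with one row per threshold: `threshold` plus the
#'   [confusion_table()] columns.
#' @export
confusion_at_cutoff <- function(scores, labels, threshold,
                                orientation = "higher_is_positive") {
  labels <- check_binary_labels(labels)
  check_finite(threshold, "threshold")
  s <- oriented_scores(scores, orientation)
  thr <- oriented_scores(threshold, orientation)
  rows <- lapply(thr, function(t) {
    pred <- s >= t
    confusion_table(
      tp = sum(pred & labels), fp = sum(pred & !labels),
      tn = sum(!pred & !labels), fn = sum(!pred & labels)
    )
  })
  dplyr::bind_cols(
    tibble::tibble(threshold = threshold),
    dplyr::bind_rows(rows)
  )
}

#' Youden-index cut-off
#'
#' Scans every observed score as a candidate threshold and returns the one
#' maximizing `Se + Sp` (equivalently Youden's J). Ties are broken toward
#' higher sensitivity (not missing adverse outcomes), then toward the more
#' inclusive threshold.
#'
#' @inheritParams empirical_auc
#' @return One-row tibble: `threshold` plus the [confusion_table()] columns.
#' @examples
#' youden_cutoff(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))$threshold  # 5
#' @export
youden_cutoff <- function(scores, labels, orientation = "higher_is_positive") {
  grid <- confusion_at_cutoff(scores, labels, sort(unique(scores)), orientation)
  ord <- order(
    -(grid$se + grid$sp),
    -grid$se,
    if (check_orientation(orientation) == "higher_is_positive")
      grid$threshold else -grid$threshold
  )
  grid[ord[1], , drop = FALSE]
}

#' Reconstruct a confusion table from printed sensitivity/specificity
#'
#' Given a published sensitivity and specificity (percent, one decimal) and
#' the class sizes, recovers the integer table: `tp` and `tn` round half-up,
#' the complements fill `fn` and `fp`. Used to recover PPV, NPV and CC from
#' printed accuracy panels.
#'
#' @param se_pct,sp_pct Percentages in `[0, 100]`.
#' @param n_pos,n_neg Positive and negative class sizes.
#' @return One-row tibble as from [confusion_table()].
#' @examples
#' reconstruct_confusion(76.9, 88.2, 26, 245)[, c("tp", "tn", "ppv", "npv")]
#' @export
reconstruct_confusion <- function(se_pct, sp_pct, n_pos, n_neg) {
  check_finite(c(se_pct, sp_pct), "se_pct/sp_pct")
  if (any(c(se_pct, sp_pct) < 0) || any(c(se_pct, sp_pct) > 100)) {
    abort("`se_pct` and `sp_pct` must be in [0, 100]")
  }
  if (any(c(n_pos, n_neg) <= 0)) abort("class sizes must be positive")
  tp <- round_half_up(se_pct / 100 * n_pos, 0)
  tn <- round_half_up(sp_pct / 100 * n_neg, 0)
  if (any(tp > n_pos) || any(tn > n_neg)) {
    abort("rounding produced counts exceeding the class sizes")
  }
  confusion_table(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' Bonferroni-corrected significance level
#'
#' `0.05 / n`, rounded to four decimals as conventionally reported; six
#' pairwise ROC comparisons give 0.0083.
#'
#' @param n_comparisons Number of comparisons (>= 1).
#' @return Corrected alpha.
#' @examples
#' bonferroni_alpha(6)  # 0.0083
#' @export
bonferroni_alpha <- function(n_comparisons) {
  check_finite(n_comparisons, "n_comparisons")
  if (any(n_comparisons < 1 | n_comparisons != round(n_comparisons))) {
    abort("`n_comparisons` must be a positive integer")
  }
  round(0.05 / n_comparisons, 4)
}
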
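# Empirical ROC analysis with DeLong variance machinery.
#
# All internals work on a "positive-adverse" representation: for scales where
# low values are adverse (GCS, FOUR) the scores are negated up front, so the
# Mann-Whitney kernel and the DeLong placements are always written for
# higher = more positive.

check_orientation <- function(orientation) {
  if (!orientation %in% c("higher_is_positive", "lower_is_positive")) {
    abort('`orientation` must be "higher_is_positive" or "lower_is_positive"')
  }
  orientation
}

check_binary_labels <- function(labels) {
  labels <- as.logical(labels)
  if (any(is.na(labels))) abort("`labels` must be binary with no missing values")
  if (all(labels) || !any(labels)) {
    abort("both outcome classes must be present")
  }
  labels
}

oriented_scores <- function(scores, orientation) {
  check_finite(scores, "scores")
  if (check_orientation(orientation) == "lower_is_positive") -scores else scores
}

# DeLong structural components (placements). Midrank implementation:
# V10[i] = Pr-hat(score_pos_i more adverse than a random negative), etc.
delong_placements <- function(scores, labels) {
  x <- scores[labels]
  y <- scores[!labels]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(v10 = v10, v01 = v01, auc = sum(r_all[seq_len(m)] / (m * n)) -
         (m + 1) / (2 * n))
}

#' Empirical AUC by pair counting
#'
#' The Mann-Whitney estimate: the fraction of (positive, negative) pairs in
#' which the positive subject has the more adverse score, ties counting 1/2.
#'
#' @param scores Numeric score vector.
#' @param labels Binary outcome vector (`TRUE`/1 = positive class).
#' @param orientation `"higher_is_positive"` (INCNS, APACHE II) or
#'   `"lower_is_positive"` (GCS, FOUR).
#' @return AUC in `[0, 1]`.
#' @examples
#' empirical_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))  # 1
#' @export
empirical_auc <- function(scores, labels, orientation = "higher_is_positive") {
  labels <- check_binary_labels(labels)
  if (length(scores) != length(labels)) abort("`scores` and `labels` lengths differ")
  s <- oriented_scores(scores, orientation)
  delong_placements(s, labels)$auc
}

#' AUC with a DeLong confidence interval
#'
#' Variance from the DeLong structural components; the interval is computed
#' on the logit scale and back-transformed (clipped to `[0, 1]`), which keeps
#' it inside the unit interval. When the placement values are degenerate
#' (e.g. perfect separation) the interval collapses to the point estimate
#' with a warning. A stratified bootstrap percentile interval is available
#' with `ci_method = "bootstrap"`.
#'
#' @inheritParams empirical_auc
#' @param level Confidence level (default 0.95).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return One-row tibble: `auc`, `ci_low`, `ci_high`, `var_auc`, `n_pos`,
#'   `n_neg`, `degenerate`.
#' @export
delong_auc_ci <- function(scores, labels, orientation = "higher_is_positive",
                          level = 0.95, ci_method = c("delong", "bootstrap"),
                          n_boot = 2000) {
  ci_method <- match.arg(ci_method)
  labels <- check_binary_labels(labels)
  s <- oriented_scores(scores, orientation)
  m <- sum(labels)
  n <- sum(!labels)
  if (m < 2 || n < 2) abort("need at least 2 subjects in each class")
  pl <- delong_placements(s, labels)
  auc <- pl$auc
  v <- stats::var(pl$v10) / m + stats::var(pl$v01) / n
  degenerate <- !is.finite(v) || v <= .Machine$double.eps ||
    auc <= 0 || auc >= 1
  if (ci_method == "bootstrap") {
    reps <- replicate(n_boot, {
      i_pos <- sample(which(labels), m, replace = TRUE)
      i_neg <- sample(which(!labels), n, replace = TRUE)
      idx <- c(i_pos, i_neg)
      delong_placements(s[idx], labels[idx])$auc
    })
    ci <- unname(quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2)))
  } else if (degenerate) {
    warn("degenerate DeLong variance; CI collapsed to the point estimate")
    ci <- c(auc, auc)
  } else {
    z <- qnorm(1 - (1 - level) / 2)
    lg <- stats::qlogis(auc)
    half <- z * sqrt(v) / (auc * (1 - auc))
    ci <- stats::plogis(c(lg - half, lg + half))
  }
  tibble::tibble(
    auc = auc, ci_low = max(0, min(ci)), ci_high = min(1, max(ci)),
    var_auc = v, n_pos = m, n_neg = n, degenerate = degenerate
  )
}

#' Paired DeLong test for two correlated AUCs
#'
#' Two-sided z-test on the AUC difference of two scores measured on the same
#' subjects, using the paired DeLong covariance of the structural
#' components. The ROC-family significance level defaults to the
#' multiplicity-corrected 0.0083 (six pairwise comparisons).
#'
#' @param scores_a,scores_b Paired score vectors (same subjects).
#' @param labels Binary outcome vector.
#' @param orientation_a,orientation_b Orientation of each score.
#' @param alpha Significance level recorded in the result.
#' @return One-row tibble: `metric`, `method`, `auc_a`, `auc_b`, `estimate`
#'   (AUC difference), `statistic` (z), `p_value`, `alpha`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels,
                               orientation_a = "higher_is_positive",
                               orientation_b = "higher_is_positive",
                               alpha = 0.0083) {
  labels <- check_binary_labels(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels)) {
    abort("`scores_a`, `scores_b` and `labels` must have the same length")
  }
  sa <- oriented_scores(scores_a, orientation_a)
  sb <- oriented_scores(scores_b, orientation_b)
  m <- sum(labels)
  n <- sum(!labels)
  pa <- delong_placements(sa, labels)
  pb <- delong_placements(sb, labels)
  diff <- pa$auc - pb$auc
  var_d <- stats::var(pa$v10 - pb$v10) / m + stats::var(pa$v01 - pb$v01) / n
  if (!is.finite(var_d) || var_d <= .Machine$double.eps) {
    z <- 0
    p <- if (abs(diff) < 1e-12) 1 else 0
  } else {
    z <- diff / sqrt(var_d)
    p <- 2 * pnorm(-abs(z))
  }
  tibble::tibble(
    metric = "auc", method = "delong", auc_a = pa$auc, auc_b = pb$auc,
    estimate = diff, statistic = z, p_value = p, alpha = alpha
  )
}

#' Empirical ROC curve with AUC and confidence interval
#'
#' Evaluates sensitivity and specificity at every observed score (predicted
#' positive when the score is at least the threshold for higher-adverse
#' scales, at most the threshold for lower-adverse scales) and attaches the
#' DeLong AUC machinery of [delong_auc_ci()].
#'
#' @inheritParams delong_auc_ci
#' @param scale Optional scale label carried through to outputs.
#' @return Object of class `coma_roc` with `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
roc_curve <- function(scores, labels, orientation = "higher_is_positive",
                      level = 0.95, ci_method = "delong", scale = NULL) {
  labels <- check_binary_labels(labels)
  thresholds <- sort(unique(scores))
  conf <- confusion_at_cutoff(scores, labels, thresholds, orientation)
  ci <- delong_auc_ci(scores, labels, orientation, level = level,
                      ci_method = ci_method)
  structure(
    list(
      scale = scale, orientation = orientation, thresholds = thresholds,
      se_at = conf$se, sp_at = conf$sp, auc = ci$auc,
      ci95 = c(ci$ci_low, ci$ci_high), level = level,
      n_pos = ci$n_pos, n_neg = ci$n_neg, var_auc = ci$var_auc,
      degenerate = ci$degenerate
    ),
    class = "coma_roc"
  )
}

#' @export
print.coma_roc <- function(x, ...) {
  cat("<coma_roc>", x$scale %||% "", "\n")
  cat(sprintf("  AUC %.3f (%d%% CI %.3f-%.3f), %d positive / %d negative\n",
              x$auc, round(100 * x$level), x$ci95[1], x$ci95[2],
              x$n_pos, x$n_neg))
  invisible(x)
}
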
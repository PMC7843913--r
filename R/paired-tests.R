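# Paired comparisons of classification accuracy: McNemar tests for Se / Sp /
# CC and a cluster-robust generalized score test for PPV / NPV.

#' McNemar test for paired classification accuracy
#'
#' Compares two classifiers' correctness on the same subjects: sensitivity
#' (restrict to true positives), specificity (true negatives) or overall
#' correct classification (all subjects). Uses the exact binomial test on
#' the discordant pairs when there are fewer than 25 of them, otherwise the
#' continuity-corrected chi-square approximation.
#'
#' @param correct_a,correct_b Logical vectors: was each subject classified
#'   correctly by score A / score B (already restricted to the relevant
#'   subset for Se or Sp).
#' @param metric Label recorded in the result (`"se"`, `"sp"` or `"cc"`).
#' @param method `"auto"` (default: exact below 25 discordant pairs),
#'   `"exact"` or `"asymptotic"`.
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return One-row tibble: `metric`, `method`, `prop_a`, `prop_b`, `b`
#'   (A correct, B wrong), `c` (A wrong, B correct), `statistic`, `p_value`,
#'   `alpha`, `note`.
#' @export
mcnemar_paired <- function(correct_a, correct_b, metric = "cc",
                           method = c("auto", "exact", "asymptotic"),
                           alpha = 0.05) {
  method <- match.arg(method)
  correct_a <- as.logical(correct_a)
  correct_b <- as.logical(correct_b)
  if (length(correct_a) != length(correct_b) || anyNA(correct_a) || anyNA(correct_b)) {
    abort("`correct_a` and `correct_b` must be equal-length logical vectors without NA")
  }
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  note <- ""
  if (b + cc == 0) {
    method_used <- "mcnemar_degenerate"
    stat <- 0
    p <- 1
    note <- "no discordant pairs"
  } else if (method == "exact" || (method == "auto" && b + cc < 25)) {
    method_used <- "mcnemar_exact"
    stat <- min(b, cc)
    p <- min(1, 2 * pbinom(min(b, cc), b + cc, 0.5))
  } else {
    method_used <- "mcnemar_asymptotic"
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  tibble::tibble(
    metric = metric, method = method_used,
    prop_a = mean(correct_a), prop_b = mean(correct_b),
    b = b, c = cc, statistic = stat, p_value = p, alpha = alpha, note = note
  )
}

#' Generalized score test for paired predictive values
#'
#' Tests equality of the positive (or negative) predictive values of two
#' dichotomized scores applied to the same subjects. Records are stacked
#' over the subjects' predicted-positive (PPV) or predicted-negative (NPV)
#' results of each score and a cluster-robust score statistic for the
#' score-indicator effect on the outcome is formed (the marginal-regression
#' score-test family of Leisenring, Alonzo and Pepe); subjects contribute
#' one or two records and act as clusters.
#'
#' @param predictions_a,predictions_b Logical/0-1 vectors of dichotomized
#'   predictions from scores A and B on the same subjects.
#' @param labels Binary outcome vector.
#' @param metric `"ppv"` or `"npv"`.
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return One-row tibble: `metric`, `method`, `pv_a`, `pv_b`, `statistic`
#'   (chi-square, 1 df), `p_value`, `alpha`, `note`.
#' @export
compare_predictive_values <- function(predictions_a, predictions_b, labels,
                                      metric = c("ppv", "npv"), alpha = 0.05) {
  metric <- match.arg(metric)
  labels <- check_binary_labels(labels)
  pa <- as.logical(predictions_a)
  pb <- as.logical(predictions_b)
  if (length(pa) != length(labels) || length(pb) != length(labels) ||
      anyNA(pa) || anyNA(pb)) {
    abort("predictions must be binary vectors matching `labels` in length")
  }
  if (metric == "npv") {
    pa <- !pa
    pb <- !pb
    labels <- !labels
  }
  if (!any(pa) || !any(pb)) {
    abort(sprintf("%s undefined: a score has no predicted %s",
                  toupper(metric), if (metric == "ppv") "positives" else "negatives"))
  }
  # stacked records: one per (subject, score) with a positive prediction
  cluster <- c(which(pa), which(pb))
  x <- c(rep(0, sum(pa)), rep(1, sum(pb)))
  y <- as.numeric(c(labels[pa], labels[pb]))
  mu <- mean(y)
  xc <- x - mean(x)
  resid <- y - mu
  u <- sum(xc * resid)
  cl_sum <- tapply(xc * resid, cluster, sum)
  v <- sum(cl_sum^2)
  note <- ""
  if (!is.finite(v) || v <= .Machine$double.eps) {
    stat <- 0
    p <- if (abs(u) < 1e-12) 1 else 0
    note <- "degenerate score variance"
  } else {
    stat <- u^2 / v
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  tibble::tibble(
    metric = metric, method = "generalized_score",
    pv_a = mean(labels[pa]), pv_b = mean(labels[pb]),
    statistic = stat, p_value = p, alpha = alpha, note = note
  )
}
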
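# Diagnostic accuracy statistics: Mann-Whitney AUC, DeLong variance and the
# one-sided paired DeLong test, exact Clopper-Pearson intervals, McNemar
# tests, and report assembly.

#' ROC area under the curve (Mann-Whitney form)
#'
#' `AUC = mean over (positive, negative) pairs of [score_p > score_n] +
#' 1/2 [tie]`.
#'
#' @param scores numeric positive-class scores.
#' @param labels binary truth (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both classes must be present")
  }
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# DeLong structural components: V10 (per positive), V01 (per negative)
delong_components <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
}

#' DeLong confidence interval for an AUC
#'
#' Variance from the structural components of the Mann-Whitney statistic;
#' normal-approximation interval truncated to `[0, 1]`. The point estimate
#' equals [roc_auc()] exactly.
#'
#' @param scores,labels as in [roc_auc()] (>= 2 members per class).
#' @param alpha significance level (default 0.05 for a 95% CI).
#' @return list with `auc`, `lo`, `hi`, `se`.
#' @export
delong_ci <- function(scores, labels, alpha = 0.05) {
  labels <- as.integer(labels)
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  if (m < 2 || n < 2) stop("need at least 2 members per class")
  dc <- delong_components(scores, labels)
  v <- stats::var(dc$v10) / m + stats::var(dc$v01) / n
  if (v == 0 && dc$auc < 1 && dc$auc > 0) {
    warning("degenerate zero DeLong variance; collapsing CI to the point")
  }
  z <- stats::qnorm(1 - alpha / 2)
  list(auc = dc$auc,
       lo = max(0, dc$auc - z * sqrt(v)),
       hi = min(1, dc$auc + z * sqrt(v)),
       se = sqrt(v))
}

#' One-sided paired DeLong test for two correlated ROC curves
#'
#' Tests the alternative `AUC_a > AUC_b` for two score vectors over the same
#' subjects, using the covariance of the paired structural components.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels shared binary truth.
#' @return list with `auc_a`, `auc_b`, `z`, `p` (upper-tail one-sided).
#' @export
delong_compare_one_sided <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("paired score vectors and labels must have equal length")
  }
  labels <- as.integer(labels)
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  v10 <- cbind(da$v10, db$v10)
  v01 <- cbind(da$v01, db$v01)
  s10 <- stats::cov(v10); s01 <- stats::cov(v01)
  contrast <- c(1, -1)
  v <- drop(t(contrast) %*% (s10 / m + s01 / n) %*% contrast)
  d <- da$auc - db$auc
  z <- if (v > 0) d / sqrt(v) else if (d == 0) 0 else sign(d) * Inf
  list(auc_a = da$auc, auc_b = db$auc, z = z,
       p = stats::pnorm(z, lower.tail = FALSE))
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact Beta-quantile bounds; `lo = 0` when `k = 0` and `hi = 1` when
#' `k = n`.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @param alpha significance level (default 0.05).
#' @return list with `point` (`k/n`), `lo`, `hi`.
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    stop("require integers 0 <= k <= n, n >= 1")
  }
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  list(point = k / n, lo = lo, hi = hi)
}

#' McNemar test from discordant pair counts
#'
#' Two-sided paired test of marginal proportions. With few discordant pairs
#' (`b + c < 25`) the exact binomial test on `(b, b + c)` at p = 1/2 is
#' used; otherwise the continuity-corrected chi-square approximation.
#'
#' @param b,c discordant counts (a-only and b-only successes).
#' @param verbose also return both variants.
#' @return list with `p`, `method`, and (if `verbose`) `p_exact`,
#'   `p_chisq`.
#' @export
mcnemar_discordant <- function(b, c, verbose = FALSE) {
  stopifnot(b >= 0, c >= 0, b == round(b), c == round(c))
  if (b == 0 && c == 0) {
    warning("no discordant pairs; McNemar test is degenerate")
    return(list(p = 1, method = "degenerate"))
  }
  p_exact <- stats::binom.test(b, b + c, p = 0.5)$p.value
  p_chisq <- stats::mcnemar.test(matrix(c(0, c, b, 0), 2, 2))$p.value
  if (b + c < 25) {
    out <- list(p = p_exact, method = "exact")
  } else {
    out <- list(p = p_chisq, method = "chisq")
  }
  if (verbose) {
    out$p_exact <- p_exact
    out$p_chisq <- p_chisq
  }
  out
}

#' Assemble a diagnostic report from per-ear predictions
#'
#' Dichotomizes each ear (negative if the argmax category is normal), then
#' reports ROC AUC with a DeLong 95% CI on the `1 - p(normal)` scores,
#' sensitivity/specificity/accuracy with exact Clopper-Pearson CIs, and the
#' 3 x 3 confusion matrix (true category x predicted argmax category). The
#' two ears of a subject are treated as independent observations.
#'
#' @param predictions list of per-subject `BilateralPrediction`s, or a list
#'   of per-ear 3-vectors when `labels` carries one row per ear.
#' @param labels data.frame with columns `subject_id`, `right`, `left` (one
#'   row per subject, non-excluded), aligned with `predictions`.
#' @return a `DiagnosticReport`: list with `auc`, `auc_ci`, `sensitivity`,
#'   `specificity`, `accuracy` (each a list with point/lo/hi/k/n),
#'   `confusion`, `n_ears`.
#' @export
evaluate <- function(predictions, labels) {
  if (length(predictions) != nrow(labels)) {
    stop("predictions and labels are misaligned")
  }
  if (any(labels$right == 3L | labels$left == 3L)) {
    stop("excluded (postoperative) labels cannot be evaluated")
  }
  truth <- integer(0); probs <- list()
  for (i in seq_len(nrow(labels))) {
    p <- predictions[[i]]
    if (!is.null(p$right_probs)) {
      probs <- c(probs, list(p$right_probs), list(p$left_probs))
      truth <- c(truth, labels$right[i], labels$left[i])
    } else {
      stop("predictions must be BilateralPrediction objects")
    }
  }
  report_from_ears(probs, truth)
}

report_from_ears <- function(probs, truth) {
  n <- length(truth)
  pred_cat <- vapply(probs, function(p) {
    d <- dichotomize_prediction(p)
    if (d$outcome == "negative") 0L else which.max(p[2:3])
  }, integer(1))
  score <- vapply(probs, function(p) 1 - p[1], numeric(1))
  y <- as.integer(truth > 0L)
  yhat <- as.integer(pred_cat > 0L)
  confusion <- matrix(0L, 3, 3, dimnames = list(true = 0:2, predicted = 0:2))
  for (i in seq_len(n)) {
    confusion[truth[i] + 1L, pred_cat[i] + 1L] <-
      confusion[truth[i] + 1L, pred_cat[i] + 1L] + 1L
  }
  tp <- sum(y == 1L & yhat == 1L); fn <- sum(y == 1L & yhat == 0L)
  tn <- sum(y == 0L & yhat == 0L); fp <- sum(y == 0L & yhat == 1L)
  acc_k <- sum(diag(confusion))
  prop <- function(k, nn) c(clopper_pearson(k, nn), list(k = k, n = nn))
  auc_ci <- if (length(unique(y)) == 2 && sum(y) >= 2 && sum(1 - y) >= 2) {
    delong_ci(score, y)
  } else {
    list(auc = NA_real_, lo = NA_real_, hi = NA_real_, se = NA_real_)
  }
  structure(list(
    auc = auc_ci$auc, auc_ci = c(lo = auc_ci$lo, hi = auc_ci$hi),
    sensitivity = prop(tp, tp + fn),
    specificity = prop(tn, tn + fp),
    accuracy = prop(acc_k, n),
    confusion = confusion,
    n_ears = n,
    scores = score, truth_binary = y),
    class = "DiagnosticReport")
}

#' @export
print.DiagnosticReport <- function(x, ...) {
  pct <- function(p) {
    sprintf("%.1f%% (%d/%d, %.1f-%.1f%%)", 100 * p$point, p$k, p$n,
            100 * p$lo, 100 * p$hi)
  }
  cat("Diagnostic report (", x$n_ears, " ears)\n", sep = "")
  if (!is.na(x$auc)) {
    cat(sprintf("  AUC         %.3f (%.3f-%.3f)\n", x$auc,
                x$auc_ci["lo"], x$auc_ci["hi"]))
  }
  cat("  Sensitivity ", pct(x$sensitivity), "\n", sep = "")
  cat("  Specificity ", pct(x$specificity), "\n", sep = "")
  cat("  Accuracy    ", pct(x$accuracy), "\n", sep = "")
  cat("  Confusion matrix (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}
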
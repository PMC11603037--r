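#' Area under the ROC curve
#'
#' Rank-based concordance over all positive/negative pairs, counting ties as
#' one half — the Mann-Whitney formulation.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (both classes must be present).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration of the precision-recall curve over the distinct score
#' thresholds (each recall increment weighted by the precision reached
#' there). For random scores this approaches the outcome prevalence, the
#' chance level of the metric.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) stop("AUPRC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # collapse tied scores: metrics are defined per distinct threshold
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics at a threshold
#'
#' @inheritParams auroc
#' @param threshold scores `>= threshold` are predicted positive.
#' @param recall_level recall floor for the precision-at-recall summary
#'   (`max` precision among thresholds with recall at or above it).
#' @return list with `auroc`, `auprc`, `sensitivity`, `specificity`,
#'   `precision`, `precision_at_recall`, `threshold`, `recall_level`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5,
                            recall_level = 0.8) {
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0); fp <- sum(pred & labels == 0)
  sweep_df <- threshold_sweep(scores, labels)
  ok <- sweep_df$recall >= recall_level & !is.na(sweep_df$precision)
  list(auroc = auroc(scores, labels),
       auprc = auprc(scores, labels),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       precision_at_recall = if (any(ok)) max(sweep_df$precision[ok]) else NA_real_,
       threshold = threshold, recall_level = recall_level)
}

# confusion quantities at every distinct score used as a cut point
threshold_sweep <- function(scores, labels) {
  thr <- sort(unique(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  out <- data.frame(threshold = thr, sensitivity = NA_real_,
                    specificity = NA_real_, precision = NA_real_,
                    recall = NA_real_)
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    out$sensitivity[i] <- tp / n1
    out$recall[i] <- tp / n1
    out$specificity[i] <- (n0 - fp) / n0
    out$precision[i] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  }
  out
}

#' Bootstrap confidence intervals for test metrics
#'
#' Draws `B` resamples of the test surgeries with replacement (same size as
#' the test set), computes AUROC and AUPRC on each, and reports the mean and
#' percentile 95% interval. Resamples containing a single class are redrawn
#' (their count is recorded).
#'
#' @inheritParams auroc
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @return object of class `bootstrap_result`: list with per-resample vectors
#'   `auroc`, `auprc`, their `mean` and `ci` (2.5/97.5 percentiles), `B`,
#'   `seed`, `n_redrawn`.
#' @export
bootstrap_metrics <- function(scores, labels, B = 1000, seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  if (length(unique(labels)) < 2) stop("test set needs both classes")
  n <- length(scores)
  roc <- numeric(B); prc <- numeric(B)
  n_redrawn <- 0L
  local_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
        n_redrawn <- n_redrawn + 1L
      }
      roc[b] <- auroc(scores[idx], labels[idx])
      prc[b] <- auprc(scores[idx], labels[idx])
    }
  })
  out <- list(auroc = roc, auprc = prc,
              mean = c(auroc = mean(roc), auprc = mean(prc)),
              ci = rbind(auroc = stats::quantile(roc, c(0.025, 0.975), names = FALSE),
                         auprc = stats::quantile(prc, c(0.025, 0.975), names = FALSE)),
              B = B, seed = as.integer(seed), n_redrawn = n_redrawn)
  class(out) <- "bootstrap_result"
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap (B = %d): AUROC %.3f [%.3f, %.3f], AUPRC %.3f [%.3f, %.3f]\n",
              x$B, x$mean["auroc"], x$ci["auroc", 1], x$ci["auroc", 2],
              x$mean["auprc"], x$ci["auprc", 1], x$ci["auprc", 2]))
  if (x$n_redrawn > 0) cat("single-class resamples redrawn:", x$n_redrawn, "\n")
  invisible(x)
}

#' Train/test-size corrected paired t-test for resampled metrics
#'
#' Bootstrapped test sets are strongly dependent, so a plain paired t-test
#' on per-resample metric vectors underestimates the variance. The corrected
#' statistic inflates the variance of the per-resample differences `D` by the
#' train/test size ratio: `sigma2_mod = Var(D) * (1/n + n_train/n_test)` and
#' `t = mean(D) / sqrt(sigma2_mod)` with `n - 1` degrees of freedom
#' (two-sided p). By default `D = |P0 - P1|`, making the mean difference
#' non-negative; set `absolute = FALSE` for signed differences, and
#' `ratio = "test_over_train"` for the orientation used in the resampling
#' correction literature.
#'
#' @param P0,P1 equal-length per-resample metric vectors for the two models.
#' @param n_train,n_test training and test set sizes.
#' @param absolute use `|P0 - P1|` (default) or signed differences.
#' @param ratio size-ratio orientation entering the variance correction.
#' @return list with `t`, `p`, `D_bar`, `sigma2_mod`, `df`.
#' @export
corrected_t_test <- function(P0, P1, n_train, n_test,
                             absolute = TRUE,
                             ratio = c("train_over_test", "test_over_train")) {
  ratio <- match.arg(ratio)
  stopifnot(length(P0) == length(P1), length(P0) >= 2,
            n_train > 0, n_test > 0)
  D <- if (absolute) abs(P0 - P1) else P0 - P1
  n <- length(D)
  rr <- if (ratio == "train_over_test") n_train / n_test else n_test / n_train
  s2 <- stats::var(D) * (1 / n + rr)
  D_bar <- mean(D)
  if (s2 == 0) {
    if (D_bar == 0) {
      return(list(t = 0, p = 1, D_bar = 0, sigma2_mod = 0, df = n - 1))
    }
    warning("zero variance with non-zero mean difference; t set to +Inf")
    return(list(t = Inf, p = 0, D_bar = D_bar, sigma2_mod = 0, df = n - 1))
  }
  t_stat <- D_bar / sqrt(s2)
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  list(t = t_stat, p = p, D_bar = D_bar, sigma2_mod = s2, df = n - 1)
}

#' Decision-threshold scenarios
#'
#' Three clinically motivated operating points: Scenario A maximizes the sum
#' of sensitivity and specificity, Scenario B maximizes the sum of precision
#' and recall, Scenario C uses the highest threshold whose recall still
#' reaches `recall_target` (i.e. the most precise operating point subject to
#' the recall floor).
#'
#' @inheritParams auroc
#' @param recall_target recall floor for Scenario C.
#' @return `data.frame` with one row per scenario: threshold, sensitivity,
#'   specificity, precision, recall.
#' @export
threshold_scenarios <- function(scores, labels, recall_target = 0.8) {
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  sw <- threshold_sweep(scores, labels)
  a <- which.max(sw$sensitivity + sw$specificity)
  pr <- ifelse(is.na(sw$precision), -Inf, sw$precision)
  b <- which.max(pr + sw$recall)
  ok <- which(sw$recall >= recall_target)
  if (length(ok) == 0) stop("recall ", recall_target, " is unreachable")
  cc <- max(ok)  # thresholds are sorted ascending; recall is non-increasing
  rows <- c(A = a, B = b, C = cc)
  out <- sw[rows, ]
  out$scenario <- names(rows)
  rownames(out) <- NULL
  out[, c("scenario", "threshold", "sensitivity", "specificity",
          "precision", "recall")]
}

#' Scale an operating point to a daily caseload confusion matrix
#'
#' Projects a recall/precision operating point onto a stated caseload and
#' prevalence: `P = round(caseload * prevalence)` positives,
#' `N = caseload - P` negatives, `TP = floor(recall * P)`, predicted
#' positives `PP = round(TP / precision)`, `FP = PP - TP`, `TN = N - FP`,
#' `FN = P - TP`.
#'
#' @param recall,precision operating point in `(0, 1]`.
#' @param caseload surgeries per day.
#' @param prevalence POD prevalence.
#' @return named integer vector `c(TP, FP, TN, FN, P, N)`.
#' @export
scale_confusion <- function(recall, precision, caseload = 100,
                            prevalence = 0.09) {
  stopifnot(recall > 0, recall <= 1, precision > 0, precision <= 1,
            caseload * prevalence >= 1)
  P <- round(caseload * prevalence)
  N <- caseload - P
  TP <- floor(recall * P)
  PP <- round(TP / precision)
  FP <- PP - TP
  if (FP < 0) stop("inconsistent recall/precision: negative false positives")
  TN <- N - FP
  FN <- P - TP
  c(TP = TP, FP = FP, TN = TN, FN = FN, P = P, N = N)
}

#' Summarize an attention matrix for reporting
#'
#' Row sums of the feature-by-time saliency give per-feature importance over
#' time; the per-time profile is the mean attention mass per time index with
#' a bootstrap percentile CI over surgeries.
#'
#' @param am an `attention_matrix` from [extract_attention()].
#' @param B bootstrap resamples for the time-profile CI.
#' @param seed integer seed.
#' @return list with `feature_importance` (named, sums over time) and
#'   `time_profile` (`data.frame`: time, mean, lo, hi).
#' @export
aggregate_attention_report <- function(am, B = 200, seed = 1L) {
  stopifnot(inherits(am, "attention_matrix"))
  fi <- rowSums(am$saliency)
  names(fi) <- am$channel_names
  P <- am$per_surgery_time
  m <- nrow(P)
  boots <- local_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      colMeans(P[sample.int(m, m, replace = TRUE), , drop = FALSE])
    }, numeric(ncol(P))))
  })
  tp <- data.frame(time = am$time_min,
                   mean = colMeans(P),
                   lo = apply(boots, 2, stats::quantile, 0.025),
                   hi = apply(boots, 2, stats::quantile, 0.975))
  list(feature_importance = fi, time_profile = tp)
}
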
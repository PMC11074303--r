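# Evaluation battery: pooled two-sample t-test on the first principal
# component (cancer vs non-cancer pixels), per-region ROC/AUC with Youden
# segmentation thresholds, one-vs-rest classification metrics built from
# the TP/TN/FP/FN counts, and learning-curve summaries.

#' Pooled two-sample t-test
#'
#' Student's t-test with pooled variance: degrees of freedom
#' `n1 + n2 - 2`, two-sided p-value, and a 95% confidence interval for
#' `mean(a) - mean(b)`. `log10_p` is computed on the log scale so extreme
#' statistics do not underflow to an uninformative zero.
#'
#' @param a,b numeric samples, each with at least 2 values.
#' @param conf_level confidence level for the interval.
#' @return Object of class `ttest_result`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `log10_p`, `confidence_interval`,
#'   `pooled_sd`, `mean_difference`.
#' @export
two_sample_ttest <- function(a, b, conf_level = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each sample needs at least 2 values")
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  diff <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (diff != 0)
      stop("degenerate error: zero pooled variance with unequal means")
    tt <- list(statistic = 0, p.value = 1, conf.int = c(0, 0))
    log10_p <- 0
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE, conf.level = conf_level)
    log10_p <- (stats::pt(abs(tt$statistic), df, lower.tail = FALSE,
                          log.p = TRUE) + log(2)) / log(10)
  }
  structure(list(t_statistic = unname(tt$statistic),
                 degrees_of_freedom = df,
                 p_value = unname(tt$p.value),
                 log10_p = unname(log10_p),
                 confidence_interval = as.numeric(tt$conf.int),
                 pooled_sd = sqrt(sp2),
                 mean_difference = diff,
                 n = c(n1, n2)),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf(
    "Pooled two-sample t-test: t = %.4f, df = %d, p = %.4g (log10 p = %.2f)\n",
    x$t_statistic, x$degrees_of_freedom, x$p_value, x$log10_p))
  cat(sprintf("  mean difference %.4f, 95%% CI [%.4f, %.4f], pooled SD %.4f\n",
              x$mean_difference, x$confidence_interval[1],
              x$confidence_interval[2], x$pooled_sd))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann–Whitney) AUC with half credit for ties: the probability
#' that a random positive outscores a random negative. Equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric per-pixel scores.
#' @param positives logical (or 0/1) mask of positive pixels; both classes
#'   must be present.
#' @return Scalar AUC in \[0, 1\].
#' @export
auc <- function(scores, positives) {
  positives <- as.logical(positives)
  if (length(scores) != length(positives))
    stop("dimension error: scores and positives differ in length")
  n_pos <- sum(positives); n_neg <- sum(!positives)
  if (n_pos == 0L || n_neg == 0L)
    stop("undefined-AUC error: both classes must be present")
  r <- rank(scores)  # average ranks give the tie half-credit
  (sum(r[positives]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Most favorable segmentation threshold (Youden's J)
#'
#' Scans all candidate thresholds (midpoints between adjacent distinct
#' scores plus the extremes; a pixel is called positive when its score is
#' >= the threshold) and returns the maximizer of
#' `J = sensitivity + specificity - 1`. Ties are broken toward higher
#' sensitivity, prioritizing cancer identification over the other regions.
#'
#' @param scores numeric scores.
#' @param positives logical positive mask; both classes must be present.
#' @return List: `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
best_threshold <- function(scores, positives) {
  positives <- as.logical(positives)
  n_pos <- sum(positives); n_neg <- sum(!positives)
  if (n_pos == 0L || n_neg == 0L)
    stop("undefined-AUC error: both classes must be present")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  best <- NULL
  for (thr in cand) {
    pred <- scores >= thr
    sens <- sum(pred & positives) / n_pos
    spec <- sum(!pred & !positives) / n_neg
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden_j + 1e-12 ||
        (abs(j - best$youden_j) <= 1e-12 && sens > best$sensitivity))
      best <- list(threshold = thr, sensitivity = sens,
                   specificity = spec, youden_j = j)
  }
  best
}

#' One-vs-rest classification report
#'
#' Builds, per class, the TP/TN/FP/FN counts (the mu, mu1, Gamma, Gamma1
#' convention) and the derived metrics: accuracy `(mu + mu1) / N`,
#' precision `mu / (mu + Gamma)`, recall `mu / (mu + Gamma1)` and
#' `F1 = 2PR / (P + R)`. Zero-denominator metrics are reported as `NA`
#' with a warning rather than silently coerced to zero.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param classes class set; defaults to the union of observed labels in
#'   `tissue_classes()` order, then any extras.
#' @return Object of class `classification_report`: `counts` (data.frame
#'   class, mu, mu1, Gamma, Gamma1), `metrics` (data.frame class,
#'   accuracy, precision, recall, f1), `micro_accuracy`.
#' @export
classification_report <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("dimension error: y_true and y_pred differ in length")
  if (is.null(classes)) {
    seen <- unique(c(y_true, y_pred))
    classes <- c(intersect(tissue_classes(), seen),
                 setdiff(seen, tissue_classes()))
  }
  N <- length(y_true)
  counts <- lapply(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    tn <- N - tp - fp - fn
    data.frame(class = cl, mu = tp, mu1 = tn, Gamma = fp, Gamma1 = fn)
  })
  counts <- do.call(rbind, counts)
  safe_div <- function(num, den, what, cl) {
    if (den == 0) {
      warning(what, " undefined for class '", cl, "' (zero denominator)")
      return(NA_real_)
    }
    num / den
  }
  metrics <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    w <- counts[i, ]
    P <- safe_div(w$mu, w$mu + w$Gamma, "precision", w$class)
    R <- safe_div(w$mu, w$mu + w$Gamma1, "recall", w$class)
    f1 <- if (is.na(P) || is.na(R) || (P + R) == 0) {
      if (!is.na(P) && !is.na(R))
        warning("F1 undefined for class '", w$class, "' (P + R = 0)")
      NA_real_
    } else 2 * P * R / (P + R)
    data.frame(class = w$class, accuracy = (w$mu + w$mu1) / N,
               precision = P, recall = R, f1 = f1)
  }))
  structure(list(counts = counts, metrics = metrics,
                 micro_accuracy = mean(y_true == y_pred)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("One-vs-rest classification report\n")
  m <- x$metrics
  m[, -1] <- round(m[, -1], 4)
  print(m, row.names = FALSE)
  cat(sprintf("micro accuracy: %.4f\n", x$micro_accuracy))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' `F1 = 2 P R / (P + R)` — the harmonic mean used in the per-class
#' reports.
#'
#' @param precision,recall scalars in \[0, 1\].
#' @return The F1 score.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Learning-curve summary
#'
#' Tabulates per-epoch training/validation loss and accuracy, reports the
#' epoch with the highest validation accuracy, and flags a plateau (no
#' validation-accuracy improvement beyond 1e-4 over the last `patience`
#' epochs).
#'
#' @param round_log data.frame with columns `epoch`, `train_loss`,
#'   `val_loss`, `train_acc`, `val_acc` (extra columns pass through).
#' @param patience plateau window in epochs.
#' @return List: `table` (the per-epoch data.frame),
#'   `best_val_acc_epoch`, `plateau` (logical).
#' @export
learning_curves <- function(round_log, patience = 10L) {
  if (!is.data.frame(round_log) || nrow(round_log) == 0L)
    stop("'round_log' must be a non-empty data.frame")
  need <- c("epoch", "val_acc")
  if (!all(need %in% names(round_log)))
    stop("'round_log' must contain columns: ", paste(need, collapse = ", "))
  tab <- round_log[order(round_log$epoch), , drop = FALSE]
  best <- tab$epoch[which.max(tab$val_acc)]
  plateau <- FALSE
  if (nrow(tab) > patience) {
    tail_max <- max(tab$val_acc[(nrow(tab) - patience + 1L):nrow(tab)])
    prev_max <- max(tab$val_acc[seq_len(nrow(tab) - patience)])
    plateau <- tail_max <= prev_max + 1e-4
  }
  list(table = tab, best_val_acc_epoch = best, plateau = plateau)
}
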
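test_that("the pooled t-test matches hand computation and conventions", {
  # identical samples: no evidence at all
  r0 <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(mean(r0$confidence_interval), 0, tolerance = 1e-12)

  # group sizes 102 + 102 give the pooled convention's df
  set.seed(1)
  r <- two_sample_ttest(rnorm(102), rnorm(102))
  expect_equal(r$degrees_of_freedom, 202L)

  # closed-form hand computation for a = (1,2,3), b = (2,3,4):
  # sp2 = 1, t = -1 / sqrt(2/3), df = 4
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  rh <- two_sample_ttest(a, b)
  t_hand <- -1 / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(rh$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(rh$p_value, 2 * pt(t_hand, 4), tolerance = 1e-12)
  expect_equal(rh$pooled_sd, 1)
  hw <- qt(0.975, 4) * sqrt(2 / 3)
  expect_equal(rh$confidence_interval, c(-1 - hw, -1 + hw),
               tolerance = 1e-12)
})

test_that("t and p are invariant under positive rescaling of both samples", {
  set.seed(9)
  a <- rnorm(30, 1); b <- rnorm(25)
  r1 <- two_sample_ttest(a, b)
  r2 <- two_sample_ttest(7 * a, 7 * b)
  expect_equal(r1$t_statistic, r2$t_statistic, tolerance = 1e-10)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-10)
  # p and the CI agree about significance at the 5% level
  expect_equal(r1$p_value < 0.05,
               prod(sign(r1$confidence_interval)) > 0)
  # log10 p stays informative for extreme statistics
  rext <- two_sample_ttest(rnorm(200, 10, 0.1), rnorm(200, 0, 0.1))
  expect_lt(rext$log10_p, -100)
  expect_true(is.finite(rext$log10_p))
  expect_error(two_sample_ttest(c(1, 1), c(2, 2)), "degenerate")
})

test_that("rank AUC equals brute-force pair counting", {
  expect_equal(auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(auc(rep(4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)

  # 8-point mixed example with ties
  s <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.9, 0.5, 0.8)
  pos <- c(0, 0, 1, 1, 0, 1, 0, 0)
  expect_equal(auc(s, pos), brute_auc(s, pos))

  # all n <= 12 instances from a seeded family
  set.seed(77)
  for (n in c(4, 8, 12)) {
    for (rep_i in 1:5) {
      s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
      pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(pos) || all(pos)) next
      expect_equal(auc(s, pos), brute_auc(s, pos))
    }
  }
  expect_error(auc(1:3, c(1, 1, 1)), "undefined-AUC")
})

test_that("AUC respects its structural invariants and matches pROC", {
  set.seed(12)
  s <- rnorm(40)
  pos <- s + rnorm(40) > 0
  a <- auc(s, pos)
  expect_equal(auc(exp(s), pos), a, tolerance = 1e-12)   # monotone invariance
  expect_equal(auc(-s, pos), 1 - a, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(pos, s, quiet = TRUE))))
})

test_that("the Youden threshold matches an exhaustive scan", {
  # perfectly separated scores
  bt <- best_threshold(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_equal(bt$youden_j, 1)
  expect_equal(bt$sensitivity, 1)

  # all ties: no threshold helps
  bt0 <- best_threshold(rep(2, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(bt0$youden_j, 0)

  set.seed(3)
  s <- round(rnorm(15), 1)
  pos <- rbinom(15, 1, 0.4)
  if (any(pos == 1) && any(pos == 0)) {
    bt <- best_threshold(s, pos)
    # exhaustive oracle over all midpoints and extremes
    cand <- c(min(s) - 1, sort(unique(s)), max(s) + 1)
    js <- vapply(cand, function(thr) {
      pred <- s >= thr
      sum(pred & pos == 1) / sum(pos == 1) +
        sum(!pred & pos == 0) / sum(pos == 0) - 1
    }, numeric(1))
    expect_equal(bt$youden_j, max(js), tolerance = 1e-12)
  }
})

test_that("classification reports follow the TP/TN/FP/FN formulas", {
  # perfect predictions
  y <- rep(tissue_classes(), times = c(5, 7, 9))
  rp <- classification_report(y, y)
  expect_true(all(rp$metrics[, c("accuracy", "precision", "recall",
                                 "f1")] == 1))
  expect_equal(rp$micro_accuracy, 1)

  # hand-built one-vs-rest confusion: mu=8, mu1=85, Gamma=3, Gamma1=4
  y_true <- c(rep("cancer", 12), rep("fat", 88))
  y_pred <- c(rep("cancer", 8), rep("fat", 4),      # 8 TP, 4 FN
              rep("cancer", 3), rep("fat", 85))     # 3 FP, 85 TN
  rp2 <- classification_report(y_true, y_pred)
  m <- rp2$metrics[rp2$metrics$class == "cancer", ]
  cm <- rp2$counts[rp2$counts$class == "cancer", ]
  expect_equal(unlist(cm[c("mu", "mu1", "Gamma", "Gamma1")], use.names = FALSE),
               c(8, 85, 3, 4))
  expect_equal(m$accuracy, 0.93)
  expect_equal(m$precision, 8 / 11)
  expect_equal(m$recall, 8 / 12)
  expect_equal(m$f1, 2 * (8 / 11) * (8 / 12) / (8 / 11 + 8 / 12))

  # micro accuracy equals the overall fraction correct
  set.seed(5)
  yt <- sample(tissue_classes(), 60, replace = TRUE)
  yp <- sample(tissue_classes(), 60, replace = TRUE)
  expect_equal(classification_report(yt, yp)$micro_accuracy,
               mean(yt == yp))

  # counts per class always partition the observations
  rp3 <- classification_report(yt, yp)
  expect_true(all(rowSums(rp3$counts[, c("mu", "mu1", "Gamma",
                                         "Gamma1")]) == 60))

  # undefined metrics surface as NA with a warning, never silent zeros
  w <- capture_warnings(
    rp4 <- classification_report(c("fat", "fat"), c("fat", "fat"),
                                 classes = c("fat", "cancer")))
  expect_true(all(grepl("undefined", w)) && length(w) == 2L)
  expect_true(is.na(rp4$metrics$precision[
    rp4$metrics$class == "cancer"]))
  expect_error(classification_report(c("fat"), c("fat", "fat")),
               "dimension error")
})

test_that("learning curves locate the best epoch and detect plateaus", {
  mono <- data.frame(epoch = 1:20, val_acc = seq(0.5, 0.9, length.out = 20))
  expect_equal(learning_curves(mono)$best_val_acc_epoch, 20)

  planted <- data.frame(epoch = 1:15,
                        val_acc = c(1:7, 6:-1) / 10 + 0.1)
  planted$val_acc[7] <- 0.95
  expect_equal(learning_curves(planted)$best_val_acc_epoch, 7)

  flat_tail <- data.frame(epoch = 1:30,
                          val_acc = c(seq(0.3, 0.8, length.out = 15),
                                      rep(0.8, 15)))
  expect_true(learning_curves(flat_tail)$plateau)
  expect_false(learning_curves(mono)$plateau)
})
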
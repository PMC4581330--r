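test_that("confusion counts follow the >=-threshold decision rule", {
  s <- c(0.9, 0.8, 0.6, 0.4, 0.2)
  y <- c(1, 0, 1, 0, 0)
  c0 <- confusion(s, y, 0)
  expect_identical(c(c0$TN, c0$FN), c(0L, 0L))
  expect_identical(c0$TP + c0$FP, 5L)
  c1 <- confusion(s, y, 1.0001)
  expect_identical(c(c1$TP, c1$FP), c(0L, 0L))

  # exactly-at-threshold scores count positive
  ct <- confusion(s, y, 0.6)
  expect_identical(ct$TP, 2L)
  expect_identical(ct$FP, 1L)

  s10 <- c(0.95, 0.9, 0.7, 0.65, 0.55, 0.5, 0.35, 0.3, 0.2, 0.1)
  y10 <- c(1, 1, 0, 1, 0, 1, 0, 0, 1, 0)
  cm <- confusion(s10, y10, 0.5)
  # hand-enumerated: positives at >= 0.5 are 0.95,0.9,0.7,0.65,0.55,0.5
  expect_identical(c(cm$TP, cm$FP, cm$TN, cm$FN), c(4L, 2L, 3L, 1L))
  expect_error(confusion(numeric(0), integer(0), 0.5), "empty")
})

test_that("binary measures reproduce hand-computed and printed examples", {
  perfect <- binary_metrics(list(TP = 10, FP = 0, TN = 90, FN = 0))
  expect_equal(unlist(perfect[c("SE", "SP", "Prec", "Acc", "MCC")]),
               c(SE = 1, SP = 1, Prec = 1, Acc = 1, MCC = 1))

  m <- binary_metrics(list(TP = 3, FP = 1, TN = 5, FN = 1))
  expect_equal(m$SE, 0.75)
  expect_equal(m$SP, 5 / 6, tolerance = 1e-10)
  expect_equal(m$Prec, 0.75)
  expect_equal(m$Acc, (0.75 + 5 / 6) / 2, tolerance = 1e-10)
  expect_equal(m$MCC, 14 / 24, tolerance = 1e-10)

  # counts realising SE = 0.582 and SP = 0.982 give balanced accuracy 0.782
  mt <- binary_metrics(list(TP = 582, FN = 418, TN = 982, FP = 18))
  expect_equal(mt$SE, 0.582)
  expect_equal(mt$SP, 0.982)
  expect_equal(mt$Acc, 0.782)

  zero <- binary_metrics(list(TP = 0, FP = 0, TN = 5, FN = 0))
  expect_identical(zero$MCC, 0)
})

test_that("MCC is invariant under swapping both predictions and labels", {
  set.seed(71)
  for (i in 1:20) {
    cnt <- as.list(setNames(sample(0:30, 4, replace = TRUE),
                            c("TP", "FP", "TN", "FN")))
    swapped <- list(TP = cnt$TN, FP = cnt$FN, TN = cnt$TP, FN = cnt$FP)
    expect_equal(binary_metrics(cnt)$MCC, binary_metrics(swapped)$MCC)
  }
})

test_that("ROC handles perfect, random and worked examples", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)

  set.seed(72)
  s <- runif(10000); y <- sample(0:1, 10000, replace = TRUE)
  expect_lt(abs(auc_roc(s, y) - 0.5), 0.02)

  expect_equal(auc_roc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)

  expect_error(auc_roc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("ROC area equals the pair-counting statistic on random instances", {
  set.seed(73)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    s <- round(runif(n), sample(1:3, 1))     # rounding forces ties
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_equal(auc_roc(s, y), auc_pair_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("ROC curve is monotone and reproduces its sweep metrics", {
  set.seed(74)
  s <- runif(200); y <- rbinom(200, 1, 0.3)
  crv <- roc_curve(s, y)
  expect_true(all(diff(crv$points$x) >= 0))
  expect_true(all(diff(crv$points$y) >= 0))
  # each sweep point is the confusion at its threshold
  for (k in sample(seq_len(nrow(crv$points))[-1], 10)) {
    cm <- binary_metrics(confusion(s, y, crv$thresholds[k]))
    expect_equal(crv$points$y[k], cm$SE)
    expect_equal(crv$points$x[k], 1 - cm$SP)
  }
})

test_that("ROC/PR areas agree with an established independent implementation", {
  set.seed(75)
  s <- runif(500); y <- rbinom(500, 1, 0.2)
  expect_equal(auc_roc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("PR curve covers perfect, degenerate and enumerable cases", {
  expect_equal(auc_pr(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)

  # all-tied scores: a single point at full recall, precision = prevalence
  pr <- pr_curve(rep(0.4, 10), c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(pr$points$y[nrow(pr$points)], 0.2)
  expect_equal(pr$points$x[nrow(pr$points)], 1)
  expect_equal(pr$area, 0.2)

  # 4-point case against exhaustive threshold enumeration
  s <- c(0.9, 0.8, 0.4, 0.2); y <- c(1, 0, 1, 0)
  pr4 <- pr_curve(s, y)
  ths <- sort(unique(s), decreasing = TRUE)
  pts <- t(vapply(ths, function(t) {
    cm <- confusion(s, y, t)
    c(recall = cm$TP / 2, precision = cm$TP / (cm$TP + cm$FP))
  }, numeric(2)))
  expect_equal(pr4$points$x[-1], unname(pts[, "recall"]))
  expect_equal(pr4$points$y[-1], unname(pts[, "precision"]))

  expect_error(pr_curve(c(0.2, 0.4), c(0, 0)), "positive")
})

test_that("FPR-anchored threshold selection meets its target on training", {
  s <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  y <- c(1, 0, 1, 0, 0)
  expect_equal(threshold_at_fpr(s, y, 1.0), 0.1)      # everything positive

  t0 <- threshold_at_fpr(s, y, 0)
  expect_gt(t0, max(s[y == 0]))                       # above every negative

  set.seed(76)
  sc <- runif(5000); yy <- rbinom(5000, 1, 0.1)
  sc[yy == 1] <- sc[yy == 1] * 0.5 + 0.5
  thr <- threshold_at_fpr(sc, yy, 0.05)
  neg <- sc[yy == 0]
  realized <- mean(neg >= thr)
  expect_lte(realized, 0.05)
  expect_gt(realized, 0.05 - 1 / length(neg))

  expect_warning(threshold_at_fpr(rep(0.5, 10), c(1, rep(0, 9)), 0.05),
                 "unattainable")
})

test_that("termini trimming removes flanks and short chains", {
  sc <- list(a = runif(25), b = runif(50), c = runif(20))
  lb <- list(a = rbinom(25, 1, 0.5), b = rbinom(50, 1, 0.5),
             c = rbinom(20, 1, 0.5))
  t0 <- trim_termini(sc, lb, 0)
  expect_identical(t0$scores, unlist(unname(sc[c("a", "b", "c")])))

  tr <- trim_termini(sc, lb, 10)
  expect_identical(tr$dropped_ids, "c")               # 20 <= 2*10
  expect_length(tr$scores, 5 + 30)                    # 25-20 and 50-20
  # mask oracle
  mask_scores <- c(sc$a[11:15], sc$b[11:40])
  mask_labels <- c(lb$a[11:15], lb$b[11:40])
  expect_identical(tr$scores, mask_scores)
  expect_identical(tr$labels, mask_labels)
})

test_that("identity-binned AUC uses half-open bins with a closed top bin", {
  set.seed(77)
  sc <- lapply(1:6, function(i) runif(30))
  lb <- lapply(1:6, function(i) rbinom(30, 1, 0.3))
  names(sc) <- names(lb) <- paste0("c", 1:6)
  ident <- setNames(c(0.5, 0.55, 0.5, 0.59, 1.0, 0.05), names(sc))
  tab <- auc_by_identity_bins(sc, lb, ident)
  expect_identical(tab$n_chains[tab$bin_lo == 0.5], 4L)   # 0.5 in [0.5,0.6)
  expect_identical(tab$n_chains[tab$bin_lo == 0.9], 1L)   # 1.0 in top bin
  expect_identical(tab$n_chains[tab$bin_lo == 0.0], 1L)
  expect_identical(sum(tab$n_chains), 6L)

  pooled <- auc_roc(unlist(sc[c(1, 2, 3, 4)]), unlist(lb[c(1, 2, 3, 4)]))
  expect_equal(tab$auc[tab$bin_lo == 0.5], pooled)

  one <- auc_by_identity_bins(sc[1], lb[1], ident[1])
  expect_identical(sum(!is.na(one$auc)), 1L)
})
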
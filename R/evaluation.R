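#' Confusion counts at a decision threshold
#'
#' A residue is called disordered (positive) when its predicted disorder
#' probability is greater than or equal to the threshold.
#'
#' @param scores per-residue disorder probabilities.
#' @param labels binary string or 0/1 vector (1 = disordered).
#' @param threshold decision threshold.
#' @return an object of class `confusion` with counts TP, FP, TN, FN.
#' @export
confusion <- function(scores, labels, threshold) {
  y <- label_vector(labels)
  if (length(scores) == 0L) stop("empty score vector")
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  pos <- scores >= threshold
  structure(list(TP = sum(pos & y == 1L), FP = sum(pos & y == 0L),
                 TN = sum(!pos & y == 0L), FN = sum(!pos & y == 1L)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat("<confusion> TP", x$TP, "FP", x$FP, "TN", x$TN, "FN", x$FN, "\n")
  invisible(x)
}

#' Binary classification measures from confusion counts
#'
#' Sensitivity `SE = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`, precision
#' `Prec = TP/(TP+FP)`, balanced accuracy `Acc = (SE+SP)/2`, and Matthews'
#' correlation coefficient.  Any zero denominator yields 0 for MCC and NA
#' for the affected ratio.
#'
#' @param counts a [confusion()] object (or list with TP/FP/TN/FN).
#' @return list of class `binary_metrics`: SE, SP, Prec, Acc, MCC.
#' @export
binary_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  SE <- ratio(TP, TP + FN)
  SP <- ratio(TN, TN + FP)
  Prec <- ratio(TP, TP + FP)
  Acc <- if (is.na(SE) || is.na(SP)) NA_real_ else (SE + SP) / 2
  den2 <- as.numeric(TP + FP) * (TN + FP) * (TP + FN) * (TN + FN)
  MCC <- if (den2 == 0) 0 else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den2)
  structure(list(SE = SE, SP = SP, Prec = Prec, Acc = Acc, MCC = MCC),
            class = "binary_metrics")
}

#' @export
print.binary_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("SE %.*f  SP %.*f  Prec %.*f  Acc %.*f  MCC %.*f\n",
              digits, x$SE, digits, x$SP, digits, x$Prec, digits, x$Acc,
              digits, x$MCC))
  invisible(x)
}

#' @noRd
sweep_counts <- function(scores, labels) {
  y <- label_vector(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  # collapse tied scores into single threshold steps
  last <- c(s[-1] != s[-length(s)], TRUE)
  cum_tp <- cumsum(yy)[last]
  cum_fp <- cumsum(1 - yy)[last]
  list(tp = cum_tp, fp = cum_fp, P = sum(y == 1L), Nn = sum(y == 0L),
       thresholds = s[last])
}

#' Receiver-operating-characteristic curve and area
#'
#' Threshold sweep over the distinct scores (ties collapsed, giving the
#' Mann-Whitney half-credit convention for tied scores); area by the
#' trapezoidal rule, which equals the pair-counting statistic: the fraction
#' of (positive, negative) pairs ranked correctly, ties counting one half.
#'
#' @param scores per-residue disorder probabilities.
#' @param labels binary labels; both classes must be present.
#' @return object of class `disorder_curve`: `points` data frame (x = FPR,
#'   y = TPR from (0,0) to (1,1)), `kind = "ROC"`, `area`, `thresholds`.
#' @export
roc_curve <- function(scores, labels) {
  sw <- sweep_counts(scores, labels)
  if (sw$P == 0L || sw$Nn == 0L)
    stop("ROC requires both classes to be present")
  x <- c(0, sw$fp / sw$Nn)
  yv <- c(0, sw$tp / sw$P)
  area <- sum(diff(x) * (head(yv, -1) + yv[-1]) / 2)
  structure(list(points = data.frame(x = x, y = yv), kind = "ROC",
                 area = area, thresholds = c(Inf, sw$thresholds)),
            class = "disorder_curve")
}

#' @rdname roc_curve
#' @return `auc_roc`: the area alone.
#' @export
auc_roc <- function(scores, labels) roc_curve(scores, labels)$area

#' Precision-recall curve and area
#'
#' Points at every distinct score threshold, preceded by a (recall 0)
#' anchor at the first threshold's precision; the area is the trapezoid
#' over recall — an approximation, since precision-recall curves are not
#' monotonic and admit several interpolation conventions.
#'
#' @param scores per-residue disorder probabilities.
#' @param labels binary labels; at least one positive required.
#' @return object of class `disorder_curve` with `points` (x = recall,
#'   y = precision), `kind = "PR"`, `area`.
#' @export
pr_curve <- function(scores, labels) {
  sw <- sweep_counts(scores, labels)
  if (sw$P == 0L) stop("PR curve requires at least one positive label")
  recall <- sw$tp / sw$P
  precision <- sw$tp / (sw$tp + sw$fp)
  x <- c(0, recall)
  yv <- c(precision[1], precision)
  area <- sum(diff(x) * (head(yv, -1) + yv[-1]) / 2)
  structure(list(points = data.frame(x = x, y = yv), kind = "PR",
                 area = area, thresholds = c(Inf, sw$thresholds)),
            class = "disorder_curve")
}

#' @rdname pr_curve
#' @export
auc_pr <- function(scores, labels) pr_curve(scores, labels)$area

#' @export
print.disorder_curve <- function(x, ...) {
  cat("<disorder_curve> ", x$kind, ", ", nrow(x$points),
      " points, AUC = ", format(x$area, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.disorder_curve <- function(x, ...) {
  lab <- if (x$kind == "ROC") c("false positive rate", "true positive rate")
         else c("recall", "precision")
  graphics::plot(x$points$x, x$points$y, type = "l", xlab = lab[1],
                 ylab = lab[2], xlim = c(0, 1), ylim = c(0, 1), ...)
  if (x$kind == "ROC") graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Decision threshold anchored at a target false-positive rate
#'
#' The smallest observed score threshold whose training-set FPR does not
#' exceed the target (default 5%).  With untied scores the realized FPR is
#' within one negative count of the target; applying the threshold to other
#' data may realize a nearby, slightly different FPR.
#'
#' @param scores training-set disorder probabilities.
#' @param labels training-set labels; both classes must be present.
#' @param target_fpr maximum tolerated training FPR (default 0.05).
#' @return the threshold.  When even the largest score cannot meet the
#'   target (all scores tied), a value above the maximum score is returned
#'   with a warning.
#' @export
threshold_at_fpr <- function(scores, labels, target_fpr = 0.05) {
  y <- label_vector(labels)
  if (!any(y == 1L) || !any(y == 0L))
    stop("threshold selection requires both classes")
  neg <- scores[y == 0L]
  cand <- sort(unique(scores))
  for (t in cand) {
    if (mean(neg >= t) <= target_fpr) return(t)
  }
  warning("target FPR unattainable at any observed score; ",
          "returning a threshold above the maximum score")
  max(scores) + 1
}

#' Exclude chain termini from evaluation
#'
#' Drops `n_trim` residues from each end of every chain before pooling
#' scores and labels, isolating performance on internal disorder; chains
#' with no more than `2 * n_trim` residues drop out entirely.
#'
#' @param scores named list of per-chain score vectors.
#' @param labels named list of per-chain 0/1 label vectors (same names).
#' @param n_trim residues trimmed per terminus (default 10).
#' @return list: pooled `scores` and `labels`, `kept_ids`, `dropped_ids`.
#' @export
trim_termini <- function(scores, labels, n_trim = 10L) {
  stopifnot(n_trim >= 0L, setequal(names(scores), names(labels)))
  kept <- character(0); dropped <- character(0)
  ps <- numeric(0); pl <- integer(0)
  for (id in names(scores)) {
    n <- length(scores[[id]])
    if (n <= 2L * n_trim) {
      dropped <- c(dropped, id)
      next
    }
    idx <- if (n_trim > 0L) (n_trim + 1L):(n - n_trim) else seq_len(n)
    ps <- c(ps, scores[[id]][idx])
    pl <- c(pl, label_vector(labels[[id]])[idx])
    kept <- c(kept, id)
  }
  list(scores = ps, labels = pl, kept_ids = kept, dropped_ids = dropped)
}

#' AUC binned by identity to the best template
#'
#' Chains are grouped by the sequence identity of their best template into
#' half-open bins of `bin_width` (default 10%), the top bin closed at 1;
#' within each bin the residues are pooled and an ROC AUC computed.  Bins
#' whose pooled residues contain a single class get an NA AUC.
#'
#' @param scores named list of per-chain score vectors.
#' @param labels named list of per-chain 0/1 label vectors.
#' @param best_identity named numeric vector: best-template identity per
#'   chain, in `[0, 1]`.
#' @param bin_width bin width (default 0.1).
#' @return data frame: `bin_lo`, `bin_hi`, `n_chains`, `auc`.
#' @export
auc_by_identity_bins <- function(scores, labels, best_identity,
                                 bin_width = 0.1) {
  stopifnot(all(best_identity >= 0), all(best_identity <= 1))
  nb <- ceiling(1 / bin_width)
  bin <- pmin(floor(best_identity / bin_width), nb - 1L)  # top bin closed
  out <- data.frame(bin_lo = (0:(nb - 1L)) * bin_width,
                    bin_hi = (1:nb) * bin_width,
                    n_chains = 0L, auc = NA_real_)
  for (b in 0:(nb - 1L)) {
    ids <- names(best_identity)[bin == b]
    out$n_chains[b + 1L] <- length(ids)
    if (length(ids) == 0L) next
    s <- unlist(scores[ids], use.names = FALSE)
    l <- unlist(lapply(labels[ids], label_vector), use.names = FALSE)
    if (length(unique(l)) < 2L) next
    out$auc[b + 1L] <- auc_roc(s, l)
  }
  out
}

#' Full evaluation report
#'
#' Metrics at a threshold plus ROC/PR curves and areas over pooled
#' per-chain predictions.
#'
#' @param scores named list of per-chain score vectors (or one numeric
#'   vector).
#' @param labels matching labels.
#' @param threshold decision threshold (default 0.5).
#' @param n_trim optional termini trimming before pooling (default 0).
#' @return list of class `eval_report`: `counts`, `metrics`, `roc`, `pr`,
#'   `auc_roc`, `auc_pr`, `threshold`, `n_residues`, `dropped_ids`.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5,
                                 n_trim = 0L) {
  if (is.list(scores)) {
    pooled <- trim_termini(scores, labels, n_trim)
  } else {
    pooled <- list(scores = scores, labels = label_vector(labels),
                   dropped_ids = character(0))
  }
  cnt <- confusion(pooled$scores, pooled$labels, threshold)
  roc <- roc_curve(pooled$scores, pooled$labels)
  pr <- pr_curve(pooled$scores, pooled$labels)
  structure(list(counts = cnt, metrics = binary_metrics(cnt), roc = roc,
                 pr = pr, auc_roc = roc$area, auc_pr = pr$area,
                 threshold = threshold, n_residues = length(pooled$scores),
                 dropped_ids = pooled$dropped_ids),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$n_residues, " residues at threshold ",
      format(x$threshold, digits = 4), "\n", sep = "")
  print(x$metrics)
  cat(sprintf("AUC-ROC %.4f  AUC-PR %.4f\n", x$auc_roc, x$auc_pr))
  if (length(x$dropped_ids))
    cat("chains dropped by termini trimming:",
        paste(x$dropped_ids, collapse = ", "), "\n")
  invisible(x)
}
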
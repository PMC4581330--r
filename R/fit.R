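#' Fit a short-disorder predictor
#'
#' The package's front door: trains the two-stage bidirectional recurrent
#' predictor on an annotated corpus and returns a classed fit.  With
#' `folds` supplied (or `k`), training is cross-validated — one ensemble of
#' the best checkpoints per fold, pooled out-of-fold predictions for every
#' chain, and a merged final ensemble; otherwise a single model is trained
#' against an explicit validation set.  The decision threshold stored in
#' the fit is anchored at a target false-positive rate on the fit's
#' held-out predictions.
#'
#' @param corpus named list of annotated [protein_record()]s.
#' @param variant input-encoding variant: `"MSA"`, `"MSA-SS-SA"`,
#'   `"MSA-Templ"` or `"MSA-SS-SA-Templ"`.
#' @param config a [train_config()].
#' @param folds a [make_folds()] assignment; if `NULL` and
#'   `validation` is `NULL`, folds are created with `k` folds under the
#'   config seed.
#' @param k number of folds when `folds` is `NULL` (default 5).
#' @param validation explicit validation records for a single
#'   (non-cross-validated) fit.
#' @param target_fpr false-positive rate anchoring the stored threshold
#'   (default 0.05).
#' @param geometry a [filter_geometry()].
#' @param state_width,hidden_width,span stage sizes, see [brnn_stage()].
#' @param verbose progress messages?
#' @return an object of class `disbrnn` with components `ensemble` (merged
#'   final predictor), `fold_ensembles`, `scores` / `labels` (held-out
#'   per-chain predictions), `threshold`, `variant`, `histories`, `folds`.
#' @seealso [predict.disbrnn()], [summary.disbrnn()]
#' @export
disbrnn <- function(corpus, variant = "MSA", config = train_config(),
                    folds = NULL, k = 5L, validation = NULL,
                    target_fpr = 0.05, geometry = filter_geometry(),
                    state_width = 11L, hidden_width = 11L, span = 2L,
                    verbose = FALSE) {
  variant <- match.arg(variant, VARIANTS)
  if (is.null(validation)) {
    if (is.null(folds)) folds <- make_folds(corpus, k, seed = config$seed)
    cv <- crossvalidate(corpus, folds, variant, config,
                        geometry = geometry, state_width = state_width,
                        hidden_width = hidden_width, span = span,
                        verbose = verbose)
    scores <- cv$scores; labels <- cv$labels
    fold_ensembles <- cv$ensembles
    ensemble <- merge_ensembles(cv$ensembles)
    histories <- cv$histories
  } else {
    fit <- train_model(corpus, variant, config, validation = validation,
                       geometry = geometry, state_width = state_width,
                       hidden_width = hidden_width, span = span,
                       verbose = verbose)
    scores <- lapply(validation, function(r)
      ensemble_predict(fit$ensemble, assemble_inputs(variant, r))[, 2L])
    names(scores) <- vapply(validation, `[[`, "", "id")
    labels <- lapply(validation, function(r) label_vector(r$labels))
    names(labels) <- names(scores)
    fold_ensembles <- list(fit$ensemble)
    ensemble <- fit$ensemble
    histories <- list(fit$history)
    folds <- NULL
  }
  pooled_s <- unlist(scores, use.names = FALSE)
  pooled_l <- unlist(labels, use.names = FALSE)
  threshold <- threshold_at_fpr(pooled_s, pooled_l, target_fpr)
  structure(list(ensemble = ensemble, fold_ensembles = fold_ensembles,
                 scores = scores, labels = labels, threshold = threshold,
                 target_fpr = target_fpr, variant = variant,
                 histories = histories, folds = folds, config = config),
            class = "disbrnn")
}

#' @export
print.disbrnn <- function(x, ...) {
  cat("Two-stage bidirectional recurrent disorder predictor\n")
  cat("  variant: ", x$variant, "  (input width ",
      x$ensemble$members[[1]]$stage1$d, ")\n", sep = "")
  cat("  ensemble: ", length(x$ensemble$members), " member(s) from ",
      length(x$fold_ensembles), " fold(s)\n", sep = "")
  cat("  decision threshold: ", format(x$threshold, digits = 4),
      " (anchored at ", format(100 * x$target_fpr), "% FPR)\n", sep = "")
  cat("  held-out chains: ", length(x$scores), "\n", sep = "")
  invisible(x)
}

#' Summarise a disorder-predictor fit
#'
#' Evaluates the held-out (out-of-fold) predictions at the stored
#' threshold: confusion counts, sensitivity/specificity/precision/balanced
#' accuracy/MCC, and ROC / precision-recall areas.
#'
#' @param object a [disbrnn()] fit.
#' @param threshold override the stored threshold.
#' @param ... unused.
#' @return an `eval_report` (see [evaluate_predictions()]).
#' @export
summary.disbrnn <- function(object, threshold = object$threshold, ...) {
  evaluate_predictions(object$scores, object$labels, threshold = threshold)
}

#' Predict disorder probabilities for new chains
#'
#' @param object a [disbrnn()] fit.
#' @param newdata a [protein_record()] or list of them, annotated with the
#'   components the fit's variant requires (missing template hits are
#'   allowed: the template block is left blank).
#' @param type `"prob"` for per-residue disorder probabilities, `"class"`
#'   for binary calls at the stored threshold.
#' @param ... unused.
#' @return named list of per-residue numeric (or integer) vectors.
#' @export
predict.disbrnn <- function(object, newdata, type = c("prob", "class"),
                            ...) {
  type <- match.arg(type)
  if (inherits(newdata, "protein_record")) newdata <- list(newdata)
  out <- lapply(newdata, function(r) {
    p <- ensemble_predict(object$ensemble,
                          assemble_inputs(object$variant, r))[, 2L]
    if (type == "class") as.integer(p >= object$threshold) else p
  })
  names(out) <- vapply(newdata, `[[`, "", "id")
  out
}

#' @export
fitted.disbrnn <- function(object, ...) object$scores

#' @export
residuals.disbrnn <- function(object, ...) {
  mapply(function(s, l) label_vector(l) - s, object$scores, object$labels,
         SIMPLIFY = FALSE)
}

#' @export
coef.disbrnn <- function(object, member = 1L, ...) {
  flatten_params(object$ensemble$members[[member]])
}

#' Diagnostic plots for a disorder-predictor fit
#'
#' @param x a [disbrnn()] fit.
#' @param which `"roc"`, `"pr"` or `"history"`.
#' @param ... forwarded to the underlying plot.
#' @export
plot.disbrnn <- function(x, which = c("roc", "pr", "history"), ...) {
  which <- match.arg(which)
  if (which == "history") {
    h <- x$histories[[1]]
    graphics::plot(h$epoch, h$val_loss, type = "l", xlab = "epoch",
                   ylab = "cross-entropy", ...)
    graphics::lines(h$epoch, h$train_loss, lty = 2)
    graphics::legend("topright", legend = c("validation", "training"),
                     lty = c(1, 2), bty = "n")
    return(invisible(x))
  }
  s <- unlist(x$scores, use.names = FALSE)
  l <- unlist(x$labels, use.names = FALSE)
  crv <- if (which == "roc") roc_curve(s, l) else pr_curve(s, l)
  plot(crv, ...)
  invisible(x)
}
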
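#' Training schedule configuration
#'
#' The full-scale schedule: 2000 epochs, the shuffled training set cut into
#' 500 contiguous batch blocks per epoch (so 500 weight updates per epoch),
#' plain gradient descent with no momentum or weight decay, the learning
#' rate halved whenever the validation error has not improved for
#' `lr_halving_patience` epochs, and the `n_best_checkpoints` networks with
#' the best validation error retained for ensembling.  Tests and the
#' bundled synthetic experiments use scaled-down schedules (e.g. 100 epochs
#' x 50 blocks).
#'
#' @param epochs training epochs (default 2000).
#' @param batches_per_epoch batch blocks, i.e. weight updates per epoch
#'   (default 500).
#' @param learning_rate initial per-residue learning rate: each update is
#'   `lr * gradient / residues-in-block` (default 0.05).
#' @param lr_halving_patience epochs without validation improvement before
#'   the rate is halved (default 500).
#' @param n_best_checkpoints checkpoints kept for the ensemble (default 9).
#' @param seed RNG seed covering initialisation and shuffling.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 2000L, batches_per_epoch = 500L,
                         learning_rate = 0.05, lr_halving_patience = 500L,
                         n_best_checkpoints = 9L, seed = 1L) {
  stopifnot(epochs >= 1L, batches_per_epoch >= 1L, learning_rate > 0,
            lr_halving_patience >= 1L, n_best_checkpoints >= 1L)
  structure(list(epochs = as.integer(epochs),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 learning_rate = learning_rate,
                 lr_halving_patience = as.integer(lr_halving_patience),
                 n_best_checkpoints = as.integer(n_best_checkpoints),
                 seed = as.integer(seed)), class = "train_config")
}

#' Mean per-residue cross-entropy
#'
#' `-sum(log p[label]) / N` with probabilities floored at 1e-12; uniform
#' two-class predictions score `log 2`.
#'
#' @param pred N x m matrix of class probabilities (rows normalised).
#' @param labels binary string or 0/1 vector of length N.
#' @return nonnegative scalar.
#' @export
cross_entropy_loss <- function(pred, labels) {
  y <- label_vector(labels)
  pred <- as.matrix(pred)
  if (length(y) != nrow(pred)) stop("label length != prediction rows")
  p <- pmax(pred[cbind(seq_along(y), y + 1L)], 1e-12)
  -mean(log(p))
}

#' @noRd
prepare_xy <- function(records, variant) {
  list(X = lapply(records, function(r) assemble_inputs(variant, r)),
       y = lapply(records, function(r) label_vector(r$labels)))
}

#' Train one two-stage model with checkpoint ensembling
#'
#' Gradient-descent training of the joint two-stage cross-entropy by
#' backpropagation through structure.  Each epoch the corpus is reshuffled
#' and cut into `batches_per_epoch` contiguous blocks; gradients are summed
#' over all residues of a block and applied once per block.  After every
#' epoch the validation cross-entropy is recorded; it drives both
#' learning-rate halving and the ranking of retained checkpoints.  The
#' returned ensemble averages the `n_best_checkpoints` best checkpoints.
#'
#' @param corpus list of annotated [protein_record()]s to train on.
#' @param variant input-encoding variant (see [assemble_inputs()]).
#' @param config a [train_config()].
#' @param validation non-empty list of held-out records used for checkpoint
#'   ranking and the halving schedule.
#' @param geometry a [filter_geometry()].
#' @param state_width,hidden_width,span stage sizes, see [brnn_stage()].
#' @param verbose emit a message per epoch?
#' @return list: `ensemble` (an [ensemble_model()]), `history` (data frame
#'   with epoch, train_loss, val_loss, lr), `variant`, `model` (the final
#'   epoch's parameters).
#' @export
train_model <- function(corpus, variant = "MSA", config = train_config(),
                        validation, geometry = filter_geometry(),
                        state_width = 11L, hidden_width = 11L, span = 2L,
                        verbose = FALSE) {
  variant <- match.arg(variant, VARIANTS)
  if (length(corpus) == 0L) stop("empty training corpus")
  if (missing(validation) || length(validation) == 0L)
    stop("validation set must be non-empty (checkpoint ranking undefined)")
  train_ids <- vapply(corpus, `[[`, "", "id")
  val_ids <- vapply(validation, `[[`, "", "id")
  if (length(intersect(train_ids, val_ids)) > 0L)
    stop("validation records overlap the training corpus")

  tr <- prepare_xy(corpus, variant)
  va <- prepare_xy(validation, variant)
  d <- ncol(tr$X[[1]])

  set.seed(config$seed)
  model <- two_stage_model(d, geometry, state_width, hidden_width, span)

  n <- length(corpus)
  nblocks <- min(config$batches_per_epoch, n)
  lr <- config$learning_rate
  best_val <- Inf
  since_improve <- 0L
  checkpoints <- list()   # each: list(val, epoch, model)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    block_of <- sort(rep_len(seq_len(nblocks), n))
    epoch_loss <- 0; epoch_res <- 0L
    for (b in seq_len(nblocks)) {
      idx <- perm[block_of == b]
      acc <- NULL; nres <- 0L
      for (i in idx) {
        g <- cpp_two_stage_grad(unclass(model$stage1), unclass(model$stage2),
                                model$geometry$w, model$geometry$p,
                                tr$X[[i]], tr$y[[i]])
        acc <- accumulate_grads(acc, g)
        nres <- nres + g$n
        epoch_loss <- epoch_loss + g$loss_final
      }
      model <- apply_update(model, acc, -lr / nres)
      epoch_res <- epoch_res + nres
    }
    val_loss <- mean(vapply(seq_along(va$X), function(i)
      cross_entropy_loss(two_stage_predict(model, va$X[[i]]), va$y[[i]]),
      numeric(1)))
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = epoch_loss / epoch_res,
                                   val_loss = val_loss, lr = lr))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f lr %.4g",
                      epoch, epoch_loss / epoch_res, val_loss, lr))
    if (val_loss < best_val) {
      best_val <- val_loss
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= config$lr_halving_patience) {
        lr <- lr / 2
        since_improve <- 0L
      }
    }
    checkpoints <- c(checkpoints,
                     list(list(val = val_loss, epoch = epoch, model = model)))
    vals <- vapply(checkpoints, `[[`, numeric(1), "val")
    keep <- order(vals)[seq_len(min(length(vals), config$n_best_checkpoints))]
    checkpoints <- checkpoints[sort(keep)]
  }

  members <- lapply(checkpoints, `[[`, "model")
  prov <- data.frame(
    epoch = vapply(checkpoints, `[[`, numeric(1), "epoch"),
    val_loss = vapply(checkpoints, `[[`, numeric(1), "val"))
  list(ensemble = ensemble_model(members, prov), history = hist,
       variant = variant, model = model)
}

#' Ensemble of two-stage models
#'
#' @param members list of [two_stage_model()]s with identical geometry and
#'   class count.
#' @param provenance optional data frame recording each member's origin
#'   (fold, checkpoint epoch, validation loss).
#' @return an object of class `ensemble_model`.
#' @export
ensemble_model <- function(members, provenance = NULL) {
  if (length(members) < 1L) stop("ensemble needs at least one member")
  g1 <- members[[1]]$geometry
  ok <- vapply(members, function(mm) {
    identical(mm$geometry$w, g1$w) && identical(mm$geometry$p, g1$p) &&
      identical(mm$geometry$m, g1$m) &&
      identical(mm$stage1$d, members[[1]]$stage1$d)
  }, logical(1))
  if (!all(ok)) stop("ensemble members differ in geometry or input width")
  structure(list(members = members, provenance = provenance,
                 geometry = g1), class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> ", length(x$members), " member(s), input width ",
      x$members[[1]]$stage1$d, ", filter w=", x$geometry$w, " p=",
      x$geometry$p, "\n", sep = "")
  invisible(x)
}

#' Ensemble-averaged prediction
#'
#' @param ensemble an [ensemble_model()].
#' @param inputs N x d input matrix.
#' @return N x m matrix: the unweighted mean of the members' probability
#'   outputs (rows sum to 1).
#' @export
ensemble_predict <- function(ensemble, inputs) {
  out <- NULL
  for (mm in ensemble$members) {
    p <- two_stage_predict(mm, inputs)
    out <- if (is.null(out)) p else out + p
  }
  out / length(ensemble$members)
}

#' Five-fold cross-validated training
#'
#' For each fold, trains on the remaining folds (an eighth of those chains
#' is carved out, deterministically under the config seed, as the
#' validation set driving checkpointing) and predicts the held-out fold, so
#' the pooled predictions cover every chain exactly once and are never made
#' by a model that saw the chain.
#'
#' @param corpus named list of annotated [protein_record()]s.
#' @param folds a [make_folds()] assignment covering exactly the corpus.
#' @param variant input-encoding variant.
#' @param config a [train_config()].
#' @param ... stage sizes and geometry forwarded to [train_model()].
#' @param verbose emit progress messages?
#' @return list: `ensembles` (one [ensemble_model()] per fold), `scores`
#'   (per-chain out-of-fold disorder-probability vectors), `labels`
#'   (per-chain 0/1 vectors), `fold` (per-chain fold index), `histories`.
#' @export
crossvalidate <- function(corpus, folds, variant = "MSA",
                          config = train_config(), ..., verbose = FALSE) {
  ids <- vapply(corpus, `[[`, "", "id")
  if (!setequal(ids, names(folds)) || length(ids) != length(folds))
    stop("fold assignment does not match the corpus")
  k <- attr(folds, "k")
  ensembles <- vector("list", k)
  histories <- vector("list", k)
  scores <- list(); labels <- list(); foldmap <- integer(0)
  for (f in 0:(k - 1L)) {
    test_ids <- names(folds)[folds == f]
    pool_ids <- setdiff(ids, test_ids)
    set.seed(config$seed + f)
    val_ids <- sample(pool_ids, max(1L, length(pool_ids) %/% 8L))
    train_ids <- setdiff(pool_ids, val_ids)
    if (verbose)
      message("fold ", f, ": ", length(train_ids), " train / ",
              length(val_ids), " val / ", length(test_ids), " test chains")
    fit <- train_model(corpus[train_ids], variant, config,
                       validation = corpus[val_ids], ...,
                       verbose = FALSE)
    ensembles[[f + 1L]] <- fit$ensemble
    histories[[f + 1L]] <- fit$history
    for (id in test_ids) {
      X <- assemble_inputs(variant, corpus[[id]])
      scores[[id]] <- ensemble_predict(fit$ensemble, X)[, 2L]
      labels[[id]] <- label_vector(corpus[[id]]$labels)
      foldmap[id] <- f
    }
  }
  list(ensembles = ensembles, scores = scores, labels = labels,
       fold = foldmap, histories = histories, variant = variant)
}

#' Merge per-fold ensembles into one final predictor
#'
#' @param ensembles list of [ensemble_model()]s (e.g. the five per-fold
#'   ensembles; nine checkpoints each gives 45 members in total).
#' @return a single [ensemble_model()] containing every member.
#' @export
merge_ensembles <- function(ensembles) {
  members <- do.call(c, lapply(ensembles, `[[`, "members"))
  prov <- do.call(rbind, lapply(seq_along(ensembles), function(i) {
    p <- ensembles[[i]]$provenance
    if (is.null(p)) return(NULL)
    cbind(fold = i - 1L, p)
  }))
  ensemble_model(members, prov)
}
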
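# Shared fixture builders.  Everything is generated in code; no files.

# Short-chain generator config keeping unit tests fast.
tiny_config <- function(n_chains = 8L, seed = 42L, ...) {
  synthetic_config(n_chains = n_chains, length_range = c(60L, 100L),
                   msa_depth = 10L, seed = seed, ...)
}

tiny_corpus <- function(n_chains = 8L, seed = 42L, ...) {
  generate_corpus(tiny_config(n_chains, seed, ...))
}

# A record built by hand from an explicit label string.
labelled_record <- function(labels, id = "rec1", resolution = 1.5) {
  set.seed(nchar(labels))
  n <- nchar(labels)
  seq <- paste(sample(c("A", "G", "L", "S", "P", "K"), n, replace = TRUE),
               collapse = "")
  protein_record(id = id, sequence = seq, labels = labels,
                 resolution = resolution)
}

# Fixed-size two-stage model with all parameters zeroed.
zeroed_stage <- function(stage) {
  for (pn in c("WF1", "WF2", "WB1", "WB2", "WO1", "WO2"))
    stage[[pn]][] <- 0
  for (pn in c("bF1", "bF2", "bB1", "bB2", "bO1", "bO2"))
    stage[[pn]][] <- 0
  stage
}

zeroed_model <- function(model) {
  model$stage1 <- zeroed_stage(model$stage1)
  model$stage2 <- zeroed_stage(model$stage2)
  model
}

# Plain-R reference for the Eq.-1-style filter inputs: exhaustive loops.
filter_inputs_oracle <- function(P, w, p) {
  n <- nrow(P); m <- ncol(P)
  out <- matrix(0, n, m * (2 * p + 2))
  for (j in seq_len(n)) {
    out[j, 1:m] <- P[j, ]
    for (f in -p:p) {
      kf <- j + f * (2 * w + 1)
      lo <- max(1, kf - w); hi <- min(n, kf + w)
      if (lo > hi) next
      blk <- m * (1 + f + p) + 1:m
      out[j, blk] <- colMeans(P[lo:hi, , drop = FALSE])
    }
  }
  out
}

# Pair-counting AUC oracle (Mann-Whitney with half credit for ties).
auc_pair_oracle <- function(scores, labels) {
  y <- as.integer(labels)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Per-residue CE oracle by direct summation.
ce_oracle <- function(pred, y) {
  s <- 0
  for (j in seq_along(y)) s <- s - log(max(pred[j, y[j] + 1], 1e-12))
  s / length(y)
}
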
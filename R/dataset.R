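#' Select chains carrying short disordered regions
#'
#' Applies the corpus selection rules: chain length strictly greater than
#' `min_len`; at least one maximal disordered run no shorter than the lower
#' run bound; no maximal run longer than the upper bound (a chain that also
#' carries a long run is rejected — the corpus targets short disorder); and,
#' where a resolution is recorded, resolution strictly below
#' `max_resolution` Angstrom.
#'
#' @param records list of labelled [protein_record()]s.
#' @param min_len minimum exclusive chain length (default 50).
#' @param run_range admissible range of maximal disordered run lengths
#'   (default 3-30).
#' @param max_resolution exclusive resolution cut in Angstrom (default 2.0).
#' @return the retained records, in input order.
#' @export
filter_chains <- function(records, min_len = 50L, run_range = c(3L, 30L),
                          max_resolution = 2.0) {
  keep <- vapply(records, function(r) {
    if (is.null(r$labels)) stop("record '", r$id, "' has no disorder labels")
    if (nchar(r$sequence) <= min_len) return(FALSE)
    runs <- disorder_runs(r$labels)
    if (!any(runs >= run_range[1])) return(FALSE)
    if (any(runs > run_range[2])) return(FALSE)
    if (!is.null(r$resolution) && !is.na(r$resolution) &&
        r$resolution >= max_resolution) return(FALSE)
    TRUE
  }, logical(1))
  records[keep]
}

#' Remove redundant chains above a mutual-identity threshold
#'
#' Greedy homology reduction: while any retained pair exceeds the identity
#' threshold, the conflicted record of lesser quality is removed.  Quality
#' is crystallographic resolution where available (smaller is better; a
#' missing resolution ranks below any measured one), then chain length
#' (longer is better), then the lexicographically earlier id.
#'
#' @param records list of [protein_record()]s.
#' @param pairwise_identity symmetric numeric matrix of proportions with
#'   unit diagonal, dimnames = record ids.  See
#'   [pairwise_identity_matrix()] for a built-in fallback.
#' @param threshold maximum tolerated mutual identity (default 0.30).
#' @return the retained records; no retained pair exceeds `threshold`.
#' @export
redundancy_reduce <- function(records, pairwise_identity, threshold = 0.30) {
  ids <- vapply(records, `[[`, "", "id")
  M <- pairwise_identity
  if (is.null(dimnames(M)) || !all(ids %in% rownames(M)) ||
      !all(ids %in% colnames(M)))
    stop("pairwise identity matrix is missing entries for some record ids")
  M <- M[ids, ids, drop = FALSE]
  if (anyNA(M)) stop("pairwise identity matrix contains missing entries")
  if (max(abs(M - t(M))) > 1e-12) stop("pairwise identity matrix not symmetric")
  if (max(abs(diag(M) - 1)) > 1e-12) stop("pairwise identity diagonal must be 1")

  quality_rank <- function(r) {
    res <- if (is.null(r$resolution) || is.na(r$resolution)) Inf else r$resolution
    c(res = res, neg_len = -nchar(r$sequence))
  }
  alive <- seq_along(records)
  repeat {
    Ma <- M[alive, alive, drop = FALSE]
    conf <- which(Ma > threshold & upper.tri(Ma), arr.ind = TRUE)
    if (nrow(conf) == 0L) break
    involved <- alive[unique(as.vector(conf))]
    q <- t(vapply(records[involved], quality_rank, numeric(2)))
    ord <- order(q[, "res"], q[, "neg_len"],
                 vapply(records[involved], `[[`, "", "id"),
                 decreasing = TRUE)
    # worst quality first after decreasing order on (res, -len, id)
    alive <- setdiff(alive, involved[ord[1]])
  }
  records[alive]
}

#' Pairwise sequence-identity matrix (alignment fallback)
#'
#' A simple global-alignment identity for when no external identity matrix
#' is supplied: unit match score, zero mismatch, mild affine gap penalty,
#' identity = matched identical positions divided by the shorter sequence
#' length (gaps ignored).
#'
#' @param records list of [protein_record()]s.
#' @return symmetric matrix of proportions with unit diagonal.
#' @export
pairwise_identity_matrix <- function(records) {
  ids <- vapply(records, `[[`, "", "id")
  seqs <- vapply(records, `[[`, "", "sequence")
  n <- length(records)
  M <- diag(1, n)
  dimnames(M) <- list(ids, ids)
  if (n < 2L) return(M)
  sub <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  diag(sub) <- 1
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- Biostrings::pairwiseAlignment(
        seqs[i], seqs[j], type = "global", substitutionMatrix = sub,
        gapOpening = 1, gapExtension = 0.5)
      M[i, j] <- M[j, i] <-
        Biostrings::nmatch(aln) / min(nchar(seqs[i]), nchar(seqs[j]))
    }
  }
  M
}

#' Split a corpus into cross-validation folds
#'
#' Chains are assigned uniformly at random (under `seed`) to `k` folds whose
#' sizes differ by at most one.  The residue-count imbalance across folds is
#' reported in a message.
#'
#' @param records list of [protein_record()]s.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the assignment.
#' @return a named integer vector (class `fold_split`) mapping record id to
#'   a fold index in `0..k-1`.
#' @export
make_folds <- function(records, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  n <- length(records)
  if (n < k) stop("fewer records (", n, ") than folds (", k, ")")
  ids <- vapply(records, `[[`, "", "id")
  set.seed(seed)
  assignment <- rep_len(0:(k - 1L), n)[order(sample.int(n))]
  names(assignment) <- ids
  nres <- vapply(records, function(r) nchar(r$sequence), integer(1))
  per_fold <- vapply(0:(k - 1L), function(f) sum(nres[assignment == f]),
                     numeric(1))
  message("fold residue counts: ", paste(per_fold, collapse = ", "),
          " (spread ", max(per_fold) - min(per_fold), ")")
  structure(assignment, class = "fold_split", k = k)
}

#' @export
print.fold_split <- function(x, ...) {
  k <- attr(x, "k")
  cat("<fold_split> ", length(x), " chains in ", k, " folds: ",
      paste(tabulate(unclass(x) + 1L, k), collapse = "/"), "\n", sep = "")
  invisible(x)
}
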
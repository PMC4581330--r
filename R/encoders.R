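#' Amino-acid frequency profile of a multiple sequence alignment
#'
#' Per query position, the frequencies of the 20 amino acids plus the gap
#' frequency over the corresponding alignment column, the query row
#' included.  Columns where the query itself carries a gap are dropped
#' (query coordinates define positions).  Nonstandard letters (X, B, Z, U,
#' ...) are spread uniformly over the 20 amino-acid channels.
#'
#' @param msa character vector of equal-length aligned rows; row 1 is the
#'   query.
#' @return N x 21 matrix of proportions; each row sums to 1.  Columns are
#'   the 20 amino acids in alphabetical one-letter order, then the gap.
#' @export
build_profile <- function(msa) {
  if (length(msa) < 1L) stop("MSA must contain at least one row")
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L) stop("MSA rows have unequal lengths")
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  m <- m[, m[1, ] != "-", drop = FALSE]          # query coordinates
  depth <- nrow(m)
  n <- ncol(m)
  code <- match(m, c(AA20, "-"))                 # 21 channels, NA = nonstandard
  dim(code) <- dim(m)
  prof <- matrix(0, nrow = n, ncol = 21L,
                 dimnames = list(NULL, c(AA20, "gap")))
  for (k in 1:21) prof[, k] <- colSums(code == k, na.rm = TRUE)
  nonstd <- colSums(is.na(code))
  if (any(nonstd > 0)) prof[, 1:20] <- prof[, 1:20] + nonstd / 20
  prof / depth
}

#' One-hot encoding of a 3-class secondary-structure string
#'
#' @param ss string over `H` (helix), `E` (strand), `C` (coil).
#' @return N x 3 one-hot matrix with columns helix, strand, coil.
#' @export
encode_ss <- function(ss) {
  one_hot(ss, SS_ALPHABET, "secondary structure")
}

#' One-hot encoding of a 4-class solvent-accessibility string
#'
#' @param sa string over `B` (completely buried), `b` (partly buried),
#'   `e` (partly exposed), `E` (exposed).
#' @return N x 4 one-hot matrix in that class order.
#' @export
encode_sa <- function(sa) {
  one_hot(sa, SA_ALPHABET, "solvent accessibility")
}

#' @noRd
one_hot <- function(s, alphabet, what) {
  cc <- chars(s)
  idx <- match(cc, alphabet)
  if (anyNA(idx))
    stop("invalid ", what, " symbol(s): ",
         paste(unique(cc[is.na(idx)]), collapse = ", "))
  out <- matrix(0, nrow = length(idx), ncol = length(alphabet),
                dimnames = list(NULL, alphabet))
  out[cbind(seq_along(idx), idx)] <- 1
  out
}

#' Cubed-identity-weighted template encoding
#'
#' Transfers order/disorder annotations from template hits into three
#' per-residue channels.  At a position j covered by at least one hit, the
#' first two channels are the identity-cubed weighted mean of the hits'
#' one-hot states (ordered = (1,0), disordered = (0,1)) and the third is a
#' significance score, the identity-weighted mean identity
#' `sum(I^4) / sum(I^3)` over the covering hits.  Cubing the identity makes
#' a 90%-identity template weigh about two orders of magnitude more than a
#' 20% one.  Positions no hit covers are left blank (all-zero), as is the
#' whole matrix when there are no hits.
#'
#' @param hits list of [template_hit()]s with identities in (0, 1] and
#'   annotations of length `n`.  Near-self hits are normally removed
#'   upstream with [filter_hits_by_identity()]; [assemble_inputs()] does so
#'   automatically.
#' @param n query length.
#' @return N x 3 matrix: weighted ordered component, weighted disordered
#'   component, score.
#' @export
encode_templates <- function(hits, n) {
  out <- matrix(0, nrow = n, ncol = 3L,
                dimnames = list(NULL, c("ordered", "disordered", "score")))
  if (length(hits) == 0L) return(out)
  w3 <- numeric(n); w4 <- numeric(n); word <- numeric(n)
  for (h in hits) {
    if (h$identity <= 0 || h$identity > 1)
      stop("template '", h$template_id, "' identity outside (0, 1]")
    ann <- chars(h$annotation)
    if (length(ann) != n)
      stop("template '", h$template_id, "' annotation length != query length")
    if (any(!ann %in% c("O", "D", "-")))
      stop("template '", h$template_id,
           "' annotation contains symbols outside {O, D, -}")
    cov <- ann != "-"
    w3[cov] <- w3[cov] + h$identity^3
    w4[cov] <- w4[cov] + h$identity^4
    word[cov & ann == "O"] <- word[cov & ann == "O"] + h$identity^3
  }
  covered <- w3 > 0
  out[covered, 1] <- word[covered] / w3[covered]
  out[covered, 2] <- 1 - out[covered, 1]
  out[covered, 3] <- w4[covered] / w3[covered]
  out
}

#' Drop template hits above an identity cap
#'
#' Hits whose sequence identity to the query exceeds the cap are removed
#' (strictly "exceeding": a hit at exactly the cap is retained).  The
#' default 0.95 removes near-self hits; a 0.50 cap reproduces the
#' low-homology evaluation protocol.
#'
#' @param hits list of [template_hit()]s.
#' @param max_identity retention cap (default 0.95).
#' @return the retained hits, in input order.
#' @export
filter_hits_by_identity <- function(hits, max_identity = 0.95) {
  if (length(hits) == 0L) return(hits)
  hits[vapply(hits, function(h) h$identity <= max_identity, logical(1))]
}

#' Assemble the per-residue input matrix for a system variant
#'
#' Concatenates, in order: the 21-channel evolutionary profile, the 3-class
#' secondary-structure one-hot and 4-class accessibility one-hot (for the
#' `-SS-SA` variants), and the 3-channel template encoding (for the
#' `-Templ` variants).  Total widths per variant: MSA 21, MSA-SS-SA 28,
#' MSA-Templ 24, MSA-SS-SA-Templ 31.
#'
#' @param variant one of `"MSA"`, `"MSA-SS-SA"`, `"MSA-Templ"`,
#'   `"MSA-SS-SA-Templ"`.
#' @param record a [protein_record()] carrying the components the variant
#'   requires; missing template hits yield a blank (all-zero) template
#'   block, but a missing MSA or SS/SA string is an error.
#' @param max_template_identity identity cap applied to hits before
#'   encoding (default 0.95).
#' @return N x d numeric matrix, d per the variant.
#' @export
assemble_inputs <- function(variant, record, max_template_identity = 0.95) {
  variant <- match.arg(variant, VARIANTS)
  n <- nchar(record$sequence)
  if (is.null(record$msa))
    stop("record '", record$id, "' lacks the required component: msa")
  blocks <- list(build_profile(record$msa))
  if (nrow(blocks[[1]]) != n)
    stop("record '", record$id, "': MSA query length != sequence length")
  if (variant %in% c("MSA-SS-SA", "MSA-SS-SA-Templ")) {
    for (comp in c("ss", "sa")) {
      if (is.null(record[[comp]]))
        stop("record '", record$id, "' lacks the required component: ", comp)
      if (nchar(record[[comp]]) != n)
        stop("record '", record$id, "': ", comp, " length != sequence length")
    }
    blocks <- c(blocks, list(encode_ss(record$ss)), list(encode_sa(record$sa)))
  }
  if (variant %in% c("MSA-Templ", "MSA-SS-SA-Templ")) {
    hits <- filter_hits_by_identity(record$template_hits %||% list(),
                                    max_template_identity)
    blocks <- c(blocks, list(encode_templates(hits, n)))
  }
  do.call(cbind, blocks)
}

#' Input width of a system variant
#'
#' @param variant system variant name.
#' @return integer: 21, 28, 24 or 31.
#' @export
variant_width <- function(variant) {
  variant <- match.arg(variant, VARIANTS)
  c("MSA" = 21L, "MSA-SS-SA" = 28L, "MSA-Templ" = 24L,
    "MSA-SS-SA-Templ" = 31L)[[variant]]
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
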
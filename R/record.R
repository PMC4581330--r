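#' Protein record
#'
#' The unit of a disorder-prediction corpus: an amino-acid sequence with a
#' per-residue binary disorder annotation and optional companions — a
#' multiple sequence alignment, predicted secondary-structure and
#' solvent-accessibility strings, template hits and a crystallographic
#' resolution used as a quality proxy.
#'
#' @param id chain identifier.
#' @param sequence amino-acid string (20-letter alphabet) of length N >= 1.
#' @param labels binary string of length N; `"1"` marks a disordered residue.
#' @param resolution optional crystallographic resolution in Angstrom.
#' @param msa optional character vector of aligned rows (row 1 = the query).
#' @param ss optional 3-class secondary-structure string over `H`/`E`/`C`.
#' @param sa optional 4-class solvent-accessibility string over `B`/`b`/`e`/`E`.
#' @param template_hits optional list of [template_hit()] objects.
#' @return an object of class `protein_record`.
#' @seealso [template_hit()], [generate_corpus()]
#' @export
protein_record <- function(id, sequence, labels = NULL, resolution = NA_real_,
                           msa = NULL, ss = NULL, sa = NULL,
                           template_hits = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L,
            nchar(sequence) >= 1L)
  if (!is.null(labels)) {
    if (nchar(labels) != nchar(sequence))
      stop("labels and sequence of '", id, "' differ in length")
    if (grepl("[^01]", labels))
      stop("labels of '", id, "' contain symbols other than 0/1")
  }
  structure(list(id = id, sequence = sequence, labels = labels,
                 resolution = resolution, msa = msa, ss = ss, sa = sa,
                 template_hits = template_hits),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  n <- nchar(x$sequence)
  runs <- if (is.null(x$labels)) integer(0) else disorder_runs(x$labels)
  cat("<protein_record> ", x$id, ": ", n, " residues",
      if (!is.null(x$labels))
        paste0(", ", sum(label_vector(x$labels)), " disordered in ",
               length(runs), " run(s)"),
      if (!is.null(x$msa)) paste0(", MSA depth ", length(x$msa)),
      if (!is.null(x$template_hits))
        paste0(", ", length(x$template_hits), " template hit(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Template hit
#'
#' A homologous chain of known structure whose per-residue order/disorder
#' annotation is transferred to the query.  The annotation string is aligned
#' to query coordinates: `O` = ordered, `D` = disordered, `-` = position not
#' covered by the hit.
#'
#' @param template_id identifier of the template chain.
#' @param identity sequence identity to the query, a proportion in (0, 1].
#' @param annotation string over `O`/`D`/`-` of the query's length.
#' @return an object of class `template_hit`.
#' @export
template_hit <- function(template_id, identity, annotation) {
  stopifnot(is.character(template_id), length(identity) == 1L)
  if (!is.finite(identity) || identity <= 0 || identity > 1)
    stop("template identity must lie in (0, 1]")
  if (grepl("[^OD-]", annotation))
    stop("template annotation contains symbols outside {O, D, -}")
  structure(list(template_id = template_id, identity = identity,
                 annotation = annotation),
            class = "template_hit")
}

#' Maximal disordered run lengths of a label string
#'
#' @param labels binary 0/1 string or integer vector.
#' @return integer vector of lengths of the maximal runs of 1s.
#' @export
disorder_runs <- function(labels) {
  y <- label_vector(labels)
  r <- rle(y)
  r$lengths[r$values == 1L]
}

#' @noRd
label_vector <- function(labels) {
  if (is.character(labels)) {
    stopifnot(length(labels) == 1L)
    as.integer(strsplit(labels, "", fixed = TRUE)[[1]])
  } else {
    as.integer(labels)
  }
}

#' @noRd
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
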
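#' Write a corpus directory
#'
#' Layout: `sequences.fasta`; `labels.fasta` (0/1 strings, FASTA-like);
#' `ss.fasta` / `sa.fasta` (class strings); `resolutions.tsv`;
#' `msa/<id>.afa` (aligned FASTA, query first); `templates/<id>.tsv`
#' (columns template_id, identity, annotation over O/D/-).  Components a
#' record lacks are simply not written.
#'
#' @param records named list of [protein_record()]s.
#' @param dir output directory (created if needed).
#' @param overwrite allow writing into an existing non-empty directory?
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(records, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !overwrite)
    stop("output directory ", dir, " is non-empty; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(records, `[[`, "", "id")
  write_fasta_strings(setNames(vapply(records, `[[`, "", "sequence"), ids),
                      file.path(dir, "sequences.fasta"))
  labs <- vapply(records, function(r) r$labels %||% NA_character_, "")
  if (!anyNA(labs))
    write_fasta_strings(setNames(labs, ids), file.path(dir, "labels.fasta"))
  sss <- vapply(records, function(r) r$ss %||% NA_character_, "")
  if (!anyNA(sss))
    write_fasta_strings(setNames(sss, ids), file.path(dir, "ss.fasta"))
  sas <- vapply(records, function(r) r$sa %||% NA_character_, "")
  if (!anyNA(sas))
    write_fasta_strings(setNames(sas, ids), file.path(dir, "sa.fasta"))
  res <- vapply(records, function(r) r$resolution %||% NA_real_, numeric(1))
  write.table(data.frame(id = ids, resolution = res),
              file.path(dir, "resolutions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (any(!vapply(records, function(r) is.null(r$msa), logical(1)))) {
    dir.create(file.path(dir, "msa"), showWarnings = FALSE)
    for (r in records)
      if (!is.null(r$msa))
        write_fasta_strings(
          setNames(r$msa, c(r$id, sprintf("%s_h%03d", r$id,
                                          seq_len(length(r$msa) - 1L)))),
          file.path(dir, "msa", paste0(r$id, ".afa")))
  }
  if (any(!vapply(records, function(r) is.null(r$template_hits),
                  logical(1)))) {
    dir.create(file.path(dir, "templates"), showWarnings = FALSE)
    for (r in records) {
      if (is.null(r$template_hits)) next
      df <- data.frame(
        template_id = vapply(r$template_hits, `[[`, "", "template_id"),
        identity = vapply(r$template_hits, `[[`, numeric(1), "identity"),
        annotation = vapply(r$template_hits, `[[`, "", "annotation"))
      if (nrow(df) == 0L)
        df <- data.frame(template_id = character(0), identity = numeric(0),
                         annotation = character(0))
      write.table(df, file.path(dir, "templates", paste0(r$id, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a corpus directory written by [write_corpus()]
#'
#' @param dir corpus directory.
#' @return named list of [protein_record()]s.
#' @export
read_corpus <- function(dir) {
  seqs <- read_fasta_strings(file.path(dir, "sequences.fasta"))
  labf <- file.path(dir, "labels.fasta")
  labs <- if (file.exists(labf)) read_fasta_strings(labf) else NULL
  ssf <- file.path(dir, "ss.fasta")
  sss <- if (file.exists(ssf)) read_fasta_strings(ssf) else NULL
  saf <- file.path(dir, "sa.fasta")
  sas <- if (file.exists(saf)) read_fasta_strings(saf) else NULL
  resf <- file.path(dir, "resolutions.tsv")
  res <- if (file.exists(resf))
    read.table(resf, header = TRUE, sep = "\t",
               colClasses = c("character", "numeric")) else NULL
  records <- lapply(names(seqs), function(id) {
    msa_f <- file.path(dir, "msa", paste0(id, ".afa"))
    tpl_f <- file.path(dir, "templates", paste0(id, ".tsv"))
    hits <- NULL
    if (file.exists(tpl_f)) {
      df <- read.table(tpl_f, header = TRUE, sep = "\t",
                       colClasses = c("character", "numeric", "character"))
      hits <- lapply(seq_len(nrow(df)), function(i)
        template_hit(df$template_id[i], df$identity[i], df$annotation[i]))
    }
    protein_record(
      id = id, sequence = seqs[[id]],
      labels = if (!is.null(labs)) labs[[id]] else NULL,
      resolution = if (!is.null(res)) res$resolution[match(id, res$id)]
                   else NA_real_,
      msa = if (file.exists(msa_f))
        unname(read_fasta_strings(msa_f)) else NULL,
      ss = if (!is.null(sss)) sss[[id]] else NULL,
      sa = if (!is.null(sas)) sas[[id]] else NULL,
      template_hits = hits)
  })
  names(records) <- names(seqs)
  records
}

#' @noRd
write_fasta_strings <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path, width = 80L)
}

#' @noRd
read_fasta_strings <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' Serialize an ensemble model to JSON
#'
#' The container holds the filter geometry, stage widths, decision
#' threshold and every parameter array under named keys, at full double
#' precision, so a write/read round trip reproduces predictions exactly.
#'
#' @param ensemble an [ensemble_model()].
#' @param path output file.
#' @param variant input-encoding variant the model was trained for.
#' @param threshold stored decision threshold (optional).
#' @return `path`, invisibly.
#' @export
write_model <- function(ensemble, path, variant = NULL, threshold = NULL) {
  stage_out <- function(st) {
    c(lapply(st[STAGE_PAR_NAMES], function(x)
        if (is.matrix(x)) x else as.numeric(x)),
      st[c("d", "m", "state_width", "hidden_width", "span")])
  }
  obj <- list(
    format = "disbrnn_ensemble",
    version = as.character(utils::packageVersion("disbrnn")),
    variant = variant,
    threshold = threshold,
    geometry = unclass(ensemble$geometry),
    members = lapply(ensemble$members, function(mm)
      list(stage1 = stage_out(mm$stage1), stage2 = stage_out(mm$stage2))))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read an ensemble model written by [write_model()]
#'
#' @param path model JSON file.
#' @return list: `ensemble`, `variant`, `threshold`, `geometry`.
#' @export
read_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(raw$format, "disbrnn_ensemble"))
    stop(path, " is not a serialized model container")
  geom <- filter_geometry(raw$geometry$w, raw$geometry$p, raw$geometry$m)
  to_mat <- function(x) {
    if (is.list(x) && length(x) > 0L && is.list(x[[1]]))
      do.call(rbind, lapply(x, function(r) as.numeric(unlist(r))))
    else as.numeric(unlist(x))
  }
  members <- lapply(raw$members, function(mm) {
    stg <- function(sl) {
      st <- lapply(STAGE_PAR_NAMES, function(pn) to_mat(sl[[pn]]))
      names(st) <- STAGE_PAR_NAMES
      for (pn in c("bF1", "bF2", "bB1", "bB2", "bO1", "bO2"))
        st[[pn]] <- as.numeric(st[[pn]])
      st$d <- as.integer(sl$d); st$m <- as.integer(sl$m)
      st$state_width <- as.integer(sl$state_width)
      st$hidden_width <- as.integer(sl$hidden_width)
      st$span <- as.integer(sl$span)
      # single-row matrices survive as plain vectors; restore shapes
      fix_shape <- function(x, nr, nc) {
        if (!is.matrix(x)) matrix(x, nr, nc, byrow = (nr == 1L)) else x
      }
      H <- st$state_width; K <- st$hidden_width; S <- st$span
      st$WF1 <- fix_shape(st$WF1, K, st$d + S * H)
      st$WF2 <- fix_shape(st$WF2, H, K)
      st$WB1 <- fix_shape(st$WB1, K, st$d + S * H)
      st$WB2 <- fix_shape(st$WB2, H, K)
      st$WO1 <- fix_shape(st$WO1, K, st$d + 2L * H)
      st$WO2 <- fix_shape(st$WO2, st$m, K)
      structure(st, class = "brnn_stage")
    }
    structure(list(stage1 = stg(mm$stage1), stage2 = stg(mm$stage2),
                   geometry = geom), class = "two_stage_model")
  })
  list(ensemble = ensemble_model(members),
       variant = if (is.null(raw$variant)) NULL else raw$variant,
       threshold = if (is.null(raw$threshold)) NULL else raw$threshold,
       geometry = geom)
}

#' Write per-residue predictions as TSV
#'
#' Columns: chain id, 1-based position, residue, disorder probability,
#' binary call at the given threshold.
#'
#' @param records named list of [protein_record()]s.
#' @param scores named list of per-chain disorder-probability vectors.
#' @param path output TSV.
#' @param threshold decision threshold for the call column.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, scores, path, threshold = 0.5) {
  rows <- lapply(names(scores), function(id) {
    r <- records[[id]]
    data.frame(id = id, pos = seq_len(nchar(r$sequence)),
               residue = chars(r$sequence),
               prob = scores[[id]],
               call = as.integer(scores[[id]] >= threshold))
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction TSV written by [write_predictions()]
#' @param path prediction TSV.
#' @return data frame with columns id, pos, residue, prob, call.
#' @export
read_predictions <- function(path) {
  read.table(path, header = TRUE, sep = "\t",
             colClasses = c("character", "integer", "character",
                            "numeric", "integer"))
}
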
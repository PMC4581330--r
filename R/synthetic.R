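#' Configuration for the synthetic-corpus generator
#'
#' The generator plants short disordered runs into random amino-acid chains
#' and emits the companion annotations the predictor consumes: an MSA whose
#' conservation depends on the order/disorder state, secondary-structure and
#' solvent-accessibility strings coupled to the labels, and template hits
#' with controlled identity and annotation noise.  Defaults emulate a corpus
#' of X-ray chains harbouring short disorder: lengths 80-300 (all above the
#' length-50 selection cut), runs of 3-30 consecutive disordered residues,
#' about 6% residue-level disorder prevalence.
#'
#' @param n_chains number of chains.
#' @param length_range integer pair; chain lengths are drawn uniformly from
#'   this range.  The lower bound must exceed 50 (shorter chains would be
#'   discarded by the corpus length filter).
#' @param disorder_run_range integer pair; every maximal disordered run
#'   length falls in this range (default 3-30).
#' @param target_disorder_fraction residue-level disorder prevalence aimed
#'   for per chain (default 0.06).
#' @param msa_depth number of alignment rows, query included.
#' @param mutation_rate_ordered,mutation_rate_disordered per-residue
#'   substitution probabilities in non-query MSA rows; the disordered rate
#'   must be at least the ordered rate (disordered regions are less
#'   conserved).
#' @param template_identities proportions in (0, 1], one synthetic template
#'   hit per value.
#' @param template_label_noise probability that a template's annotation at a
#'   covered position contradicts the true label.
#' @param seed integer seed making [generate_corpus()] deterministic.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chains = 200L,
                             length_range = c(80L, 300L),
                             disorder_run_range = c(3L, 30L),
                             target_disorder_fraction = 0.06,
                             msa_depth = 30L,
                             mutation_rate_ordered = 0.10,
                             mutation_rate_disordered = 0.40,
                             template_identities = c(0.95, 0.90, 0.85, 0.80),
                             template_label_noise = 0.05,
                             seed = 1L) {
  cfg <- list(n_chains = as.integer(n_chains),
              length_range = as.integer(length_range),
              disorder_run_range = as.integer(disorder_run_range),
              target_disorder_fraction = target_disorder_fraction,
              msa_depth = as.integer(msa_depth),
              mutation_rate_ordered = mutation_rate_ordered,
              mutation_rate_disordered = mutation_rate_disordered,
              template_identities = template_identities,
              template_label_noise = template_label_noise,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' @noRd
validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_chains >= 1L, length(cfg$length_range) == 2L,
            cfg$length_range[1] <= cfg$length_range[2],
            length(cfg$disorder_run_range) == 2L,
            cfg$disorder_run_range[1] >= 1L,
            cfg$disorder_run_range[1] <= cfg$disorder_run_range[2],
            cfg$disorder_run_range[2] <= cfg$length_range[1])
  probs <- c(cfg$mutation_rate_ordered, cfg$mutation_rate_disordered,
             cfg$template_label_noise)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$mutation_rate_disordered < cfg$mutation_rate_ordered)
    stop("disordered mutation rate must be >= ordered rate")
  if (cfg$target_disorder_fraction < 0 || cfg$target_disorder_fraction >= 1)
    stop("target_disorder_fraction must lie in [0, 1)")
  if (length(cfg$template_identities) > 0 &&
      any(cfg$template_identities <= 0 | cfg$template_identities > 1))
    stop("template identities must lie in (0, 1]")
  invisible(cfg)
}

# Residue compositions. Disordered segments are enriched in P/E/S/K/Q/G and
# depleted in W/C/F/I/Y/V; ordered segments the reverse. The planted signal
# is therefore learnable from local composition alone.
DISORDER_ENRICHED <- c("P", "E", "S", "K", "Q", "G")
DISORDER_DEPLETED <- c("W", "C", "F", "I", "Y", "V")

#' @noRd
residue_dist <- function(state) {
  p <- setNames(rep(0, 20L), AA20)
  other <- setdiff(AA20, c(DISORDER_ENRICHED, DISORDER_DEPLETED))
  if (state == "disordered") {
    p[DISORDER_ENRICHED] <- 0.66 / 6
    p[DISORDER_DEPLETED] <- 0.03 / 6
    p[other] <- 0.31 / 8
  } else {
    p[DISORDER_ENRICHED] <- 0.18 / 6
    p[DISORDER_DEPLETED] <- 0.48 / 6
    p[other] <- 0.34 / 8
  }
  p
}

# Emission bias of the synthetic structural annotations: a disordered
# residue is coil / fully exposed with this probability, an ordered residue
# helix-or-strand / buried-class with the same probability.
SS_SA_COUPLING <- 0.85
# Per-residue gap rate in non-query MSA rows; exercises the 21st profile
# channel.
MSA_GAP_RATE <- 0.02

#' Generate one labelled synthetic chain
#'
#' Draws a chain length, partitions the target number of disordered residues
#' into runs whose lengths fall in `disorder_run_range`, places the runs
#' with at least one ordered residue between them, and samples residues from
#' the state-dependent compositions.  Uses the current RNG state; seed via
#' [generate_corpus()] or `set.seed()`.
#'
#' @param config a [synthetic_config()].
#' @return a [protein_record()] with sequence, labels and a resolution drawn
#'   uniformly from 1.0-1.9 Angstrom.
#' @export
generate_chain <- function(config) {
  validate_synthetic_config(config)
  if (config$length_range[1] <= 50L)
    stop("length_range lower bound must exceed 50 (corpus length filter)")
  len <- sample(config$length_range[1]:config$length_range[2], 1L)
  target <- round(config$target_disorder_fraction * len)
  runs <- partition_runs(target, config$disorder_run_range)
  lab <- place_runs(runs, len)
  seq <- character(len)
  n_dis <- sum(lab)
  seq[lab == 1L] <- sample(AA20, n_dis, replace = TRUE,
                           prob = residue_dist("disordered"))
  seq[lab == 0L] <- sample(AA20, len - n_dis, replace = TRUE,
                           prob = residue_dist("ordered"))
  protein_record(id = "chain", sequence = paste(seq, collapse = ""),
                 labels = paste(lab, collapse = ""),
                 resolution = round(runif(1, 1.0, 1.9), 3))
}

# Partition `target` residues into run lengths within [rmin, rmax]; at most
# rmin-1 residues are left unplaced.
#' @noRd
partition_runs <- function(target, run_range) {
  rmin <- run_range[1]; rmax <- run_range[2]
  runs <- integer(0)
  rem <- target
  while (rem >= rmin) {
    cand <- rmin:min(rmax, rem)
    # prefer lengths that leave a placeable (or zero) remainder; when none
    # exists, place anyway and drop the sub-minimum leftover
    ok <- cand[rem - cand == 0L | rem - cand >= rmin]
    if (length(ok) > 0L) cand <- ok
    L <- if (length(cand) == 1L) cand else sample(cand, 1L)
    runs <- c(runs, L)
    rem <- rem - L
  }
  runs
}

# Place runs separated by >= 1 ordered residue; returns 0/1 integer vector.
#' @noRd
place_runs <- function(runs, len) {
  k <- length(runs)
  lab <- integer(len)
  if (k == 0L) return(lab)
  ordered <- len - sum(runs)
  if (ordered < k - 1L)
    stop("cannot place ", k, " disordered runs in a chain of length ", len)
  spare <- ordered - (k - 1L)                       # freely distributable
  gaps <- tabulate(sample.int(k + 1L, spare, replace = TRUE), nbins = k + 1L)
  if (k > 1L) gaps[2:k] <- gaps[2:k] + 1L           # internal separators
  pos <- gaps[1]
  for (i in seq_len(k)) {
    lab[(pos + 1L):(pos + runs[i])] <- 1L
    pos <- pos + runs[i] + gaps[i + 1L]
  }
  lab
}

#' Generate a synthetic MSA for a chain
#'
#' Row 1 is the query.  Every other row substitutes each residue
#' independently at a rate depending on the order/disorder label (disordered
#' columns mutate faster, i.e. are less conserved), drawing replacements
#' from the state's residue composition, and then turns residues into gaps
#' at a small fixed rate.
#'
#' @param record a labelled [protein_record()].
#' @param config a [synthetic_config()] (depth and mutation rates).
#' @return character vector of `msa_depth` aligned rows.
#' @export
generate_msa <- function(record, config) {
  if (config$msa_depth < 1L) stop("msa_depth must be >= 1")
  q <- chars(record$sequence)
  lab <- label_vector(record$labels)
  n <- length(q)
  rate <- ifelse(lab == 1L, config$mutation_rate_disordered,
                 config$mutation_rate_ordered)
  dis_draw <- function(k) sample(AA20, k, replace = TRUE,
                                 prob = residue_dist("disordered"))
  ord_draw <- function(k) sample(AA20, k, replace = TRUE,
                                 prob = residue_dist("ordered"))
  rows <- character(config$msa_depth)
  rows[1] <- record$sequence
  for (i in seq_len(config$msa_depth - 1L)) {
    r <- q
    mut <- runif(n) < rate
    if (any(mut & lab == 1L)) r[mut & lab == 1L] <- dis_draw(sum(mut & lab == 1L))
    if (any(mut & lab == 0L)) r[mut & lab == 0L] <- ord_draw(sum(mut & lab == 0L))
    # identical sequences align gap-free; diverged rows gap at a small rate
    if (config$mutation_rate_ordered > 0 || config$mutation_rate_disordered > 0) {
      gap <- runif(n) < MSA_GAP_RATE
      r[gap] <- "-"
    }
    rows[i + 1L] <- paste(r, collapse = "")
  }
  rows
}

#' Generate synthetic structural-annotation strings
#'
#' Disordered residues emit coil (`C`) and full exposure (`E`) with
#' probability 0.85; ordered residues emit helix/strand and a buried class
#' with the same bias, mirroring the qualitative coupling between disorder,
#' secondary structure and burial that the predictor exploits.
#'
#' @param record a labelled [protein_record()].
#' @return list with elements `ss` and `sa`, each a string of the chain's
#'   length.
#' @export
generate_ss_sa <- function(record) {
  lab <- label_vector(record$labels)
  n <- length(lab)
  ss <- character(n); sa <- character(n)
  biased <- runif(n) < SS_SA_COUPLING
  dis <- lab == 1L
  ss[dis & biased] <- "C"
  ss[dis & !biased] <- sample(c("H", "E"), sum(dis & !biased), replace = TRUE)
  ss[!dis & biased] <- sample(c("H", "E"), sum(!dis & biased), replace = TRUE)
  ss[!dis & !biased] <- "C"
  biased2 <- runif(n) < SS_SA_COUPLING
  sa[dis & biased2] <- "E"
  sa[dis & !biased2] <- sample(c("B", "b", "e"), sum(dis & !biased2),
                               replace = TRUE)
  sa[!dis & biased2] <- sample(c("B", "b"), sum(!dis & biased2),
                               replace = TRUE)
  sa[!dis & !biased2] <- sample(c("e", "E"), sum(!dis & !biased2),
                                replace = TRUE)
  list(ss = paste(ss, collapse = ""), sa = paste(sa, collapse = ""))
}

#' Generate synthetic template hits for a chain
#'
#' One hit per requested identity.  The first hit covers the whole chain;
#' each further hit annotates either the whole chain or (with probability
#' 1/2) a contiguous fragment of at least half its length.  Covered
#' positions carry the true order/disorder state flipped independently with
#' probability `template_label_noise`; uncovered positions are `-`.
#'
#' @param record a labelled [protein_record()].
#' @param config a [synthetic_config()].
#' @return list of [template_hit()] objects (empty when
#'   `template_identities` is empty).
#' @export
generate_template_hits <- function(record, config) {
  ids <- config$template_identities
  if (length(ids) == 0L) return(list())
  if (any(ids <= 0 | ids > 1)) stop("template identities must lie in (0, 1]")
  lab <- label_vector(record$labels)
  n <- length(lab)
  lapply(seq_along(ids), function(i) {
    state <- ifelse(lab == 1L, "D", "O")
    flip <- runif(n) < config$template_label_noise
    state[flip] <- ifelse(state[flip] == "D", "O", "D")
    if (i > 1L && runif(1) < 0.5) {             # fragment hit
      flen <- sample(ceiling(n / 2):n, 1L)
      start <- sample.int(n - flen + 1L, 1L)
      mask <- rep(TRUE, n)
      mask[start:(start + flen - 1L)] <- FALSE
      state[mask] <- "-"
    }
    template_hit(sprintf("%s_t%02d", record$id, i), ids[i],
                 paste(state, collapse = ""))
  })
}

#' Generate a fully-annotated synthetic corpus
#'
#' Deterministic given `config$seed`: seeds the RNG, then draws each chain
#' with its MSA, secondary-structure/accessibility strings and template
#' hits.
#'
#' @param config a [synthetic_config()].
#' @return named list of [protein_record()]s with all annotations attached.
#' @export
generate_corpus <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  records <- vector("list", config$n_chains)
  for (i in seq_len(config$n_chains)) {
    rec <- generate_chain(config)
    rec$id <- sprintf("chain%04d", i)
    rec$msa <- generate_msa(rec, config)
    anno <- generate_ss_sa(rec)
    rec$ss <- anno$ss
    rec$sa <- anno$sa
    rec$template_hits <- generate_template_hits(rec, config)
    records[[i]] <- rec
  }
  names(records) <- vapply(records, `[[`, "", "id")
  records
}
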
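#' @title Reaction scoring from gene-homology evidence
#' @description Converts tabular alignment evidence (BLAST-style hits of the
#'   organism's proteins against the universal model's gene database) into
#'   per-gene scores, then into normalized per-reaction confidence scores via
#'   GPR algebra: a protein complex scores the minimum of its subunits (all
#'   subunits required), a reaction sums the scores of its isozymes.
#'   Organism-specific GPRs (the DNF restricted to present complexes) are
#'   emitted alongside.
#' @name scoring
NULL

BLAST_COLS <- c("query", "subject", "identity", "length", "mismatches",
                "gaps", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore")

#' Parse a 12-column BLAST-style alignment file into gene scores
#'
#' Hits with e-value above the cutoff are dropped; each database (subject)
#' gene scores the maximum bitscore over its retained hits. Bitscore is used
#' as the gene score because it is length-normalised and database-size
#' independent.
#'
#' @param path tab-separated alignment file in BLAST outfmt-6 layout (no
#'   header): query, subject, identity, length, mismatches, gaps, qstart,
#'   qend, sstart, send, evalue, bitscore.
#' @param evalue_cutoff maximum e-value for a hit to be retained (default
#'   1e-6).
#' @return named numeric vector: database gene id -> score; empty for an
#'   empty file.
#' @export
parse_alignment <- function(path, evalue_cutoff = 1e-6) {
  if (file.size(path) == 0) return(stats::setNames(numeric(0), character(0)))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(numeric(0), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf != 12L)) {
    stop("malformed alignment row (expected 12 tab-separated columns) at line ",
         which(nf != 12L)[1])
  }
  tb <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tb) <- BLAST_COLS
  for (col in c("evalue", "bitscore")) {
    v <- suppressWarnings(as.numeric(tb[[col]]))
    if (anyNA(v)) {
      stop("malformed numeric value in column '", col, "' at line ",
           which(is.na(v))[1])
    }
    tb[[col]] <- v
  }
  gene_scores_from_hits(tb, evalue_cutoff = evalue_cutoff)
}

#' Gene scores from a data.frame of alignment hits
#' @param hits data.frame with at least `subject`, `evalue`, `bitscore`.
#' @inheritParams parse_alignment
#' @return named numeric vector: gene id -> max retained bitscore.
#' @export
gene_scores_from_hits <- function(hits, evalue_cutoff = 1e-6) {
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) return(stats::setNames(numeric(0), character(0)))
  agg <- tapply(hits$bitscore, hits$subject, max)
  stats::setNames(as.numeric(agg), names(agg))
}

#' Read a precomputed two-column gene-score table
#'
#' Bypass for externally derived scores (e.g. orthology-refined mappings):
#' TSV with columns `gene_id`, `score`.
#'
#' @param path file path.
#' @return named numeric vector gene id -> score.
#' @export
read_gene_scores_tsv <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "score") %in% names(tb)))
  if (any(tb$score < 0)) stop("gene scores must be non-negative")
  stats::setNames(tb$score, tb$gene_id)
}

#' Raw reaction scores and organism GPRs from gene scores
#'
#' For each universe reaction with a GPR: a complex is present iff every one
#' of its subunit genes has a score, and then scores the minimum over its
#' subunits; the reaction's raw score is the sum over present complexes
#' (isozymes). Reactions with no present complex receive no raw score. The
#' organism GPR is the DNF restricted to present complexes.
#'
#' @param universe a `metabolic_model` whose reactions carry GPRs.
#' @param genes named numeric vector of gene scores (from
#'   [parse_alignment()] or [read_gene_scores_tsv()]).
#' @return list with `raw` (named numeric vector of raw scores) and `gprs`
#'   (named list reaction id -> organism [gpr()], for scored reactions).
#' @export
score_reactions <- function(universe, genes) {
  raw <- numeric(0)
  gprs <- list()
  for (k in seq_len(nrow(universe$rxns))) {
    x <- universe$rxns$gpr[[k]]
    if (gpr_is_empty(x)) next
    present <- Filter(function(cx) all(cx %in% names(genes)), x$complexes)
    if (length(present) == 0L) next
    score <- sum(vapply(present, function(cx) min(genes[cx]), 1))
    rid <- universe$rxns$id[k]
    raw[rid] <- score
    gprs[[rid]] <- gpr(present)
  }
  list(raw = raw, gprs = gprs)
}

#' Normalize raw scores into a reaction score table
#'
#' Evidence-based raw scores are divided by their median, so the median
#' normalized evidence score is exactly 1. Reactions without evidence get the
#' default negative score if enzyme-catalysed (enzymatic or transport), and a
#' neutral 0 if spontaneous, exchange or biomass (always allowed, never
#' rewarded).
#'
#' @param raw named numeric vector of raw scores (output of
#'   [score_reactions()]); must contain at least one positive value.
#' @param universe the universe model (supplies the reaction list and kinds).
#' @param default_negative score for enzyme-catalysed reactions without
#'   genetic evidence (default -1).
#' @param gprs optional organism GPR list to attach (from
#'   [score_reactions()]); unscored reactions keep the universe GPR.
#' @return a `reaction_scores` data.frame with columns `reaction`, `score`,
#'   `evidence` (logical) and list column `gpr`.
#' @export
normalize_scores <- function(raw, universe, default_negative = -1,
                             gprs = NULL) {
  raw <- raw[raw > 0]
  if (length(raw) == 0L) {
    stop("no positive raw scores: nothing to normalize")
  }
  med <- stats::median(raw)
  ids <- universe$rxns$id
  kind <- universe$rxns$kind
  evidence <- ids %in% names(raw)
  score <- ifelse(evidence, unname(raw[ids] / med),
                  ifelse(kind %in% c("enzymatic", "transport"),
                         default_negative, 0))
  glist <- universe$rxns$gpr
  if (!is.null(gprs)) {
    hit <- ids %in% names(gprs)
    glist[hit] <- gprs[ids[hit]]
  }
  out <- data.frame(reaction = ids, score = score, evidence = evidence,
                    stringsAsFactors = FALSE)
  out$gpr <- glist
  class(out) <- c("reaction_scores", "data.frame")
  out
}

#' One-call scoring pipeline
#'
#' [parse_alignment()] (or precomputed gene scores) then
#' [score_reactions()] then [normalize_scores()].
#'
#' @param universe a `metabolic_model`.
#' @param alignment path to a BLAST-style alignment file (or `NULL`).
#' @param gene_scores named numeric vector of gene scores (alternative to
#'   `alignment`).
#' @param evalue_cutoff,default_negative see the respective steps.
#' @return a `reaction_scores` table.
#' @export
compute_reaction_scores <- function(universe, alignment = NULL,
                                    gene_scores = NULL,
                                    evalue_cutoff = 1e-6,
                                    default_negative = -1) {
  if (is.null(gene_scores)) {
    if (is.null(alignment)) stop("provide alignment or gene_scores")
    gene_scores <- parse_alignment(alignment, evalue_cutoff = evalue_cutoff)
  }
  sc <- score_reactions(universe, gene_scores)
  normalize_scores(sc$raw, universe, default_negative = default_negative,
                   gprs = sc$gprs)
}

#' Construct a reaction score table directly
#'
#' Convenience constructor used by fixtures and tests.
#'
#' @param reaction character vector of reaction ids.
#' @param score numeric scores on the normalized scale.
#' @param evidence logical; `TRUE` for evidence-based scores.
#' @param gpr optional list of [gpr()] objects.
#' @return a `reaction_scores` data.frame.
#' @export
reaction_scores <- function(reaction, score, evidence = score > 0,
                            gpr = NULL) {
  out <- data.frame(reaction = reaction, score = as.numeric(score),
                    evidence = evidence, stringsAsFactors = FALSE)
  out$gpr <- if (is.null(gpr)) rep(list(parse_gpr("")), length(reaction)) else gpr
  class(out) <- c("reaction_scores", "data.frame")
  out
}

# Score vector aligned with a model's reactions; reactions absent from the
# table fall back to the kind-dependent default.
score_vector <- function(scores, m, default_negative = -1) {
  k <- match(m$rxns$id, scores$reaction)
  s <- scores$score[k]
  fallback <- ifelse(m$rxns$kind %in% c("enzymatic", "transport"),
                     default_negative, 0)
  ifelse(is.na(s), fallback, s)
}

# Evidence scores clamped for gap-filling weights: >= 0, 0 when unscored.
gapfill_weight_scores <- function(scores, m) {
  k <- match(m$rxns$id, scores$reaction)
  s <- ifelse(is.na(k) | !scores$evidence[k], 0, scores$score[k])
  pmax(s, 0)
}

#' Write / read a reaction-score table as TSV
#'
#' Columns: `reaction`, `score`, `evidence`, `gpr` (serialized rule string).
#'
#' @param scores a `reaction_scores` table.
#' @param path file path.
#' @export
write_reaction_scores_tsv <- function(scores, path) {
  tb <- data.frame(reaction = scores$reaction, score = scores$score,
                   evidence = scores$evidence,
                   gpr = vapply(scores$gpr, gpr_to_string, ""),
                   stringsAsFactors = FALSE)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_reaction_scores_tsv
#' @export
read_reaction_scores_tsv <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction", "score", "evidence") %in% names(tb)))
  gprs <- if ("gpr" %in% names(tb)) lapply(tb$gpr, parse_gpr)
          else rep(list(parse_gpr("")), nrow(tb))
  reaction_scores(tb$reaction, tb$score, as.logical(tb$evidence), gprs)
}
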
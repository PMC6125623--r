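#' @title Ensembles of alternative carved models
#' @description The carving MILP often has near-ties among subnetworks with
#'   no genetic evidence. Ensembles expose this structural uncertainty: the
#'   default negative weights of unevidenced reactions are re-drawn uniformly
#'   from [-1, 0) for each member and the MILP re-solved, producing a family
#'   of alternative models. Phenotypes are then called by voting across
#'   members.
#' @name model_ensemble
NULL

#' Generate an ensemble of carved models
#'
#' For each of the `n` members, every reaction without genetic evidence and
#' with a negative default score receives a fresh weight drawn uniformly
#' from [-1, 0) under a seeded stream; positive evidence scores are left
#' untouched. All member MILPs are solved in one backend batch. The same
#' seed reproduces the ensemble bit for bit.
#'
#' @param universe the universal `metabolic_model`.
#' @param scores a `reaction_scores` table.
#' @param n ensemble size (>= 1).
#' @param seed integer seed for the weight stream.
#' @param params a [carve_params()].
#' @param soft,hard optional constraints passed to every member (see
#'   [carve()]).
#' @return an object of class `model_ensemble`: `presence` (n x reactions
#'   binary matrix over universe reactions), `members` (list of
#'   `carve_solution`s), `union_model`, `seed`.
#' @export
generate_ensemble <- function(universe, scores, n, seed = 1L,
                              params = carve_params(), soft = NULL,
                              hard = NULL) {
  stopifnot(n >= 1)
  base <- score_vector(scores, universe)
  k <- match(universe$rxns$id, scores$reaction)
  randomize <- ifelse(is.na(k), base < 0, !scores$evidence[k] & base < 0)
  W <- with_seed(seed, {
    matrix(stats::runif(n * sum(randomize), min = -1, max = 0),
           nrow = n)
  })
  probs <- vector("list", n)
  svecs <- vector("list", n)
  for (i in seq_len(n)) {
    svec <- base
    svec[randomize] <- W[i, ]
    svecs[[i]] <- svec
    probs[[i]] <- carve_problem(universe, svec, params, soft = soft,
                                hard = hard)
  }
  res <- solve_lp_batch(probs, time_limit = params$time_limit)
  bad <- which(!vapply(res, function(r) identical(r$status, "optimal"), NA))
  if (length(bad)) {
    stop("ensemble member ", bad[1], " infeasible (", res[[bad[1]]]$status,
         "): the universe cannot sustain growth")
  }
  members <- Map(function(r, s) {
    sol <- carve_solution_from(universe, r, s, params)
    sol$model <- prune_to_model(universe, sol, scores)
    sol
  }, res, svecs)
  presence <- do.call(rbind, lapply(members, function(sol) {
    as.integer(universe$rxns$id %in% sol$kept)
  }))
  colnames(presence) <- universe$rxns$id
  rownames(presence) <- paste0("member_", seq_len(n))
  union_ids <- universe$rxns$id[colSums(presence) > 0]
  union_model <- keep_reactions(universe, union_ids)
  union_model$id <- paste0(universe$id, "_ensemble")
  structure(list(universe_id = universe$id, n = n, presence = presence,
                 members = members, union_model = union_model, seed = seed),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat("<model_ensemble> ", x$n, " members over ", ncol(x$presence),
      " universe reactions (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Pairwise Jaccard distance between ensemble members
#'
#' `d(a, b) = 1 - |Ra intersect Rb| / |Ra union Rb|` over member reaction
#' sets.
#'
#' @param ensemble a `model_ensemble` (or a binary presence matrix) with at
#'   least 2 members.
#' @return a symmetric n x n matrix with zero diagonal.
#' @export
jaccard_matrix <- function(ensemble) {
  P <- if (inherits(ensemble, "model_ensemble")) ensemble$presence else ensemble
  n <- nrow(P)
  stopifnot(n >= 2)
  inter <- P %*% t(P)
  sizes <- rowSums(P)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(rownames(P), rownames(P))
  d
}

#' Vote a consensus phenotype across ensemble members
#'
#' A call is positive iff the fraction of members agreeing is strictly
#' larger than the threshold `t` (so at `t = 0.5`, 5 of 10 positives is
#' negative, 6 of 10 positive). Raising `t` never flips a consensus from
#' negative to positive.
#'
#' @param member_calls a members x items logical/binary matrix (or a list of
#'   equal-length vectors, one per member).
#' @param threshold voting threshold in (0, 1); the conventional choices are
#'   0.1, 0.5 and 0.9.
#' @return named logical consensus vector.
#' @export
vote <- function(member_calls, threshold = 0.5) {
  if (is.list(member_calls)) {
    len <- unique(vapply(member_calls, length, 1L))
    if (length(len) != 1L) stop("member vectors must have equal length")
    member_calls <- do.call(rbind, member_calls)
  }
  stopifnot(threshold > 0, threshold < 1)
  frac <- colMeans(member_calls != 0)
  out <- frac > threshold
  names(out) <- colnames(member_calls)
  out
}

#' Export / import the ensemble presence matrix as TSV
#'
#' Rows are members, columns universe reactions, entries 0/1.
#'
#' @param ensemble a `model_ensemble` (or presence matrix).
#' @param path file path.
#' @export
write_presence_tsv <- function(ensemble, path) {
  P <- if (inherits(ensemble, "model_ensemble")) ensemble$presence else ensemble
  utils::write.table(cbind(member = rownames(P), as.data.frame(P)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_presence_tsv
#' @export
read_presence_tsv <- function(path) {
  tb <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  P <- as.matrix(tb[, -1, drop = FALSE])
  rownames(P) <- tb$member
  storage.mode(P) <- "integer"
  P
}

#' Write an ensemble as a single SBML file
#'
#' The union model is written as SBML FBC2 with each reaction annotated with
#' its member presence as an opaque key-value pair
#' (`ENSEMBLE_PRESENCE: 0;1;...`, one digit per member, in member order).
#' [read_ensemble_sbml()] reconstructs the presence matrix.
#'
#' @param ensemble a `model_ensemble`.
#' @param path file path.
#' @export
write_ensemble_sbml <- function(ensemble, path) {
  m <- ensemble$union_model
  P <- ensemble$presence
  for (k in seq_len(nrow(m$rxns))) {
    vec <- paste(P[, m$rxns$id[k]], collapse = ";")
    an <- m$rxns$annot[[k]]
    an <- c(an, c(ENSEMBLE_PRESENCE = vec))
    m$rxns$annot[[k]] <- an
  }
  write_model(m, path, dialect = "sbml-fbc2")
}

#' @rdname write_ensemble_sbml
#' @export
read_ensemble_sbml <- function(path) {
  m <- read_model(path, dialect = "sbml-fbc2")
  pres <- lapply(m$rxns$annot, function(an) {
    as.integer(strsplit(an[["ENSEMBLE_PRESENCE"]], ";", fixed = TRUE)[[1]])
  })
  P <- do.call(cbind, pres)
  colnames(P) <- m$rxns$id
  rownames(P) <- paste0("member_", seq_len(nrow(P)))
  for (k in seq_len(nrow(m$rxns))) {
    an <- m$rxns$annot[[k]]
    m$rxns$annot[[k]] <- an[setdiff(names(an), "ENSEMBLE_PRESENCE")]
  }
  structure(list(universe_id = m$id, n = nrow(P), presence = P,
                 members = NULL, union_model = m, seed = NA_integer_),
            class = "model_ensemble")
}

# Evaluate seeded expressions without touching the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
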
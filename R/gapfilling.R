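#' @title Score-weighted gap-filling
#' @description Minimally extends a model with universe reactions so it
#'   grows on each specified medium. Candidate reactions are weighted by
#'   `1 / (1 + s_i)` where `s_i` is the (non-negative) evidence score, so
#'   pathways with some genetic evidence are preferred over unevidenced
#'   alternatives; with all scores equal the objective reduces to minimising
#'   the number of added reactions (the parsimony limit).
#' @name gapfilling
NULL

# Gap-filling MILP for one medium. Variables: [v over all universe
# reactions, y over candidates]. Candidate fluxes are gated by
# y_i lb_i <= v_i <= y_i ub_i.
gapfill_problem <- function(universe, model_rxns, weights, med, min_growth,
                            bigM = 100) {
  m <- universe
  lb <- pmax(m$rxns$lb, -bigM)
  ub <- pmin(m$rxns$ub, bigM)
  # medium: exchange bounds on the union network
  ex <- which(m$rxns$kind == "exchange")
  comp <- exchange_compounds(m)
  lb[ex] <- 0
  for (cpd in intersect(names(med), comp)) {
    lb[rxn_idx(m, names(comp)[comp == cpd])] <- -med[[cpd]]
  }
  n <- nrow(m$rxns)
  cand <- which(!(m$rxns$id %in% model_rxns))
  nc <- length(cand)
  gk <- rxn_idx(m, m$objective)
  glb <- lb
  glb[gk] <- max(glb[gk], min_growth)
  sk <- fba_skeleton(m)
  Sm <- methods::as(methods::as(sk$S, "generalMatrix"), "TsparseMatrix")
  ii <- Sm@i + 1L; jj <- Sm@j + 1L; xx <- Sm@x
  nrow0 <- sk$nrow
  # v_i - lb_i y_i >= 0 and v_i - ub_i y_i <= 0 for candidates
  r1 <- nrow0 + seq_len(nc)
  r2 <- nrow0 + nc + seq_len(nc)
  ii <- c(ii, r1, r1, r2, r2)
  jj <- c(jj, cand, n + seq_len(nc), cand, n + seq_len(nc))
  xx <- c(xx, rep(1, nc), -lb[cand], rep(1, nc), -ub[cand])
  row_lb <- c(numeric(nrow0), numeric(nc), rep(-Inf, nc))
  row_ub <- c(numeric(nrow0), rep(Inf, nc), numeric(nc))
  vlb <- glb
  vub <- ub
  lp_problem(
    obj = c(numeric(n), weights[cand]),
    A = list(i = ii, j = jj, x = xx, nrow = nrow0 + 2L * nc),
    row_lb = row_lb, row_ub = row_ub,
    lb = c(vlb, numeric(nc)), ub = c(vub, rep(1, nc)),
    int_vars = (n + 1L):(n + nc),
    maximize = FALSE,
    vars = c(m$rxns$id, paste0("y.", m$rxns$id[cand]))
  )
}

#' Gap-fill a model against an ordered list of media
#'
#' For each medium in order, growth is tested by FBA; if below `min_growth`,
#' the gap-filling MILP selects a minimum-weight set of universe reactions
#' (weight `1/(1+s_i)`, `s_i >= 0`) whose addition restores growth.
#' Additions accumulate across media, so the medium order can influence the
#' final network (ensembles mitigate this).
#'
#' @param model the organism `metabolic_model` (a subset of the universe;
#'   ids must resolve).
#' @param universe the universal model providing candidate reactions.
#' @param scores a `reaction_scores` table; evidence scores are clamped to
#'   `>= 0` and unscored reactions weigh `1/(1+0) = 1`.
#' @param media a named list of [medium()] objects, processed in order.
#' @param params a [carve_params()] (supplies `min_growth`, `bigM` and the
#'   solver time limit).
#' @return a list with `model` (the extended model) and `added` (named list:
#'   medium -> character vector of added reaction ids).
#' @export
gapfill <- function(model, universe, scores, media, params = carve_params()) {
  if (!all(model$rxns$id %in% universe$rxns$id)) {
    stop("model is not a subset of the universe: ",
         paste(setdiff(model$rxns$id, universe$rxns$id), collapse = ", "))
  }
  if (is.null(names(media)) || any(!nzchar(names(media)))) {
    names(media) <- paste0("medium_", seq_along(media))
  }
  svec <- gapfill_weight_scores(scores, universe)
  weights <- 1 / (1 + svec)
  added <- stats::setNames(vector("list", length(media)), names(media))
  for (mi in seq_along(media)) {
    med <- media[[mi]]
    growth <- fba(model, med = med)
    if (identical(growth$status, "optimal") &&
        growth$objective >= params$min_growth - params$feas_tol) {
      added[[mi]] <- character(0)
      next
    }
    prob <- gapfill_problem(universe, model$rxns$id, weights, med,
                            params$min_growth, bigM = params$bigM)
    res <- solve_lp(prob, time_limit = params$time_limit)
    if (!identical(res$status, "optimal")) {
      stop("gap-filling infeasible for medium '", names(media)[mi],
           "': no extension of the model enables growth (", res$status, ")")
    }
    n <- nrow(universe$rxns)
    y <- res$x[-seq_len(n)]
    add_ids <- sub("^y\\.", "", names(y)[y > 0.5])
    if (length(add_ids)) {
      new_rxns <- universe$rxns[rxn_idx(universe, add_ids), , drop = FALSE]
      used <- unique(unlist(lapply(new_rxns$stoich, names), use.names = FALSE))
      new_mets <- universe$mets[universe$mets$id %in% used, , drop = FALSE]
      model <- add_reactions(model, new_rxns, mets = new_mets)
    }
    added[[mi]] <- add_ids
  }
  list(model = model, added = added)
}
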
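# Independent brute-force oracles. These deliberately avoid the package's
# MILP formulations: selections are enumerated exhaustively and each
# candidate is checked with a plain feasibility LP, so they stay valid
# yardsticks for the carve / gapfill / minimal-medium optimisers.

# Evaluate a boolean gene rule with R's own parser (truth-table oracle).
eval_rule_r <- function(text, present, genes) {
  expr <- gsub("\\band\\b", "&", text, ignore.case = TRUE)
  expr <- gsub("\\bor\\b", "|", expr, ignore.case = TRUE)
  env <- as.list(stats::setNames(genes %in% present, genes))
  isTRUE(eval(parse(text = expr), envir = env))
}

# All subsets of a character vector (list of character vectors).
all_subsets <- function(x) {
  n <- length(x)
  lapply(seq_len(2^n) - 1L, function(mask) x[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0])
}

# Feasibility LP bounds for a chosen active set with fixed flux signs.
# sign = +1 forces v in [eps, M], -1 forces v in [-M, -eps].
carve_subset_problem <- function(m, active, signs, params) {
  mm <- carvenet::complete_medium(m, params$bigM)
  lb <- pmax(mm$rxns$lb, -params$bigM)
  ub <- pmin(mm$rxns$ub, params$bigM)
  for (k in seq_len(nrow(mm$rxns))) {
    rid <- mm$rxns$id[k]
    if (!(rid %in% active)) {
      lb[k] <- 0; ub[k] <- 0
    } else if (signs[[rid]] > 0) {
      lb[k] <- max(lb[k], params$epsilon)
    } else {
      ub[k] <- min(ub[k], -params$epsilon)
    }
  }
  gk <- match(m$objective, mm$rxns$id)
  lb[gk] <- max(lb[gk], params$min_growth)
  if (any(lb > ub)) return(NULL)
  S <- carvenet::build_stoichiometric_matrix(mm)
  S <- S[!mm$mets$boundary, , drop = FALSE]
  carvenet:::lp_problem(obj = numeric(nrow(mm$rxns)), A = S,
                        row_lb = numeric(nrow(S)), row_ub = numeric(nrow(S)),
                        lb = lb, ub = ub)
}

# Exhaustive carve oracle: maximum achievable score over all feasible
# subnetworks (with sign enumeration for reversible members). Returns the
# optimum objective and one optimal subset.
oracle_carve <- function(m, svec, params, soft = NULL) {
  ids <- m$rxns$id
  names(svec) <- ids
  # direction freedom under carving conditions (exchanges opened)
  rev_ok <- carvenet::complete_medium(m, params$bigM)$rxns$lb < 0
  names(rev_ok) <- ids
  cases <- list()
  for (active in all_subsets(ids)) {
    if (!(m$objective %in% active)) next
    rev_in <- active[rev_ok[active]]
    for (rmask in seq_len(max(1L, 2^length(rev_in))) - 1L) {
      signs <- stats::setNames(rep(1, length(active)), active)
      if (length(rev_in)) {
        flip <- rev_in[bitwAnd(rmask, 2^(seq_along(rev_in) - 1L)) > 0]
        signs[flip] <- -1
      }
      score <- sum(svec[active])
      if (!is.null(soft)) {
        for (rid in names(soft)) {
          if (!(rid %in% active)) next
          val <- soft[[rid]]
          if (val == 1 && signs[[rid]] > 0) score <- score + params$w_soft
          if (val == -1 && signs[[rid]] < 0) score <- score + params$w_soft
          if (val == 0) score <- score - params$w_soft
        }
      }
      prob <- carve_subset_problem(m, active, signs, params)
      if (is.null(prob)) next
      cases[[length(cases) + 1L]] <- list(active = active, score = score,
                                          prob = prob)
    }
  }
  res <- carvenet:::solve_lp_batch(lapply(cases, `[[`, "prob"))
  best <- -Inf
  best_set <- NULL
  for (k in seq_along(cases)) {
    if (identical(res[[k]]$status, "optimal") && cases[[k]]$score > best) {
      best <- cases[[k]]$score
      best_set <- cases[[k]]$active
    }
  }
  list(objective = best, kept = best_set)
}

# Exhaustive gap-fill oracle: cheapest candidate subset restoring growth.
oracle_gapfill <- function(model, universe, weights, med, params) {
  cand <- setdiff(universe$rxns$id, model$rxns$id)
  names(weights) <- universe$rxns$id
  cases <- list()
  for (extra in all_subsets(cand)) {
    mm <- carvenet::keep_reactions(universe, c(model$rxns$id, extra))
    mm <- carvenet::apply_medium(mm, med)
    gk <- match(mm$objective, mm$rxns$id)
    lb <- pmax(mm$rxns$lb, -params$bigM)
    ub <- pmin(mm$rxns$ub, params$bigM)
    lb[gk] <- max(lb[gk], params$min_growth)
    S <- carvenet::build_stoichiometric_matrix(mm)
    S <- S[!mm$mets$boundary, , drop = FALSE]
    prob <- carvenet:::lp_problem(obj = numeric(nrow(mm$rxns)), A = S,
                                  row_lb = numeric(nrow(S)),
                                  row_ub = numeric(nrow(S)), lb = lb, ub = ub)
    cases[[length(cases) + 1L]] <- list(extra = extra,
                                        cost = sum(weights[extra]),
                                        prob = prob)
  }
  res <- carvenet:::solve_lp_batch(lapply(cases, `[[`, "prob"))
  best <- Inf
  best_set <- NULL
  for (k in seq_along(cases)) {
    if (identical(res[[k]]$status, "optimal") && cases[[k]]$cost < best) {
      best <- cases[[k]]$cost
      best_set <- cases[[k]]$extra
    }
  }
  list(cost = best, added = best_set)
}

# Exhaustive minimal-medium oracle: smallest compound subset enabling
# growth at min_growth.
oracle_minimal_medium <- function(m, candidates, params) {
  comp <- carvenet::exchange_compounds(m)
  cases <- list()
  for (sel in all_subsets(candidates)) {
    lb <- pmax(m$rxns$lb, -params$bigM)
    ub <- pmin(m$rxns$ub, params$bigM)
    for (k in which(m$rxns$id %in% names(comp))) {
      lb[k] <- if (comp[[m$rxns$id[k]]] %in% sel) -params$bigM else max(lb[k], 0)
    }
    gk <- match(m$objective, m$rxns$id)
    lb[gk] <- max(lb[gk], params$min_growth)
    S <- carvenet::build_stoichiometric_matrix(m)
    S <- S[!m$mets$boundary, , drop = FALSE]
    prob <- carvenet:::lp_problem(obj = numeric(nrow(m$rxns)), A = S,
                                  row_lb = numeric(nrow(S)),
                                  row_ub = numeric(nrow(S)), lb = lb, ub = ub)
    cases[[length(cases) + 1L]] <- list(sel = sel, prob = prob)
  }
  res <- carvenet:::solve_lp_batch(lapply(cases, `[[`, "prob"))
  best <- Inf
  for (k in seq_along(cases)) {
    if (identical(res[[k]]$status, "optimal") &&
        length(cases[[k]]$sel) < best) {
      best <- length(cases[[k]]$sel)
    }
  }
  best
}

# Tiny universes (<= 8 reactions) for oracle-equivalence checks.
tiny_universe <- function(seed) {
  carvenet::make_random_universe(
    carvenet::toy_spec(n_pathways = 2, pathway_len = 1, isozyme_prob = 0.3,
                       complex_prob = 0.2, n_distractors = 1, seed = seed))
}
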
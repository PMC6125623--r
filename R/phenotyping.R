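#' @title Simulation engines: FBA, FVA, phenotype arrays, essentiality
#' @description Flux balance analysis and its derived assays. All linear
#'   programs are dispatched through the pluggable solver backend; loops over
#'   conditions (FVA directions, array substrates, gene deletions) are batched
#'   into a single backend call.
#' @name phenotyping
NULL

# Base LP skeleton shared by fba/fva/essentiality: steady-state rows over
# non-boundary metabolites, one variable per reaction.
fba_skeleton <- function(m) {
  S <- build_stoichiometric_matrix(m)
  keep <- !m$mets$boundary
  S <- S[keep, , drop = FALSE]
  list(S = S, nrow = nrow(S), nvar = nrow(m$rxns), vars = m$rxns$id)
}

fba_problem <- function(m, sk = fba_skeleton(m), obj_rxn = m$objective,
                        lb = m$rxns$lb, ub = m$rxns$ub, maximize = TRUE) {
  obj <- numeric(sk$nvar)
  if (!is.na(obj_rxn)) obj[rxn_idx(m, obj_rxn)] <- 1
  lp_problem(obj = obj, A = sk$S,
             row_lb = numeric(sk$nrow), row_ub = numeric(sk$nrow),
             lb = lb, ub = ub, maximize = maximize, vars = sk$vars)
}

#' Flux balance analysis
#'
#' Maximises the objective (biomass) flux subject to steady state
#' (`S v = 0` over non-boundary metabolites) and the flux bounds.
#'
#' @param m a `metabolic_model` with an objective reaction.
#' @param med optional [medium()] applied via [apply_medium()] first.
#' @param objective objective reaction id (default: the model objective).
#' @return a list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `objective` (the optimum; `NA` unless optimal) and
#'   `fluxes` (named flux vector). An unbounded status is diagnostic for
#'   uncapped energy-generating cycles.
#' @export
fba <- function(m, med = NULL, objective = m$objective) {
  if (!is.null(med)) m <- apply_medium(m, med)
  if (is.na(objective)) stop("model has no objective reaction")
  res <- solve_lp(fba_problem(m, obj_rxn = objective))
  list(status = res$status,
       objective = if (identical(res$status, "optimal")) res$objective else NA_real_,
       fluxes = if (identical(res$status, "optimal")) res$x else NULL)
}

#' Flux variability analysis
#'
#' Minimum and maximum feasible flux per reaction (two LPs per reaction,
#' solved as one batch). By default no growth constraint is imposed (pure
#' connectivity analysis, as used for blocked-reaction detection); set
#' `fraction_of_optimum > 0` to require that fraction of the FBA optimum.
#'
#' @param m a `metabolic_model`.
#' @param reactions reaction ids to analyse (default: all).
#' @param fraction_of_optimum fraction of the objective optimum to enforce
#'   (default 0 = none).
#' @param med optional [medium()] applied first.
#' @return a data.frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(m, reactions = m$rxns$id, fraction_of_optimum = 0, med = NULL) {
  if (!is.null(med)) m <- apply_medium(m, med)
  sk <- fba_skeleton(m)
  lb <- m$rxns$lb
  ub <- m$rxns$ub
  if (fraction_of_optimum > 0) {
    opt <- fba(m)
    if (!identical(opt$status, "optimal")) {
      stop("fva: base model infeasible, cannot fix objective fraction")
    }
    k <- rxn_idx(m, m$objective)
    lb[k] <- max(lb[k], fraction_of_optimum * opt$objective)
  }
  idx <- rxn_idx(m, reactions)
  probs <- list()
  for (k in idx) {
    obj <- numeric(sk$nvar)
    obj[k] <- 1
    base <- lp_problem(obj = obj, A = sk$S,
                       row_lb = numeric(sk$nrow), row_ub = numeric(sk$nrow),
                       lb = lb, ub = ub, maximize = FALSE)
    probs[[length(probs) + 1L]] <- base
    base$maximize <- TRUE
    probs[[length(probs) + 1L]] <- base
  }
  res <- solve_lp_batch(probs)
  getval <- function(r) {
    if (identical(r$status, "optimal")) r$objective else NA_real_
  }
  mins <- vapply(res[seq(1, length(res), by = 2)], getval, 1)
  maxs <- vapply(res[seq(2, length(res), by = 2)], getval, 1)
  if (anyNA(mins) || anyNA(maxs)) stop("fva: infeasible base model")
  data.frame(reaction = reactions, min = mins, max = maxs,
             stringsAsFactors = FALSE)
}

#' Simulate a Biolog-style phenotype array
#'
#' Starting from a minimal base medium, the default source of the probed
#' element is iteratively replaced by each compound in the array, uptake is
#' capped at `uptake` mmol/gDW/h, and growth is evaluated by FBA. A phenotype
#' is viable if the growth rate is at least `viability_threshold`.
#'
#' @param m a `metabolic_model`.
#' @param base_medium a [medium()] containing the default source.
#' @param element probed element, one of `"C"`, `"N"`, `"S"`, `"P"`
#'   (informational; the swap is driven by `default_source`).
#' @param sources character vector of compound ids to test.
#' @param default_source compound id of the element's default source in
#'   `base_medium` (e.g. glucose for carbon, ammonia for nitrogen).
#' @param uptake uptake rate for the probed source (default 10 mmol/gDW/h).
#' @param viability_threshold growth-rate cutoff (default 0.01 h^-1,
#'   inclusive).
#' @return named logical vector of viability calls, with the growth rates in
#'   `attr(, "growth")`. Sources without an exchange reaction are called
#'   non-viable with a warning (transporter-gap semantics).
#' @export
simulate_phenotype_array <- function(m, base_medium, element = c("C", "N", "S", "P"),
                                     sources, default_source, uptake = 10,
                                     viability_threshold = 0.01) {
  element <- match.arg(element)
  if (!(default_source %in% names(base_medium))) {
    stop("base medium does not contain the default ", element, " source ",
         default_source)
  }
  if (length(sources) == 0L) {
    return(stats::setNames(logical(0), character(0)))
  }
  have_ex <- unique(unname(exchange_compounds(m)))
  sk <- fba_skeleton(m)
  probs <- list()
  testable <- logical(length(sources))
  for (k in seq_along(sources)) {
    src <- sources[k]
    if (!(src %in% have_ex)) next
    med <- base_medium[setdiff(names(base_medium), default_source)]
    med <- medium(c(stats::setNames(uptake, src), unlist(med)))
    mk <- apply_medium(m, med)
    testable[k] <- TRUE
    probs[[length(probs) + 1L]] <- fba_problem(m, sk, lb = mk$rxns$lb,
                                               ub = mk$rxns$ub)
  }
  if (any(!testable)) {
    warning("array sources without exchange reaction, called non-viable: ",
            paste(sources[!testable], collapse = ", "))
  }
  res <- solve_lp_batch(probs)
  growth <- rep(NA_real_, length(sources))
  growth[testable] <- vapply(res, function(r) {
    if (identical(r$status, "optimal")) r$objective else 0
  }, 1)
  # small slack absorbs LP solver feasibility noise at the threshold
  calls <- !is.na(growth) & growth >= viability_threshold - 1e-9
  names(calls) <- sources
  attr(calls, "growth") <- stats::setNames(growth, sources)
  calls
}

#' Allow free diffusion of untransported extracellular metabolites
#'
#' For every extracellular metabolite of the model that no transport reaction
#' connects to the cytosol, adds a reversible diffusion reaction
#' (extracellular <-> cytosol, empty GPR, kind `"spontaneous"`) and an
#' exchange reaction if absent. Used to separate transporter-annotation gaps
#' from genuine pathway gaps in phenotype simulations.
#'
#' @param m a `metabolic_model`.
#' @param universe the universal model defining the extracellular vocabulary
#'   and cytosolic counterparts (defaults to `m` itself).
#' @param cytosol id of the cytosolic compartment (default `"c"`).
#' @return the augmented model.
#' @export
enable_free_diffusion <- function(m, universe = m, cytosol = "c") {
  e_mets <- m$mets[m$mets$compartment == m$extracellular & !m$mets$boundary, ,
                   drop = FALSE]
  for (k in seq_len(nrow(e_mets))) {
    mid <- e_mets$id[k]
    cpd <- e_mets$compound[k]
    touching <- vapply(m$rxns$stoich, function(s) mid %in% names(s), NA)
    has_transport <- any(touching & m$rxns$kind != "exchange")
    if (has_transport) next
    cid <- m$mets$id[m$mets$compound == cpd & m$mets$compartment == cytosol]
    new_mets <- NULL
    if (length(cid) == 0L) {
      uc <- universe$mets[universe$mets$compound == cpd &
                            universe$mets$compartment == cytosol, , drop = FALSE]
      if (nrow(uc) == 0L) {
        uc <- metabolite(paste0(cpd, "_", cytosol), cytosol, compound = cpd)
      }
      cid <- uc$id[1]
      new_mets <- uc[1, , drop = FALSE]
      if (!(cytosol %in% m$compartments)) {
        m$compartments <- c(m$compartments, cytosol)
      }
    }
    diff_id <- paste0("DIFF_", cpd)
    if (!(diff_id %in% m$rxns$id)) {
      m <- add_reactions(m, reaction(diff_id,
                                     stats::setNames(c(-1, 1), c(mid, cid[1])),
                                     lb = -100, ub = 100, kind = "spontaneous"),
                         mets = new_mets)
    }
    if (!any(m$rxns$kind == "exchange" &
               vapply(m$rxns$stoich, function(s) identical(names(s), mid), NA))) {
      ex_id <- paste0("EX_", cpd)
      if (!(ex_id %in% m$rxns$id)) {
        m <- add_reactions(m, reaction(ex_id, stats::setNames(-1, mid),
                                       lb = 0, ub = 100, kind = "exchange"))
      }
    }
  }
  m
}

#' Single-gene essentiality by FBA
#'
#' Each gene is deleted in turn; a reaction is disabled iff its GPR has no
#' surviving complex (reactions with empty GPRs are immune); disabled
#' reactions' bounds are closed and growth re-evaluated by FBA (one batched
#' solver call for all genes). A gene is essential iff the resulting growth
#' rate falls below `threshold`.
#'
#' @param m a `metabolic_model`.
#' @param med optional [medium()] applied first.
#' @param genes genes to evaluate (default: all genes in the model's GPRs);
#'   unknown genes are skipped with a warning.
#' @param threshold essentiality growth cutoff (default 1e-6 h^-1).
#' @return character vector of essential genes, with per-gene growth rates in
#'   `attr(, "growth")`.
#' @export
gene_essentiality <- function(m, med = NULL, genes = model_genes(m),
                              threshold = 1e-6) {
  if (!is.null(med)) m <- apply_medium(m, med)
  known <- model_genes(m)
  unknown <- setdiff(genes, known)
  if (length(unknown)) {
    warning("genes not present in any GPR, skipped: ",
            paste(unknown, collapse = ", "))
    genes <- intersect(genes, known)
  }
  if (length(genes) == 0L) {
    return(stats::setNames(character(0), NULL))
  }
  sk <- fba_skeleton(m)
  probs <- lapply(genes, function(g) {
    disabled <- vapply(m$rxns$gpr, function(x) {
      !gpr_is_empty(x) && gpr_is_empty(gpr_without_genes(x, g))
    }, NA)
    lb <- m$rxns$lb
    ub <- m$rxns$ub
    lb[disabled] <- 0
    ub[disabled] <- 0
    fba_problem(m, sk, lb = lb, ub = ub)
  })
  res <- solve_lp_batch(probs)
  growth <- vapply(res, function(r) {
    if (identical(r$status, "optimal")) r$objective else 0
  }, 1)
  essential <- genes[growth < threshold]
  attr(essential, "growth") <- stats::setNames(growth, genes)
  essential
}

#' Confusion-matrix performance metrics
#'
#' Standard binary-classification metrics for phenotype and essentiality
#' benchmarks: precision TP/(TP+FP), sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), accuracy (TP+TN)/(TP+FP+TN+FN) and F1 = 2TP/(2TP+FN+FP).
#' Ratios with a zero denominator are reported as `NA` (undefined), never 0.
#'
#' @param predicted,observed equal-length logical (or 0/1) vectors.
#' @return a list with elements `precision`, `sensitivity`, `specificity`,
#'   `accuracy`, `f1` and the counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have the same length")
  }
  p <- as.logical(predicted)
  o <- as.logical(observed)
  tp <- sum(p & o); fp <- sum(p & !o); tn <- sum(!p & !o); fn <- sum(!p & o)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(precision = ratio(tp, tp + fp),
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       accuracy = ratio(tp + tn, tp + fp + tn + fn),
       f1 = ratio(2 * tp, 2 * tp + fn + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}
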
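#' @title Microbial community models
#' @description Merges single-species models into one community model: each
#'   member keeps its own namespaced intracellular compartments while the
#'   extracellular environment is shared through a common metabolite pool.
#'   Optionally each member retains an isolated extracellular compartment
#'   bridged to the pool by shuttle reactions, a common community biomass
#'   reaction couples member growth, and a growth medium initialises the
#'   pool. The metabolic interaction potential (MIP) quantifies how much the
#'   community can reduce its dependence on external nutrient supply by
#'   exchanging metabolites.
#' @name community
NULL

ns_id <- function(x, member) paste0(x, "__", member)

ns_gpr <- function(x, member) {
  gpr(lapply(x$complexes, function(cx) ns_id(cx, member)))
}

#' Merge single-species models into a community model
#'
#' Member reactions, metabolites, compartments and genes are renamed with a
#' `__<member id>` suffix. Extracellular metabolites (which must use a
#' shared compound vocabulary across members) are pooled: either merged
#' directly into a common pool compartment, or (with
#' `isolated_extracellular`) kept in per-member extracellular compartments
#' connected to the pool by reversible shuttle reactions. Member exchange
#' reactions are re-wired to pool exchanges, deduplicated by compound with
#' the widest bounds.
#'
#' @param models list of `metabolic_model`s with distinct, non-empty ids.
#' @param isolated_extracellular keep one extracellular compartment per
#'   member, bridged to the pool by shuttles (default `FALSE`).
#' @param community_biomass add a community growth reaction draining each
#'   member's biomass with equal weight `1/n`, and make it the objective
#'   (default `FALSE`; otherwise the objective is the first member's biomass
#'   reaction).
#' @param med optional [medium()] applied to the pool exchanges.
#' @param id id of the merged model.
#' @param interacting internal switch used by [mip_score()]: when `FALSE`
#'   the pool and shuttles are omitted and every member keeps private
#'   exchange reactions on its own extracellular compartment (the
#'   non-interacting baseline).
#' @param bigM flux cap used for shuttle reactions (default 100).
#' @return a `community_model` (also a `metabolic_model`), with the member
#'   ids in `$members`.
#' @export
merge_community <- function(models, isolated_extracellular = FALSE,
                            community_biomass = FALSE, med = NULL,
                            id = "community", interacting = TRUE,
                            bigM = 100) {
  stopifnot(length(models) >= 1)
  members <- vapply(models, function(m) m$id, "")
  if (any(!nzchar(members)) || anyDuplicated(members)) {
    stop("member models must have distinct non-empty ids")
  }
  isolated <- isolated_extracellular || !interacting
  pool_mets <- list()   # compound -> metabolite row (pool copy)
  pool_ex <- list()     # compound -> c(lb, ub)
  all_mets <- list()
  all_rxns <- list()
  compartments <- character(0)
  biomass_rxns <- character(0)
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    mid <- members[mi]
    is_e <- m$mets$compartment == m$extracellular
    met_map <- stats::setNames(ns_id(m$mets$id, mid), m$mets$id)
    mets <- m$mets
    mets$id <- unname(met_map)
    mets$compartment <- ns_id(mets$compartment, mid)
    if (interacting && !isolated) {
      # extracellular metabolites merge straight into the pool
      pool_ids <- paste0(m$mets$compound[is_e], "_pool")
      met_map[m$mets$id[is_e]] <- pool_ids
      mets$id[is_e] <- pool_ids
      mets$compartment[is_e] <- "pool"
    }
    for (k in which(is_e)) {
      cpd <- m$mets$compound[k]
      if (is.null(pool_mets[[cpd]])) {
        pm <- m$mets[k, , drop = FALSE]
        pm$id <- paste0(cpd, "_pool")
        pm$compartment <- "pool"
        pool_mets[[cpd]] <- pm
      }
    }
    keep_mets <- if (interacting && !isolated) !is_e else rep(TRUE, nrow(mets))
    all_mets[[mi]] <- mets[keep_mets, , drop = FALSE]
    compartments <- c(compartments, unique(mets$compartment[keep_mets]))

    rxns <- m$rxns
    drop <- logical(nrow(rxns))
    for (k in seq_len(nrow(rxns))) {
      st <- rxns$stoich[[k]]
      names(st) <- unname(met_map[names(st)])
      rxns$stoich[[k]] <- st
      rxns$gpr[[k]] <- ns_gpr(rxns$gpr[[k]], mid)
      if (rxns$kind[k] == "exchange") {
        cpd <- m$mets$compound[match(names(m$rxns$stoich[[k]]), m$mets$id)]
        old <- pool_ex[[cpd]]
        bnd <- c(rxns$lb[k], rxns$ub[k])
        pool_ex[[cpd]] <- if (is.null(old)) bnd else
          c(min(old[1], bnd[1]), max(old[2], bnd[2]))
        if (interacting && isolated) {
          # member exchange becomes a shuttle member-e <-> pool
          rxns$id[k] <- ns_id(paste0("SH_", cpd), mid)
          rxns$kind[k] <- "transport"
          rxns$stoich[[k]] <- stats::setNames(
            c(-1, 1), c(met_map[[names(m$rxns$stoich[[k]])]],
                        paste0(cpd, "_pool")))
          rxns$lb[k] <- -bigM
          rxns$ub[k] <- bigM
        } else if (interacting) {
          drop[k] <- TRUE    # replaced by a deduplicated pool exchange
        } else {
          rxns$id[k] <- ns_id(rxns$id[k], mid)  # private exchange
        }
      } else {
        rxns$id[k] <- ns_id(rxns$id[k], mid)
      }
    }
    if (!is.na(m$objective)) {
      biomass_rxns <- c(biomass_rxns, ns_id(m$objective, mid))
    }
    all_rxns[[mi]] <- rxns[!drop, , drop = FALSE]
  }
  mets <- do.call(rbind, all_mets)
  rxns <- do.call(rbind, all_rxns)
  if (interacting) {
    mets <- rbind(mets, do.call(rbind, pool_mets))
    compartments <- c(compartments, "pool")
    for (cpd in names(pool_ex)) {
      bnd <- pool_ex[[cpd]]
      rxns <- rbind(rxns, reaction(paste0("EX_", cpd, "_pool"),
                                   stats::setNames(-1, paste0(cpd, "_pool")),
                                   lb = bnd[1], ub = bnd[2],
                                   kind = "exchange"))
    }
  }
  n <- length(models)
  objective <- if (length(biomass_rxns)) biomass_rxns[1] else NA_character_
  if (community_biomass) {
    if (length(biomass_rxns) != length(models)) {
      stop("community biomass requires every member to have a biomass objective")
    }
    growth_mets <- character(n)
    for (mi in seq_len(n)) {
      k <- match(biomass_rxns[mi], rxns$id)
      st <- rxns$stoich[[k]]
      prod <- names(st)[st > 0]
      prod <- prod[mets$boundary[match(prod, mets$id)]]
      if (length(prod) == 0L) {
        gm <- paste0("biomass_", members[mi])
        mets <- rbind(mets, metabolite(gm, mets$compartment[1], compound = "biomass",
                                       boundary = FALSE))
        rxns$stoich[[k]] <- c(st, stats::setNames(1, gm))
        growth_mets[mi] <- gm
      } else {
        growth_mets[mi] <- prod[1]
        mets$boundary[match(prod[1], mets$id)] <- FALSE
      }
    }
    comm_growth <- reaction("community_growth",
                            stats::setNames(rep(-1 / n, n), growth_mets),
                            lb = 0, ub = 1000, kind = "biomass")
    # member biomass pseudo-reactions stay, but only one "biomass" kind
    rxns$kind[rxns$id %in% biomass_rxns] <- "enzymatic"
    rxns <- rbind(rxns, comm_growth)
    objective <- "community_growth"
  }
  cm <- new_model(id, unique(compartments), mets, rxns,
                  objective = objective,
                  extracellular = if (interacting) "pool" else "none",
                  validate = FALSE)
  validate_model(cm, strict = FALSE)
  cm$members <- members
  class(cm) <- c("community_model", class(cm))
  if (!is.null(med)) cm <- apply_medium(cm, med)
  cm
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", x$id, " (", length(x$members), " members: ",
      paste(x$members, collapse = ", "), ")\n", sep = "")
  NextMethod()
}

#' Minimal growth medium by MILP
#'
#' Finds a smallest set of candidate compounds whose uptake enables growth:
#' one binary per compound gates the lower bounds of all exchange reactions
#' of that compound (in a community, every member's private exchange of the
#' compound is gated by the same binary), and the number of enabled
#' compounds is minimised subject to `v_growth >= min_growth`.
#'
#' @param m a `metabolic_model` (single species or community).
#' @param candidates candidate compound ids (default: all compounds with an
#'   exchange reaction).
#' @param params a [carve_params()] (supplies `min_growth`, `bigM`,
#'   `time_limit`).
#' @return list with `compounds` (one optimal compound set), `size` and
#'   `growth` (growth rate at the optimum). Errors if the model cannot grow
#'   even on the full candidate pool.
#' @export
minimal_medium <- function(m, candidates = NULL, params = carve_params()) {
  comp <- exchange_compounds(m)
  if (is.null(candidates)) candidates <- sort(unique(unname(comp)))
  unknown <- setdiff(candidates, unname(comp))
  if (length(unknown)) {
    stop("candidate compounds without exchange reaction: ",
         paste(unknown, collapse = ", "))
  }
  M <- params$bigM
  lb <- pmax(m$rxns$lb, -M)
  ub <- pmin(m$rxns$ub, M)
  cand_ex <- which(m$rxns$id %in% names(comp)[comp %in% candidates])
  lb[cand_ex] <- -M
  gk <- rxn_idx(m, m$objective)
  # feasibility on the full pool first, for a clean error
  full <- fba_problem(m, lb = lb, ub = ub)
  fres <- solve_lp(full)
  if (!identical(fres$status, "optimal") ||
      fres$objective < params$min_growth - params$feas_tol) {
    stop("model does not grow on the full candidate pool (growth ",
         if (identical(fres$status, "optimal")) signif(fres$objective, 4)
         else fres$status, ")")
  }
  n <- nrow(m$rxns)
  nc <- length(candidates)
  glb <- lb
  glb[gk] <- max(glb[gk], params$min_growth)
  sk <- fba_skeleton(m)
  Sm <- methods::as(methods::as(sk$S, "generalMatrix"), "TsparseMatrix")
  ii <- Sm@i + 1L; jj <- Sm@j + 1L; xx <- Sm@x
  nrow0 <- sk$nrow
  rows <- nrow0
  for (ci in seq_len(nc)) {
    ex_k <- which(m$rxns$id %in% names(comp)[comp == candidates[ci]])
    for (k in ex_k) {
      rows <- rows + 1L
      ii <- c(ii, rows, rows)
      jj <- c(jj, k, n + ci)
      xx <- c(xx, 1, M)     # v_ex + M y_c >= 0
    }
  }
  extra <- rows - nrow0
  prob <- lp_problem(
    obj = c(numeric(n), rep(1, nc)),
    A = list(i = ii, j = jj, x = xx, nrow = rows),
    row_lb = c(numeric(nrow0), numeric(extra)),
    row_ub = c(numeric(nrow0), rep(Inf, extra)),
    lb = c(glb, numeric(nc)), ub = c(ub, rep(1, nc)),
    int_vars = (n + 1L):(n + nc),
    maximize = FALSE,
    vars = c(m$rxns$id, paste0("y.", candidates))
  )
  res <- solve_lp(prob, time_limit = params$time_limit)
  if (!identical(res$status, "optimal")) {
    stop("minimal-medium MILP not solved: ", res$status)
  }
  y <- res$x[n + seq_len(nc)]
  sel <- candidates[y > 0.5]
  list(compounds = sel, size = length(sel),
       growth = unname(res$x[gk]))
}

#' Metabolic interaction potential (MIP) of a community
#'
#' MIP is the number of compounds the members can provide for each other:
#' the size of the minimal medium of the non-interacting community (members
#' with isolated extracellular compartments and no pool shuttles, private
#' exchanges gated per compound) minus the size of the minimal medium of the
#' interacting community (shared extracellular pool). Interaction can only
#' shrink the minimal medium, so MIP >= 0.
#'
#' @param models list of member `metabolic_model`s; each must grow alone on
#'   the full pool.
#' @param params a [carve_params()].
#' @return non-negative integer MIP score; details (the two minimal media)
#'   in `attr(, "details")`.
#' @export
mip_score <- function(models, params = carve_params()) {
  inter <- merge_community(models, isolated_extracellular = TRUE,
                           community_biomass = TRUE, interacting = TRUE)
  noninter <- merge_community(models, isolated_extracellular = TRUE,
                              community_biomass = TRUE, interacting = FALSE)
  mm_non <- minimal_medium(noninter, params = params)
  mm_int <- minimal_medium(inter, params = params)
  out <- mm_non$size - mm_int$size
  attr(out, "details") <- list(non_interacting = mm_non, interacting = mm_int)
  out
}
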
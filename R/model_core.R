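#' Constraint-based metabolic model container
#'
#' A `metabolic_model` is a compartmentalised stoichiometric network: a table
#' of metabolites (with elemental formulas and charges), a table of reactions
#' (stoichiometry, flux bounds in mmol/gDW/h, GPR association, functional
#' kind) and a biomass objective. It is the common currency of the whole
#' package: the carving template (universal model), carved organism models
#' and merged community models are all `metabolic_model` objects.
#'
#' Reaction `kind` is one of `"enzymatic"`, `"transport"`, `"exchange"`,
#' `"spontaneous"`, `"biomass"`. Exchange reactions follow the COBRA sign
#' convention: written as `met_e ->` with the extracellular metabolite as sole
#' substrate, so uptake is negative flux and secretion positive.
#'
#' Metabolites flagged `boundary` (e.g. a biomass sink species) appear in the
#' structural stoichiometric matrix but are exempt from the steady-state
#' mass-balance constraint, mirroring SBML's `boundaryCondition`.
#'
#' @name metabolic_model
NULL

RXN_KINDS <- c("enzymatic", "transport", "exchange", "spontaneous", "biomass")

#' Create a metabolite record
#'
#' @param id unique metabolite id (opaque string; compartment suffixes such as
#'   `_c`/`_e` are a convention, not a requirement).
#' @param compartment id of the compartment the metabolite lives in.
#' @param name human-readable name.
#' @param formula elemental formula string (e.g. `"C6H12O6"`), or `NA` when
#'   unknown.
#' @param charge integer charge.
#' @param compound compartment-free base compound id shared by the same
#'   chemical species across compartments; defaults to `id` with a trailing
#'   `_<compartment>` suffix stripped.
#' @param boundary logical; boundary species are exempt from mass balance.
#' @return a one-row data.frame.
#' @export
metabolite <- function(id, compartment, name = id, formula = NA_character_,
                       charge = 0L, compound = NULL, boundary = FALSE) {
  if (is.null(compound)) {
    compound <- sub(paste0("_", compartment, "$"), "", id)
  }
  data.frame(id = id, name = name, compartment = compartment,
             formula = as.character(formula), charge = as.integer(charge),
             compound = compound, boundary = isTRUE(boundary),
             stringsAsFactors = FALSE)
}

#' Create a reaction record
#'
#' @param id unique reaction id.
#' @param stoich named numeric vector: metabolite id -> coefficient
#'   (negative = substrate, positive = product).
#' @param lb,ub flux bounds in mmol/gDW/h (h^-1 for the biomass reaction).
#' @param gpr a [gpr()] object or a rule string passed to [parse_gpr()].
#' @param kind one of `"enzymatic"`, `"transport"`, `"exchange"`,
#'   `"spontaneous"`, `"biomass"`.
#' @param name,subsystem optional descriptors.
#' @param annot optional named character vector of opaque annotations,
#'   preserved by all I/O dialects.
#' @return a one-row data.frame with list columns `stoich`, `gpr`, `annot`.
#' @export
reaction <- function(id, stoich, lb = -100, ub = 100, gpr = NULL,
                     kind = "enzymatic", name = id, subsystem = "",
                     annot = NULL) {
  kind <- match.arg(kind, RXN_KINDS)
  if (lb > ub) stop("reaction ", id, ": lb > ub")
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) gpr <- parse_gpr("")
  stopifnot(inherits(gpr, "gpr"))
  stoich <- stoich[stoich != 0]
  out <- data.frame(id = id, name = name, lb = as.numeric(lb),
                    ub = as.numeric(ub), kind = kind, subsystem = subsystem,
                    stringsAsFactors = FALSE)
  out$stoich <- list(stoich)
  out$gpr <- list(gpr)
  out$annot <- list(annot)
  out
}

#' Assemble a metabolic model
#'
#' @param id model id.
#' @param compartments character vector of compartment ids.
#' @param mets data.frame of metabolites ([metabolite()] rows, rbind-ed).
#' @param rxns data.frame of reactions ([reaction()] rows, rbind-ed).
#' @param objective id of the objective (biomass) reaction, or `NA` for a
#'   model without one.
#' @param extracellular id of the extracellular compartment (default `"e"`).
#' @param validate run [validate_model()] (default `TRUE`).
#' @return an object of class `metabolic_model`.
#' @export
new_model <- function(id, compartments, mets, rxns, objective = NA_character_,
                      extracellular = "e", validate = TRUE) {
  if (is.null(mets) || nrow(mets) == 0L) {
    mets <- metabolite("x", "c")[0L, ]
  }
  if (is.null(rxns) || nrow(rxns) == 0L) {
    rxns <- reaction("x", c(a = -1))[0L, ]
  }
  rownames(mets) <- NULL
  rownames(rxns) <- NULL
  m <- structure(list(id = id, compartments = unique(compartments),
                      extracellular = extracellular,
                      mets = mets, rxns = rxns, objective = objective),
                 class = "metabolic_model")
  if (validate) validate_model(m)
  m
}

#' Validate model invariants
#'
#' Checks id uniqueness, compartment declarations, stoichiometry resolution,
#' bound ordering, the exchange-reaction invariant (single extracellular
#' substrate) and biomass uniqueness. Called by [new_model()].
#'
#' @param m a `metabolic_model`.
#' @param strict when `FALSE`, the single-species invariants "exchanges act
#'   on the extracellular compartment" and "at most one biomass reaction"
#'   are skipped; community models use this (per-member namespaced
#'   extracellular compartments and one biomass per member).
#' @return `invisible(TRUE)`; stops with an informative error otherwise.
#' @export
validate_model <- function(m, strict = TRUE) {
  stopifnot(inherits(m, "metabolic_model"))
  if (anyDuplicated(m$mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(m$mets$id[duplicated(m$mets$id)]), collapse = ", "))
  }
  if (anyDuplicated(m$rxns$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(m$rxns$id[duplicated(m$rxns$id)]), collapse = ", "))
  }
  bad_comp <- setdiff(m$mets$compartment, m$compartments)
  if (length(bad_comp)) {
    stop("metabolites reference undeclared compartments: ",
         paste(bad_comp, collapse = ", "))
  }
  all_keys <- unique(unlist(lapply(m$rxns$stoich, names), use.names = FALSE))
  missing <- setdiff(all_keys, m$mets$id)
  if (length(missing)) {
    stop("stoichiometry references unknown metabolites: ",
         paste(missing, collapse = ", "))
  }
  if (any(m$rxns$lb > m$rxns$ub)) {
    stop("lb > ub for reactions: ",
         paste(m$rxns$id[m$rxns$lb > m$rxns$ub], collapse = ", "))
  }
  ex <- which(m$rxns$kind == "exchange")
  for (k in ex) {
    st <- m$rxns$stoich[[k]]
    if (length(st) != 1L) {
      stop("exchange reaction ", m$rxns$id[k], " must touch exactly one metabolite")
    }
    met <- m$mets[match(names(st), m$mets$id), ]
    if (strict && !identical(met$compartment, m$extracellular)) {
      stop("exchange reaction ", m$rxns$id[k],
           " must act on an extracellular metabolite")
    }
  }
  if (strict && sum(m$rxns$kind == "biomass") > 1L) {
    stop("more than one biomass reaction declared")
  }
  if (!is.na(m$objective) && !(m$objective %in% m$rxns$id)) {
    stop("objective reaction not found: ", m$objective)
  }
  invisible(TRUE)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  compartments: ", paste(x$compartments, collapse = ", "), "\n", sep = "")
  cat("  metabolites:  ", nrow(x$mets), "\n", sep = "")
  cat("  reactions:    ", nrow(x$rxns),
      " (", sum(x$rxns$kind == "exchange"), " exchanges)\n", sep = "")
  cat("  genes:        ", length(model_genes(x)), "\n", sep = "")
  cat("  objective:    ", x$objective, "\n", sep = "")
  invisible(x)
}

#' All genes referenced by a model's GPRs
#' @param m a `metabolic_model`.
#' @return sorted character vector of gene ids.
#' @export
model_genes <- function(m) {
  sort(unique(unlist(lapply(m$rxns$gpr, gpr_genes), use.names = FALSE)))
}

rxn_idx <- function(m, ids) {
  k <- match(ids, m$rxns$id)
  if (anyNA(k)) stop("unknown reaction id(s): ", paste(ids[is.na(k)], collapse = ", "))
  k
}

met_idx <- function(m, ids) {
  k <- match(ids, m$mets$id)
  if (anyNA(k)) stop("unknown metabolite id(s): ", paste(ids[is.na(k)], collapse = ", "))
  k
}

#' Exchange reactions of a model
#' @param m a `metabolic_model`.
#' @return character vector of reaction ids with `kind == "exchange"`.
#' @export
exchange_reactions <- function(m) m$rxns$id[m$rxns$kind == "exchange"]

#' Base compound imported/exported by each exchange reaction
#' @param m a `metabolic_model`.
#' @return named character vector: exchange reaction id -> compound id.
#' @export
exchange_compounds <- function(m) {
  ex <- which(m$rxns$kind == "exchange")
  mets <- vapply(m$rxns$stoich[ex], function(s) names(s)[1], "")
  stats::setNames(m$mets$compound[match(mets, m$mets$id)], m$rxns$id[ex])
}

#' Set flux bounds on a reaction
#' @param m a `metabolic_model`.
#' @param id reaction id.
#' @param lb,ub new bounds (omit to keep current value).
#' @return the modified model.
#' @export
set_bounds <- function(m, id, lb = NULL, ub = NULL) {
  k <- rxn_idx(m, id)
  if (!is.null(lb)) m$rxns$lb[k] <- lb
  if (!is.null(ub)) m$rxns$ub[k] <- ub
  if (any(m$rxns$lb[k] > m$rxns$ub[k])) stop("set_bounds: lb > ub for ", id)
  m
}

#' Remove reactions (and optionally orphaned metabolites) from a model
#'
#' @param m a `metabolic_model`.
#' @param ids reaction ids to delete.
#' @param prune_orphans also drop metabolites no longer used by any reaction
#'   (default `TRUE`). Genes are implicit in GPRs, so orphaned genes vanish
#'   with their reactions.
#' @return the reduced model.
#' @export
remove_reactions <- function(m, ids, prune_orphans = TRUE) {
  if (length(ids) == 0L) return(m)
  rxn_idx(m, ids)  # errors on unknown ids
  m$rxns <- m$rxns[!(m$rxns$id %in% ids), , drop = FALSE]
  rownames(m$rxns) <- NULL
  if (!is.na(m$objective) && !(m$objective %in% m$rxns$id)) {
    m$objective <- NA_character_
  }
  if (prune_orphans) {
    used <- unique(unlist(lapply(m$rxns$stoich, names), use.names = FALSE))
    m$mets <- m$mets[m$mets$id %in% used, , drop = FALSE]
    rownames(m$mets) <- NULL
  }
  m
}

#' Keep only the named reactions (induced submodel)
#' @inheritParams remove_reactions
#' @param ids reaction ids to keep.
#' @export
keep_reactions <- function(m, ids, prune_orphans = TRUE) {
  remove_reactions(m, setdiff(m$rxns$id, ids), prune_orphans = prune_orphans)
}

#' Add reactions (and any new metabolites) to a model
#' @param m a `metabolic_model`.
#' @param rxns a reaction data.frame ([reaction()] rows).
#' @param mets optional metabolite data.frame for new species.
#' @return the extended, re-validated model.
#' @export
add_reactions <- function(m, rxns, mets = NULL) {
  if (!is.null(mets) && nrow(mets)) {
    mets <- mets[!(mets$id %in% m$mets$id), , drop = FALSE]
    if (nrow(mets)) m$mets <- rbind(m$mets, mets)
  }
  m$rxns <- rbind(m$rxns, rxns)
  rownames(m$rxns) <- NULL
  validate_model(m)
  m
}

#' Build the stoichiometric matrix S
#'
#' Structural matrix: entry (i, j) is reaction j's coefficient for metabolite
#' i, zeros elsewhere. Boundary metabolites are included here (the simulation
#' layer drops their rows when enforcing S v = 0).
#'
#' @param m a `metabolic_model`.
#' @return a sparse [Matrix::Matrix] (metabolites x reactions) with dimnames.
#' @export
build_stoichiometric_matrix <- function(m) {
  nm <- nrow(m$mets)
  nr <- nrow(m$rxns)
  if (nr == 0L || nm == 0L) {
    return(Matrix::Matrix(0, nm, nr, sparse = TRUE,
                          dimnames = list(m$mets$id, m$rxns$id)))
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(nr)) {
    st <- m$rxns$stoich[[j]]
    if (length(st) == 0L) next
    ii <- c(ii, met_idx(m, names(st)))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nm, nr),
                       dimnames = list(m$mets$id, m$rxns$id))
}

#' Growth media
#'
#' A medium maps extracellular base compounds to their maximum uptake rates
#' (mmol/gDW/h, non-negative).
#'
#' @param entries named numeric vector: compound id -> max uptake rate.
#' @return an object of class `medium`.
#' @export
medium <- function(entries = numeric()) {
  entries <- unlist(entries)
  if (length(entries) && (is.null(names(entries)) || any(!nzchar(names(entries))))) {
    stop("medium entries must be named by compound id")
  }
  if (any(entries < 0)) stop("medium uptake rates must be >= 0")
  structure(as.numeric(entries), names = names(entries), class = "medium")
}

#' Constrain a model to a growth medium
#'
#' For every exchange reaction whose compound appears in the medium the lower
#' bound becomes minus the uptake rate; all other exchange lower bounds are
#' closed (0). Upper bounds are untouched so secretion stays open. Medium
#' compounds without an exchange reaction are skipped with a warning.
#'
#' @param m a `metabolic_model` with exchange reactions.
#' @param med a [medium()] object (or named numeric vector).
#' @return the constrained model.
#' @export
apply_medium <- function(m, med) {
  if (!inherits(med, "medium")) med <- medium(med)
  ex <- which(m$rxns$kind == "exchange")
  comp <- exchange_compounds(m)
  missing <- setdiff(names(med), unname(comp))
  if (length(missing)) {
    warning("medium compounds without exchange reaction, skipped: ",
            paste(missing, collapse = ", "))
  }
  m$rxns$lb[ex] <- 0
  for (cpd in intersect(names(med), comp)) {
    hits <- names(comp)[comp == cpd]
    m$rxns$lb[rxn_idx(m, hits)] <- -med[[cpd]]
  }
  m
}

#' Open every exchange reaction (complete medium)
#'
#' All uptake reactions are allowed to carry flux: every exchange lower bound
#' is set to `-rate`.
#'
#' @param m a `metabolic_model`.
#' @param rate uptake rate cap (default 100 mmol/gDW/h, the carving flux cap).
#' @return the relaxed model.
#' @export
complete_medium <- function(m, rate = 100) {
  ex <- which(m$rxns$kind == "exchange")
  m$rxns$lb[ex] <- -abs(rate)
  m
}

#' Read a media table
#'
#' TSV with columns `medium_id`, `compound_id`, `max_uptake`.
#'
#' @param path file path.
#' @return a named list of [medium()] objects, one per `medium_id`.
#' @export
read_media_tsv <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("medium_id", "compound_id", "max_uptake")
  if (!all(need %in% names(tb))) {
    stop("media table must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(tb, tb$medium_id), function(d) {
    medium(stats::setNames(d$max_uptake, d$compound_id))
  })
  out[unique(tb$medium_id)]
}
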
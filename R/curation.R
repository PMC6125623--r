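#' @title Universal-model curation
#' @description Screening and repair steps that turn a draft universal
#'   reaction database into a simulation-ready carving template: elemental
#'   balance checks, thermodynamics-based reversibility assignment, blocked
#'   reaction / dead-end pruning, energy-generating-cycle detection and
#'   biomass-template construction.
#' @name curation
NULL

R_GAS <- 8.314e-3  # kJ mol^-1 K^-1

#' Parse an elemental formula string
#'
#' @param formula e.g. `"C6H12O6"`; `NA` yields `NULL`.
#' @return named integer vector element -> count, or `NULL` when unknown.
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(NULL)
  rx <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  pieces <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(pieces)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  el <- sub("[0-9]*$", "", pieces)
  ct <- sub("^[A-Z][a-z]?", "", pieces)
  ct <- ifelse(nzchar(ct), as.integer(ct), 1L)
  out <- tapply(ct, el, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Elemental balance of a reaction
#'
#' Computes the per-element imbalance `sum(coefficient x count)`. Exchange
#' and biomass reactions are exempt by construction (boundary pseudo
#' reactions) and return an empty map. A participating metabolite without a
#' formula makes the reaction unverifiable: the result is empty with
#' `attr(, "unverifiable") = TRUE` (the reaction is flagged, not removed).
#'
#' @param rxn a one-row reaction data.frame (a row of `model$rxns`).
#' @param formulas named character vector metabolite id -> formula string.
#' @return named numeric vector of nonzero element imbalances (empty iff
#'   balanced or exempt).
#' @export
check_mass_balance <- function(rxn, formulas) {
  if (rxn$kind %in% c("exchange", "biomass")) return(stats::setNames(numeric(0), character(0)))
  st <- rxn$stoich[[1]]
  total <- numeric(0)
  for (met in names(st)) {
    f <- parse_formula(if (met %in% names(formulas)) formulas[[met]] else NA)
    if (is.null(f)) {
      out <- stats::setNames(numeric(0), character(0))
      attr(out, "unverifiable") <- TRUE
      return(out)
    }
    for (el in names(f)) {
      total[el] <- (if (el %in% names(total)) total[[el]] else 0) + st[[met]] * f[[el]]
    }
  }
  total[abs(total) > 1e-9]
}

#' Find atomically unbalanced (and unverifiable) reactions in a model
#'
#' @param m a `metabolic_model`.
#' @return a list with `unbalanced` (named list reaction id -> imbalance map)
#'   and `unverifiable` (reaction ids lacking some formula).
#' @export
find_unbalanced <- function(m) {
  formulas <- stats::setNames(m$mets$formula, m$mets$id)
  unbalanced <- list()
  unverifiable <- character(0)
  for (k in seq_len(nrow(m$rxns))) {
    imb <- check_mass_balance(m$rxns[k, ], formulas)
    if (isTRUE(attr(imb, "unverifiable"))) {
      unverifiable <- c(unverifiable, m$rxns$id[k])
    } else if (length(imb)) {
      unbalanced[[m$rxns$id[k]]] <- imb
    }
  }
  list(unbalanced = unbalanced, unverifiable = unverifiable)
}

#' Range of the Gibbs free energy change over a concentration box
#'
#' Implements `dG_r = dG0_r + RT ln Q`, extremising the reaction quotient Q
#' over the allowed metabolite concentration ranges: the upper bound takes
#' products at their maximum and substrates at their minimum concentration,
#' and vice versa for the lower bound. Concentrations are mM (converted to M
#' inside Q); stoichiometric coefficients become exponents. Water and protons
#' are ignored (transformed-energy convention), as are other compounds listed
#' in `ignore`.
#'
#' @param stoich named numeric vector metabolite id -> coefficient.
#' @param dg0 standard transformed Gibbs energy in kJ/mol; `NA` yields an
#'   undetermined result (`c(NA, NA)`).
#' @param conc named list metabolite id -> `c(cmin, cmax)` in mM; metabolites
#'   absent from the table default to `default_range`.
#' @param temperature in K (default 298.15).
#' @param default_range default concentration range in mM (0.01 to 10).
#' @param ignore compound/metabolite ids excluded from Q (default water and
#'   protons under their conventional ids).
#' @return numeric `c(dg_lo, dg_hi)` in kJ/mol.
#' @export
estimate_dg_bounds <- function(stoich, dg0, conc = list(),
                               temperature = 298.15,
                               default_range = c(0.01, 10),
                               ignore = c("h2o", "h")) {
  if (is.null(dg0) || is.na(dg0)) return(c(NA_real_, NA_real_))
  rt <- R_GAS * temperature
  lo <- dg0
  hi <- dg0
  for (met in names(stoich)) {
    base <- sub("_[^_]+$", "", met)
    if (met %in% ignore || base %in% ignore) next
    rng <- if (!is.null(conc[[met]])) conc[[met]] else default_range
    if (any(rng <= 0) || rng[1] > rng[2]) {
      stop("invalid concentration range for ", met)
    }
    cmin <- rng[1] / 1000  # mM -> M
    cmax <- rng[2] / 1000
    n <- stoich[[met]]
    if (n > 0) {         # product: contributes +n ln c
      hi <- hi + rt * n * log(cmax)
      lo <- lo + rt * n * log(cmin)
    } else {             # substrate: contributes n ln c with n < 0
      hi <- hi + rt * n * log(cmin)
      lo <- lo + rt * n * log(cmax)
    }
  }
  c(lo, hi)
}

#' Assign reaction reversibility from thermodynamic and curated evidence
#'
#' A reaction is made irreversible in the feasible direction whenever its
#' estimated dG range is strictly negative (forward only) or strictly
#' positive (backward only). For reactions with no dG estimate, two
#' heuristics apply, in decreasing precedence after the dG evidence:
#' a curated-direction table, then the rule that ATP-consuming reactions may
#' not run backwards. Bounds are only ever narrowed, never widened.
#'
#' @param m a `metabolic_model`.
#' @param thermo data.frame with columns `reaction_id`, `dG0_kJ_mol`.
#' @param conc optional data.frame with columns `metabolite_id`, `cmin_mM`,
#'   `cmax_mM` (others use the default 0.01-10 mM band).
#' @param curated optional data.frame with columns `reaction_id`, `direction`
#'   in `{"fwd", "rev", "rev_ok"}` (`rev_ok` = leave reversible).
#' @param atp_compound base compound id identifying ATP (default `"atp"`).
#' @param temperature in K.
#' @return the model with narrowed bounds; conflicts between a strict dG sign
#'   and a contradicting curated direction are resolved in favour of dG and
#'   recorded in `attr(, "reversibility_conflicts")`.
#' @export
assign_reversibility <- function(m, thermo = NULL, conc = NULL, curated = NULL,
                                 atp_compound = "atp", temperature = 298.15) {
  conc_list <- list()
  if (!is.null(conc) && nrow(conc)) {
    conc_list <- stats::setNames(
      lapply(seq_len(nrow(conc)), function(k) c(conc$cmin_mM[k], conc$cmax_mM[k])),
      conc$metabolite_id)
  }
  dg0 <- stats::setNames(rep(NA_real_, nrow(m$rxns)), m$rxns$id)
  if (!is.null(thermo) && nrow(thermo)) {
    hit <- intersect(thermo$reaction_id, m$rxns$id)
    dg0[hit] <- thermo$dG0_kJ_mol[match(hit, thermo$reaction_id)]
  }
  cur_dir <- character(0)
  if (!is.null(curated) && nrow(curated)) {
    cur_dir <- stats::setNames(curated$direction, curated$reaction_id)
  }
  atp_ids <- m$mets$id[m$mets$compound == atp_compound]
  conflicts <- character(0)
  for (k in seq_len(nrow(m$rxns))) {
    if (m$rxns$kind[k] %in% c("exchange", "biomass")) next
    rid <- m$rxns$id[k]
    st <- m$rxns$stoich[[k]]
    rng <- estimate_dg_bounds(st, dg0[[rid]], conc_list,
                              temperature = temperature)
    decided <- FALSE
    if (!anyNA(rng)) {
      if (rng[2] < 0) {            # strictly negative: forward only
        m$rxns$lb[k] <- max(m$rxns$lb[k], 0)
        decided <- TRUE
      } else if (rng[1] > 0) {     # strictly positive: backward only
        m$rxns$ub[k] <- min(m$rxns$ub[k], 0)
        decided <- TRUE
      }
      if (decided && rid %in% names(cur_dir)) {
        want <- cur_dir[[rid]]
        if ((rng[2] < 0 && want == "rev") || (rng[1] > 0 && want == "fwd") ||
            want == "rev_ok") {
          conflicts <- c(conflicts, rid)
        }
      }
    }
    if (!decided && rid %in% names(cur_dir)) {
      want <- cur_dir[[rid]]
      if (want == "fwd") m$rxns$lb[k] <- max(m$rxns$lb[k], 0)
      if (want == "rev") m$rxns$ub[k] <- min(m$rxns$ub[k], 0)
      decided <- TRUE               # rev_ok: explicit "leave reversible"
    }
    if (!decided) {
      consumes_atp <- any(names(st) %in% atp_ids & st < 0)
      if (consumes_atp) m$rxns$lb[k] <- max(m$rxns$lb[k], 0)
    }
  }
  if (length(conflicts)) {
    message("curated direction overridden by strict dG sign for: ",
            paste(conflicts, collapse = ", "))
    attr(m, "reversibility_conflicts") <- conflicts
  }
  m
}

#' Blocked reactions and dead-end metabolites
#'
#' Runs FVA on the complete medium (all exchanges open, no growth
#' constraint): a reaction is blocked iff its feasible flux range is
#' `[0, 0]`; a (non-boundary) metabolite is a dead end iff it cannot be both
#' produced and consumed by any feasible flux, i.e. every reaction touching
#' it is blocked.
#'
#' @param m a `metabolic_model`.
#' @param tol flux tolerance (default 1e-9).
#' @param open_exchanges open all exchanges first (default `TRUE`).
#' @return list with `blocked` (reaction ids) and `dead_ends` (metabolite
#'   ids).
#' @export
find_blocked <- function(m, tol = 1e-9, open_exchanges = TRUE) {
  mm <- if (open_exchanges) complete_medium(m) else m
  v <- fva(mm)
  blocked <- v$reaction[abs(v$min) <= tol & abs(v$max) <= tol]
  alive <- !(m$rxns$id %in% blocked)
  touched_alive <- unique(unlist(lapply(m$rxns$stoich[alive], names),
                                 use.names = FALSE))
  dead <- m$mets$id[!m$mets$boundary & !(m$mets$id %in% touched_alive)]
  list(blocked = blocked, dead_ends = dead)
}

#' Remove blocked reactions and dead-end metabolites to fixpoint
#'
#' Deletes everything [find_blocked()] reports and iterates until nothing is
#' found. Removal never changes the feasible flux space, so growth capability
#' on the complete medium is preserved.
#'
#' @inheritParams find_blocked
#' @param max_iter safety cap on iterations.
#' @return the pruned model, with the removed ids in `attr(, "removed")`.
#' @export
prune_blocked <- function(m, tol = 1e-9, max_iter = 10L) {
  removed_r <- character(0)
  removed_m <- character(0)
  for (it in seq_len(max_iter)) {
    fb <- find_blocked(m, tol = tol)
    if (length(fb$blocked) == 0L && length(fb$dead_ends) == 0L) break
    removed_r <- c(removed_r, fb$blocked)
    removed_m <- c(removed_m, fb$dead_ends)
    if (length(fb$blocked)) m <- remove_reactions(m, fb$blocked)
    m$mets <- m$mets[!(m$mets$id %in% fb$dead_ends), , drop = FALSE]
    rownames(m$mets) <- NULL
  }
  attr(m, "removed") <- list(reactions = removed_r, metabolites = removed_m)
  m
}

#' Detect energy-generating cycles
#'
#' With every exchange closed (`lb = ub = 0`) no energy source is available,
#' so any ability to drive the ATP-maintenance reaction reveals a
#' thermodynamically infeasible cycle. The maintenance flux is maximised by
#' LP; if the optimum exceeds `tol`, the support (nonzero-flux reactions) of
#' one optimal solution is reported as the offending set.
#'
#' @param m a `metabolic_model`.
#' @param maintenance_id id of the ATP-hydrolysis (maintenance) reaction.
#' @param tol detection tolerance (default 1e-6 mmol/gDW/h, above LP solver
#'   noise).
#' @return list with `detected` (logical), `atp_flux` (the optimum) and
#'   `cycles` (list of reaction-id vectors; one support set when detected).
#' @export
detect_energy_cycles <- function(m, maintenance_id = "ATPM", tol = 1e-6) {
  if (!(maintenance_id %in% m$rxns$id)) {
    stop("no ATP-maintenance reaction '", maintenance_id,
         "' in the model; pass its id via maintenance_id")
  }
  ex <- m$rxns$kind == "exchange"
  m$rxns$lb[ex] <- 0
  m$rxns$ub[ex] <- 0
  res <- fba(m, objective = maintenance_id)
  if (!identical(res$status, "optimal")) {
    stop("energy-cycle LP did not solve: ", res$status)
  }
  if (res$objective > tol) {
    support <- names(res$fluxes)[abs(res$fluxes) > tol]
    list(detected = TRUE, atp_flux = res$objective, cycles = list(support))
  } else {
    list(detected = FALSE, atp_flux = res$objective, cycles = list())
  }
}

#' Build a biomass template from a mass-fraction composition
#'
#' Replaces the universe's biomass reaction with one draining the given
#' components. Mass fractions are renormalised to sum to 1 and converted to
#' molar coefficients `c_i = 1000 f_i / MW_i` (mmol/gDW), so that
#' `sum(c_i MW_i) / 1000 = 1` g/gDW exactly: a unit biomass flux drains one
#' gram of dry weight per hour.
#'
#' @param universe a `metabolic_model` with a biomass reaction.
#' @param components data.frame with columns `metabolite_id`, `mass_fraction`
#'   (g/gDW) and `mw` (g/mol).
#' @param template_id id for the resulting template model.
#' @return the template model.
#' @export
build_template <- function(universe, components, template_id = universe$id) {
  need <- c("metabolite_id", "mass_fraction", "mw")
  if (!all(need %in% names(components))) {
    stop("components must have columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(components$metabolite_id, universe$mets$id)
  if (length(missing)) {
    stop("unknown biomass component metabolites: ",
         paste(missing, collapse = ", "))
  }
  if (any(components$mw <= 0) || any(components$mass_fraction < 0)) {
    stop("molecular weights must be positive and mass fractions non-negative")
  }
  frac <- components$mass_fraction / sum(components$mass_fraction)
  coef <- 1000 * frac / components$mw
  bk <- which(universe$rxns$kind == "biomass")
  if (length(bk) != 1L) stop("universe must have exactly one biomass reaction")
  old <- universe$rxns$stoich[[bk]]
  st <- stats::setNames(-coef, components$metabolite_id)
  # keep the biomass sink product (boundary species), if the template had one
  prod <- names(old)[old > 0]
  prod <- prod[universe$mets$boundary[match(prod, universe$mets$id)]]
  if (length(prod)) st <- c(st, stats::setNames(rep(1, length(prod)), prod))
  universe$rxns$stoich[[bk]] <- st
  universe$id <- template_id
  validate_model(universe)
  universe
}

#' Read a thermodynamics table (`reaction_id`, `dG0_kJ_mol`)
#' @param path TSV file path.
#' @export
read_thermo_tsv <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "dG0_kJ_mol") %in% names(tb)))
  tb
}

#' Read a concentration-bounds table (`metabolite_id`, `cmin_mM`, `cmax_mM`)
#' @param path TSV file path.
#' @export
read_concentrations_tsv <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite_id", "cmin_mM", "cmax_mM") %in% names(tb)))
  if (any(tb$cmin_mM <= 0) || any(tb$cmin_mM > tb$cmax_mM)) {
    stop("concentration bounds must satisfy 0 < cmin <= cmax")
  }
  tb
}

#' Read a biomass-composition table (`metabolite_id`, `mass_fraction`, `mw`)
#' @param path TSV file path.
#' @export
read_biomass_tsv <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite_id", "mass_fraction", "mw") %in% names(tb)))
  tb
}
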
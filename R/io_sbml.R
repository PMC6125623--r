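#' @title Model I/O: SBML (FBC2 and legacy COBRA) and native JSON
#' @description Models are exchanged as SBML Level 3 + Flux Balance
#'   Constraints v2 (the current standard), as legacy Level 2 COBRA-dialect
#'   SBML (GPRs in `GENE_ASSOCIATION` notes, bounds in kineticLaw
#'   parameters), or as the package's native JSON dialect. Reading a file
#'   written by any dialect restores ids, stoichiometry, bounds, GPR
#'   semantics, compartment assignment, reaction kinds and opaque
#'   annotations. Identifiers are prefixed `M_`/`R_`/`G_` on write and
#'   stripped on read, following the BiGG convention.
#' @name model-io
NULL

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBML_L2_NS <- "http://www.sbml.org/sbml/level2"
XHTML_NS <- "http://www.w3.org/1999/xhtml"

RESERVED_NOTES <- c("KIND", "SUBSYSTEM", "COMPOUND", "FORMULA", "CHARGE",
                    "EXTRACELLULAR", "GENE_ASSOCIATION", "MEMBERS",
                    "BOUNDARY")

sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

num17 <- function(v) vapply(v, function(x) sprintf("%.17g", x), "")

#' Write a metabolic model to file
#'
#' @param m a `metabolic_model`.
#' @param path output file path.
#' @param dialect `"sbml-fbc2"`, `"sbml-cobra"` or `"native-json"`; the
#'   default picks native JSON for a `.json` extension and FBC2 otherwise.
#' @return the path, invisibly.
#' @export
write_model <- function(m, path, dialect = c("auto", "sbml-fbc2",
                                             "sbml-cobra", "native-json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE))
      "native-json" else "sbml-fbc2"
  }
  switch(dialect,
         "native-json" = write_model_json(m, path),
         "sbml-fbc2" = write_model_sbml_fbc2(m, path),
         "sbml-cobra" = write_model_sbml_cobra(m, path))
  invisible(path)
}

#' Read a metabolic model from file
#'
#' @param path input file path.
#' @param dialect as in [write_model()]; `"auto"` sniffs JSON vs SBML and
#'   the FBC namespace.
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, dialect = c("auto", "sbml-fbc2", "sbml-cobra",
                                         "native-json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (dialect == "auto") {
    first <- readChar(path, 256L, useBytes = TRUE)
    if (grepl("^\\s*\\{", first)) {
      dialect <- "native-json"
    } else {
      dialect <- if (grepl(SBML_FBC_NS, paste(readLines(path, n = 5,
                                                        warn = FALSE),
                                              collapse = ""), fixed = TRUE))
        "sbml-fbc2" else "sbml-cobra"
    }
  }
  m <- switch(dialect,
              "native-json" = read_model_json(path),
              "sbml-fbc2" = read_model_sbml(path, fbc = TRUE),
              "sbml-cobra" = read_model_sbml(path, fbc = FALSE))
  validate_model(m, strict = FALSE)
  m
}

# -- notes helpers -----------------------------------------------------------

notes_lines <- function(kv) {
  kv <- kv[!is.na(kv) & nzchar(kv)]
  if (length(kv) == 0L) return(NULL)
  paste0(names(kv), ": ", kv)
}

add_notes <- function(node, kv) {
  lines <- notes_lines(kv)
  if (is.null(lines)) return(invisible(NULL))
  notes <- xml2::xml_add_child(node, "notes")
  body <- xml2::xml_add_child(notes, "body", xmlns = XHTML_NS)
  for (ln in lines) xml2::xml_add_child(body, "p", ln)
  invisible(NULL)
}

parse_notes <- function(node) {
  ps <- xml2::xml_find_all(node, ".//*[local-name()='notes']//*[local-name()='p']")
  out <- character(0)
  for (p in ps) {
    txt <- trimws(xml2::xml_text(p))
    mt <- regmatches(txt, regexec("^([^:]+):\\s*(.*)$", txt))[[1]]
    if (length(mt) == 3L) out[trimws(mt[2])] <- mt[3]
  }
  out
}

xattr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  for (nm in c(name, paste0("fbc:", name))) {
    if (nm %in% names(at)) return(unname(at[[nm]]))
  }
  NA_character_
}

strip_prefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

# -- FBC2 --------------------------------------------------------------------

write_model_sbml_fbc2 <- function(m, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_CORE_NS,
                            "xmlns:fbc" = SBML_FBC_NS,
                            level = "3", version = "1",
                            "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sid(m$id),
                             "fbc:strict" = "true")
  model_notes <- c(EXTRACELLULAR = m$extracellular)
  if (!is.null(m$members)) {
    model_notes["MEMBERS"] <- paste(m$members, collapse = ";")
  }
  add_notes(mdl, model_notes)
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in m$compartments) {
    xml2::xml_add_child(loc, "compartment", id = sid(cp), constant = "true")
  }
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (k in seq_len(nrow(m$mets))) {
    r <- m$mets[k, ]
    sp <- xml2::xml_add_child(los, "species", id = paste0("M_", sid(r$id)),
                              name = r$name, compartment = sid(r$compartment),
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = tolower(as.character(r$boundary)),
                              constant = "false",
                              "fbc:charge" = as.character(r$charge))
    if (!is.na(r$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", r$formula)
    }
    add_notes(sp, c(COMPOUND = r$compound))
  }
  # flux-bound parameters, deduplicated by value
  vals <- sort(unique(c(m$rxns$lb, m$rxns$ub)))
  pid <- stats::setNames(paste0("fb_", seq_along(vals)), num17(vals))
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in vals) {
    xml2::xml_add_child(lop, "parameter", id = pid[[num17(v)]],
                        value = num17(v), constant = "true",
                        "sboTerm" = "SBO:0000626")
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  genes <- character(0)
  for (k in seq_len(nrow(m$rxns))) {
    r <- m$rxns[k, ]
    rx <- xml2::xml_add_child(lor, "reaction", id = paste0("R_", sid(r$id)),
                              name = r$name,
                              reversible = tolower(as.character(r$lb < 0)),
                              fast = "false",
                              "fbc:lowerFluxBound" = pid[[num17(r$lb)]],
                              "fbc:upperFluxBound" = pid[[num17(r$ub)]])
    add_notes(rx, c(c(KIND = r$kind,
                      SUBSYSTEM = if (nzchar(r$subsystem)) r$subsystem else NA),
                    r$annot[[1]]))
    st <- r$stoich[[1]]
    subs <- st[st < 0]
    prods <- st[st > 0]
    if (length(subs)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (met in names(subs)) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", sid(met)),
                            stoichiometry = num17(-subs[[met]]),
                            constant = "true")
      }
    }
    if (length(prods)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (met in names(prods)) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", sid(met)),
                            stoichiometry = num17(prods[[met]]),
                            constant = "true")
      }
    }
    g <- r$gpr[[1]]
    if (!gpr_is_empty(g)) {
      genes <- union(genes, gpr_genes(g))
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      add_gpa_node(gpa, g)
    }
  }
  loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  obj <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                             "fbc:type" = "maximize")
  if (!is.na(m$objective)) {
    lfo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", sid(m$objective)),
                        "fbc:coefficient" = "1")
  }
  if (length(genes)) {
    log_ <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in sort(genes)) {
      xml2::xml_add_child(log_, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sid(g)), "fbc:label" = g)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

add_gpa_node <- function(parent, g) {
  ref <- function(node, gene) {
    xml2::xml_add_child(node, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", sid(gene)))
  }
  complex_node <- function(node, cx) {
    if (length(cx) == 1L) ref(node, cx) else {
      andn <- xml2::xml_add_child(node, "fbc:and")
      for (gene in cx) ref(andn, gene)
    }
  }
  if (length(g$complexes) == 1L) {
    complex_node(parent, g$complexes[[1]])
  } else {
    orn <- xml2::xml_add_child(parent, "fbc:or")
    for (cx in g$complexes) complex_node(orn, cx)
  }
}

# -- legacy COBRA (SBML L2) --------------------------------------------------

write_model_sbml_cobra <- function(m, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_L2_NS, level = "2",
                            version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = sid(m$id))
  model_notes <- c(EXTRACELLULAR = m$extracellular)
  if (!is.null(m$members)) {
    model_notes["MEMBERS"] <- paste(m$members, collapse = ";")
  }
  add_notes(mdl, model_notes)
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in m$compartments) {
    xml2::xml_add_child(loc, "compartment", id = sid(cp))
  }
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (k in seq_len(nrow(m$mets))) {
    r <- m$mets[k, ]
    sp <- xml2::xml_add_child(los, "species", id = paste0("M_", sid(r$id)),
                              name = r$name, compartment = sid(r$compartment),
                              charge = as.character(r$charge),
                              boundaryCondition = tolower(as.character(r$boundary)))
    add_notes(sp, c(COMPOUND = r$compound,
                    FORMULA = if (is.na(r$formula)) NA else r$formula))
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (k in seq_len(nrow(m$rxns))) {
    r <- m$rxns[k, ]
    rx <- xml2::xml_add_child(lor, "reaction", id = paste0("R_", sid(r$id)),
                              name = r$name,
                              reversible = tolower(as.character(r$lb < 0)))
    gstr <- gpr_to_string(r$gpr[[1]])
    add_notes(rx, c(c(GENE_ASSOCIATION = if (nzchar(gstr)) gstr else NA,
                      KIND = r$kind,
                      SUBSYSTEM = if (nzchar(r$subsystem)) r$subsystem else NA),
                    r$annot[[1]]))
    st <- r$stoich[[1]]
    subs <- st[st < 0]
    prods <- st[st > 0]
    if (length(subs)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (met in names(subs)) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", sid(met)),
                            stoichiometry = num17(-subs[[met]]))
      }
    }
    if (length(prods)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (met in names(prods)) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", sid(met)),
                            stoichiometry = num17(prods[[met]]))
      }
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    lopar <- xml2::xml_add_child(kl, "listOfParameters")
    xml2::xml_add_child(lopar, "parameter", id = "LOWER_BOUND",
                        value = num17(r$lb))
    xml2::xml_add_child(lopar, "parameter", id = "UPPER_BOUND",
                        value = num17(r$ub))
    xml2::xml_add_child(lopar, "parameter", id = "OBJECTIVE_COEFFICIENT",
                        value = if (!is.na(m$objective) &&
                                      identical(r$id, m$objective)) "1" else "0")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# -- shared reader -----------------------------------------------------------

read_model_sbml <- function(path, fbc = TRUE) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("invalid SBML file '", path, "': ", conditionMessage(e))
  })
  mdl <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)
  model_notes <- parse_notes_shallow(mdl)
  comps <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfCompartments']/*[local-name()='compartment']")
  comp_ids <- vapply(comps, function(x) xattr(x, "id"), "")
  sps <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  mets <- NULL
  if (length(sps)) {
    mets <- do.call(rbind, lapply(sps, function(x) {
      id <- strip_prefix(xattr(x, "id"), "M_")
      notes <- parse_notes(x)
      charge <- xattr(x, "charge")
      formula <- xattr(x, "chemicalFormula")
      if (is.na(formula) && "FORMULA" %in% names(notes)) {
        formula <- notes[["FORMULA"]]
      }
      metabolite(id, xattr(x, "compartment"),
                 name = if (is.na(xattr(x, "name"))) id else xattr(x, "name"),
                 formula = formula,
                 charge = if (is.na(charge)) 0L else as.integer(charge),
                 compound = if ("COMPOUND" %in% names(notes))
                   notes[["COMPOUND"]] else NULL,
                 boundary = identical(xattr(x, "boundaryCondition"), "true"))
    }))
  }
  # FBC2 machinery: flux-bound parameters, gene labels, active objective
  params <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pvals <- stats::setNames(
    suppressWarnings(as.numeric(vapply(params, function(x) xattr(x, "value"), ""))),
    vapply(params, function(x) xattr(x, "id"), ""))
  gps <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  glabel <- stats::setNames(vapply(gps, function(x) xattr(x, "label"), ""),
                            vapply(gps, function(x) xattr(x, "id"), ""))
  objective <- NA_character_
  fo <- xml2::xml_find_first(mdl, ".//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing")) {
    objective <- strip_prefix(xattr(fo, "reaction"), "R_")
  }
  rxs <- xml2::xml_find_all(mdl, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  rxns <- NULL
  if (length(rxs)) {
    rxns <- do.call(rbind, lapply(rxs, function(x) {
      id <- strip_prefix(xattr(x, "id"), "R_")
      notes <- parse_notes(x)
      st <- numeric(0)
      for (sr in xml2::xml_find_all(x, ".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']")) {
        met <- strip_prefix(xattr(sr, "species"), "M_")
        st[met] <- -as.numeric(xattr(sr, "stoichiometry"))
      }
      for (sr in xml2::xml_find_all(x, ".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']")) {
        met <- strip_prefix(xattr(sr, "species"), "M_")
        coef <- as.numeric(xattr(sr, "stoichiometry"))
        st[met] <- if (met %in% names(st)) st[[met]] + coef else coef
      }
      lb <- ub <- NA_real_
      lbp <- xattr(x, "lowerFluxBound")
      ubp <- xattr(x, "upperFluxBound")
      if (!is.na(lbp)) lb <- pvals[[lbp]]
      if (!is.na(ubp)) ub <- pvals[[ubp]]
      for (pp in xml2::xml_find_all(x, ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")) {
        pidv <- xattr(pp, "id")
        if (identical(pidv, "LOWER_BOUND")) lb <- as.numeric(xattr(pp, "value"))
        if (identical(pidv, "UPPER_BOUND")) ub <- as.numeric(xattr(pp, "value"))
        if (identical(pidv, "OBJECTIVE_COEFFICIENT") &&
              as.numeric(xattr(pp, "value")) != 0) {
          objective <<- id
        }
      }
      if (is.na(lb)) lb <- if (identical(xattr(x, "reversible"), "false")) 0 else -1000
      if (is.na(ub)) ub <- 1000
      g <- parse_gpr("")
      gpa <- xml2::xml_find_first(x, ".//*[local-name()='geneProductAssociation']")
      if (!inherits(gpa, "xml_missing")) {
        g <- parse_gpr(gpa_to_string(gpa, glabel))
      } else if ("GENE_ASSOCIATION" %in% names(notes)) {
        g <- parse_gpr(notes[["GENE_ASSOCIATION"]])
      }
      an <- notes[setdiff(names(notes), RESERVED_NOTES)]
      reaction(id, st, lb = lb, ub = ub, gpr = g,
               kind = if ("KIND" %in% names(notes)) notes[["KIND"]] else "enzymatic",
               name = if (is.na(xattr(x, "name"))) id else xattr(x, "name"),
               subsystem = if ("SUBSYSTEM" %in% names(notes))
                 notes[["SUBSYSTEM"]] else "",
               annot = if (length(an)) an else NULL)
    }))
  }
  extracellular <- if ("EXTRACELLULAR" %in% names(model_notes))
    model_notes[["EXTRACELLULAR"]] else "e"
  m <- new_model(xattr(mdl, "id"), comp_ids, mets, rxns,
                 objective = objective, extracellular = extracellular,
                 validate = FALSE)
  if ("MEMBERS" %in% names(model_notes)) {
    m$members <- strsplit(model_notes[["MEMBERS"]], ";", fixed = TRUE)[[1]]
    class(m) <- c("community_model", class(m))
  }
  m
}

# model-level notes only (exclude notes nested in species/reactions)
parse_notes_shallow <- function(mdl) {
  out <- character(0)
  for (child in xml2::xml_children(mdl)) {
    if (xml2::xml_name(child) == "notes") {
      ps <- xml2::xml_find_all(child, ".//*[local-name()='p']")
      for (p in ps) {
        txt <- trimws(xml2::xml_text(p))
        mt <- regmatches(txt, regexec("^([^:]+):\\s*(.*)$", txt))[[1]]
        if (length(mt) == 3L) out[trimws(mt[2])] <- mt[3]
      }
    }
  }
  out
}

gpa_to_string <- function(node, glabel) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xattr(node, "geneProduct")
    lbl <- if (gid %in% names(glabel) && nzchar(glabel[[gid]])) glabel[[gid]]
           else strip_prefix(gid, "G_")
    return(lbl)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, gpa_to_string, "", glabel = glabel)
  if (nm == "and") return(paste0("(", paste(parts, collapse = " and "), ")"))
  if (nm == "or") return(paste0("(", paste(parts, collapse = " or "), ")"))
  # geneProductAssociation wrapper
  paste(parts, collapse = " ")
}
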
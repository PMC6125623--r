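#' @title Native JSON model dialect
#' @description A plain JSON serialisation of `metabolic_model`, designed for
#'   fixtures and tests where hand-writing SBML would be error-prone. Schema
#'   (one object): `id`, `extracellular`, `compartments` (array of strings),
#'   `metabolites` (array of objects with `id`, `name`, `compartment`,
#'   `formula`, `charge`, `compound`, `boundary`), `reactions` (array of
#'   objects with `id`, `name`, `lb`, `ub`, `kind`, `subsystem`,
#'   `stoichiometry` (object metabolite id -> coefficient), `gpr` (rule
#'   string), `annotations` (object, optional)), `objective`.
#' @name native-json
NULL

write_model_json <- function(m, path) {
  mets <- lapply(seq_len(nrow(m$mets)), function(k) {
    r <- m$mets[k, ]
    list(id = r$id, name = r$name, compartment = r$compartment,
         formula = if (is.na(r$formula)) NULL else r$formula,
         charge = r$charge, compound = r$compound, boundary = r$boundary)
  })
  rxns <- lapply(seq_len(nrow(m$rxns)), function(k) {
    r <- m$rxns[k, ]
    out <- list(id = r$id, name = r$name, lb = r$lb, ub = r$ub,
                kind = r$kind, subsystem = r$subsystem,
                stoichiometry = as.list(r$stoich[[1]]),
                gpr = gpr_to_string(r$gpr[[1]]))
    an <- r$annot[[1]]
    if (!is.null(an) && length(an)) out$annotations <- as.list(an)
    out
  })
  doc <- list(id = m$id, extracellular = m$extracellular,
              compartments = m$compartments, metabolites = mets,
              reactions = rxns, objective = m$objective)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("invalid JSON model file '", path,
                                           "': ", conditionMessage(e)))
  get_chr <- function(x, field, default = NA_character_) {
    if (is.null(x[[field]])) default else as.character(x[[field]])
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(x) {
    metabolite(x$id, x$compartment, name = get_chr(x, "name", x$id),
               formula = get_chr(x, "formula"),
               charge = if (is.null(x$charge)) 0L else as.integer(x$charge),
               compound = x$compound, boundary = isTRUE(x$boundary))
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(x) {
    an <- if (is.null(x$annotations)) NULL else unlist(x$annotations)
    reaction(x$id, unlist(x$stoichiometry), lb = x$lb, ub = x$ub,
             gpr = get_chr(x, "gpr", ""), kind = get_chr(x, "kind", "enzymatic"),
             name = get_chr(x, "name", x$id),
             subsystem = get_chr(x, "subsystem", ""), annot = an)
  }))
  new_model(doc$id, unlist(doc$compartments), mets, rxns,
            objective = get_chr(doc, "objective"),
            extracellular = get_chr(doc, "extracellular", "e"),
            validate = FALSE)
}
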
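#' Gene-protein-reaction (GPR) expressions
#'
#' A GPR associates a reaction with the genes able to catalyse it: `and`
#' joins subunits of a protein complex, `or` joins isozymes (alternative
#' complexes). Expressions are stored in disjunctive normal form (DNF): a set
#' of complexes, each a non-empty set of gene ids. An empty expression (no
#' complexes) means "no gene association" (spontaneous, exchange or biomass
#' pseudo-reactions).
#'
#' @param complexes a list of character vectors, one per complex.
#' @return an object of class `gpr`.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
gpr <- function(complexes = list()) {
  cx <- lapply(complexes, function(g) sort(unique(as.character(g))))
  cx <- cx[vapply(cx, length, 1L) > 0L]
  cx <- unique(cx)
  cx <- cx[order(vapply(cx, paste, "", collapse = "\r"))]
  structure(list(complexes = cx), class = "gpr")
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}

#' Parse a boolean gene-association string into DNF
#'
#' Accepts case-insensitive `and`/`or` and parentheses over gene tokens, the
#' grammar used by BiGG-style rules. The expression is expanded into
#' disjunctive normal form by distributing `and` over `or`.
#'
#' @param text the boolean expression; an empty or all-whitespace string
#'   yields an empty association.
#' @return a [gpr()] object.
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text) || !nzchar(trimws(text))) {
    return(gpr())
  }
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  res <- gpr_parse_or(st)
  if (st$pos <= nrow(st$toks)) {
    stop("malformed GPR expression: unexpected token '",
         st$toks$text[st$pos], "' at position ", st$toks$at[st$pos])
  }
  gpr(res)
}

gpr_tokenize <- function(text) {
  out <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      out[[length(out) + 1L]] <- list(type = ch, text = ch, at = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(text, i, n), regexpr("^[^()[:space:]]+", substr(text, i, n)))
    word <- m[[1]]
    type <- switch(tolower(word), "and" = "AND", "or" = "OR", "GENE")
    out[[length(out) + 1L]] <- list(type = type, text = word, at = i)
    i <- i + nchar(word)
  }
  if (length(out) == 0L) stop("malformed GPR expression: no tokens")
  data.frame(type = vapply(out, `[[`, "", "type"),
             text = vapply(out, `[[`, "", "text"),
             at = vapply(out, `[[`, 1L, "at"))
}

gpr_peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$type[st$pos] else ""

gpr_parse_or <- function(st) {
  terms <- gpr_parse_and(st)
  while (gpr_peek(st) == "OR") {
    st$pos <- st$pos + 1L
    terms <- c(terms, gpr_parse_and(st))
  }
  terms
}

gpr_parse_and <- function(st) {
  acc <- gpr_parse_atom(st)
  while (gpr_peek(st) == "AND") {
    st$pos <- st$pos + 1L
    rhs <- gpr_parse_atom(st)
    # distribute AND over OR: cross-product union of complexes
    acc <- unlist(lapply(acc, function(a) lapply(rhs, function(b) union(a, b))),
                  recursive = FALSE)
  }
  acc
}

gpr_parse_atom <- function(st) {
  tp <- gpr_peek(st)
  if (tp == "GENE") {
    g <- st$toks$text[st$pos]
    st$pos <- st$pos + 1L
    return(list(g))
  }
  if (tp == "(") {
    open_at <- st$toks$at[st$pos]
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (gpr_peek(st) != ")") {
      stop("malformed GPR expression: unclosed '(' at position ", open_at)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  at <- if (st$pos <= nrow(st$toks)) st$toks$at[st$pos] else NA_integer_
  txt <- if (st$pos <= nrow(st$toks)) st$toks$text[st$pos] else "<end of input>"
  stop("malformed GPR expression: unexpected token '", txt, "' at position ", at)
}

#' Serialize a GPR expression
#'
#' Produces a sum-of-products string that [parse_gpr()] maps back to the same
#' DNF (round-trip identity up to complex ordering).
#'
#' @param x a [gpr()] object.
#' @return a character scalar; `""` for an empty association.
#' @export
gpr_to_string <- function(x) {
  stopifnot(inherits(x, "gpr"))
  if (length(x$complexes) == 0L) return("")
  parts <- vapply(x$complexes, function(cx) {
    s <- paste(cx, collapse = " and ")
    if (length(cx) > 1L && length(x$complexes) > 1L) paste0("(", s, ")") else s
  }, "")
  paste(parts, collapse = " or ")
}

#' Evaluate a GPR against a set of present genes
#'
#' DNF semantics: satisfied iff at least one complex has all of its subunit
#' genes present. An empty association evaluates to `TRUE` (no genetic
#' requirement).
#'
#' @param x a [gpr()] object.
#' @param genes character vector of present gene ids.
#' @export
eval_gpr <- function(x, genes) {
  stopifnot(inherits(x, "gpr"))
  if (length(x$complexes) == 0L) return(TRUE)
  any(vapply(x$complexes, function(cx) all(cx %in% genes), NA))
}

#' Genes referenced by a GPR expression
#' @param x a [gpr()] object.
#' @return sorted character vector of gene ids.
#' @export
gpr_genes <- function(x) {
  stopifnot(inherits(x, "gpr"))
  sort(unique(unlist(x$complexes, use.names = FALSE)))
}

#' Restrict a GPR to the complexes that survive a gene deletion
#' @param x a [gpr()] object.
#' @param drop character vector of deleted gene ids.
#' @return a [gpr()] with the complexes containing any deleted gene removed.
#' @keywords internal
gpr_without_genes <- function(x, drop) {
  gpr(Filter(function(cx) !any(cx %in% drop), x$complexes))
}

gpr_is_empty <- function(x) length(x$complexes) == 0L
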
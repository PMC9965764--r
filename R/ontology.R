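#' Chemical class ontology
#'
#' A single-parent class hierarchy in the style of ChemOnt: every term has a
#' unique id, a name, a parent (except the root) and a level equal to its
#' parent's level plus one. By convention the root (level 0) is named
#' "Organic compounds".
#'
#' @param terms data.frame with columns `term_id`, `name`, `parent_id`
#'   (`NA` for the root) and `level`.
#' @return an object of class `chem_ontology`.
#' @export
chem_ontology <- function(terms) {
  chk(is.data.frame(terms) && all(c("term_id", "name", "parent_id", "level") %in% names(terms)),
      "terms needs columns term_id, name, parent_id, level")
  terms$term_id <- as.character(terms$term_id)
  terms$parent_id <- as.character(terms$parent_id)
  terms$parent_id[terms$parent_id %in% c("", "NA")] <- NA_character_
  chk(!anyDuplicated(terms$term_id), "duplicate term ids")
  roots <- terms$term_id[is.na(terms$parent_id)]
  chk(length(roots) == 1L, "ontology must have exactly one root, found ", length(roots))
  chk(terms$level[terms$term_id == roots] == 0L, "root term must have level 0")
  chk(all(terms$parent_id[!is.na(terms$parent_id)] %in% terms$term_id),
      "parent_id refers to unknown term(s)")
  lev <- stats::setNames(terms$level, terms$term_id)
  nonroot <- terms[!is.na(terms$parent_id), , drop = FALSE]
  bad <- nonroot$term_id[lev[nonroot$term_id] != lev[nonroot$parent_id] + 1L]
  chk(length(bad) == 0L, "level(child) != level(parent) + 1 for: ",
      paste(bad, collapse = ", "))
  rownames(terms) <- NULL
  structure(list(terms = terms, root = roots), class = "chem_ontology")
}

#' @export
print.chem_ontology <- function(x, ...) {
  cat(sprintf("chem_ontology: %d terms, %d levels, root '%s'\n",
              nrow(x$terms), max(x$terms$level) + 1L,
              x$terms$name[x$terms$term_id == x$root]))
  invisible(x)
}

#' Read an ontology from a TSV of (term_id, name, parent_id, level)
#'
#' @param path TSV path; the root row has an empty/NA `parent_id`.
#' @return a [chem_ontology()].
#' @export
read_ontology <- function(path) {
  chk(file.exists(path), "no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  chem_ontology(df)
}

#' @rdname read_ontology
#' @param ontology a [chem_ontology()].
#' @export
write_ontology <- function(ontology, path) {
  stopifnot(inherits(ontology, "chem_ontology"))
  utils::write.table(ontology$terms, path, sep = "\t", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' Root-to-term path through the ontology
#'
#' @param ontology a [chem_ontology()].
#' @param term_id a term id.
#' @return character vector of term ids from the root down to `term_id`
#'   (inclusive).
#' @export
ancestors <- function(ontology, term_id) {
  stopifnot(inherits(ontology, "chem_ontology"))
  chk(term_id %in% ontology$terms$term_id, "unknown ontology term: ", term_id)
  parent <- stats::setNames(ontology$terms$parent_id, ontology$terms$term_id)
  path <- character(0)
  cur <- term_id
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- parent[[cur]]
  }
  path
}

#' Terms at a given level of the ontology
#' @param ontology a [chem_ontology()].
#' @param level integer level (0 = root; 1 = superclasses).
#' @return character vector of term ids.
#' @export
terms_at_level <- function(ontology, level) {
  stopifnot(inherits(ontology, "chem_ontology"))
  ontology$terms$term_id[ontology$terms$level == level]
}
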
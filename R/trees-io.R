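#' Taxon trees (phylograms and dendrograms)
#'
#' Thin wrapper around [ape::phylo] keeping track of the tree kind:
#' `"phylogram"` for trees whose branch lengths are evolutionary distances
#' (e.g. a DNA reference phylogeny) and `"dendrogram"` for ultrametric
#' cluster trees whose node heights are merge heights. The kind decides the
#' cophenetic convention in [cophenetic_matrix()].
#'
#' @param phylo an [ape::phylo] object (rooted, unique tip labels).
#' @param kind `"phylogram"` or `"dendrogram"`.
#' @return an object of class `taxon_tree`.
#' @export
taxon_tree <- function(phylo, kind = c("phylogram", "dendrogram")) {
  kind <- match.arg(kind)
  chk(inherits(phylo, "phylo"), "phylo must be an ape 'phylo' object")
  chk(!anyDuplicated(phylo$tip.label), "duplicate tip labels: ",
      paste(unique(phylo$tip.label[duplicated(phylo$tip.label)]), collapse = ", "))
  if (is.null(phylo$edge.length)) {
    phylo$edge.length <- rep(1, nrow(phylo$edge))
    message("taxon_tree: branch lengths missing, defaulting to 1.0")
  }
  chk(all(phylo$edge.length >= 0), "negative branch length")
  structure(list(phylo = phylo, kind = kind), class = "taxon_tree")
}

#' @export
print.taxon_tree <- function(x, ...) {
  cat(sprintf("taxon_tree (%s): %d tips [%s]%s\n", x$kind,
              length(x$phylo$tip.label),
              paste(x$phylo$tip.label, collapse = ", "),
              if (is_ultrametric_tree(x)) ", ultrametric" else ""))
  invisible(x)
}

#' @rdname taxon_tree
#' @param x a `taxon_tree`.
#' @param tol relative tolerance on root-to-tip path constancy.
#' @export
is_ultrametric_tree <- function(x, tol = 1e-9) {
  stopifnot(inherits(x, "taxon_tree"))
  d <- ape::node.depth.edgelength(x$phylo)[seq_along(x$phylo$tip.label)]
  if (max(d) == 0) return(TRUE)
  (max(d) - min(d)) / max(d) <= tol
}

#' Read / write Newick trees
#'
#' Round trips preserve topology and branch lengths; trees without branch
#' lengths get unit lengths (logged). Duplicate tip labels are rejected.
#'
#' @param path file path (or, for `read_newick`, a literal Newick string
#'   via `text`).
#' @param text optional Newick string read instead of `path`.
#' @param kind tree kind, see [taxon_tree()].
#' @return `read_newick()` returns a [taxon_tree()].
#' @export
read_newick <- function(path = NULL, text = NULL, kind = "phylogram") {
  if (is.null(text)) {
    chk(!is.null(path) && file.exists(path), "no such file: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop(sprintf("unbalanced parentheses in Newick (%d '(' vs %d ')')",
                 n_open, n_close), call. = FALSE)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE))
  chk(inherits(tr, "phylo"), "Newick parse error: no tree found")
  taxon_tree(tr, kind = kind)
}

#' @rdname read_newick
#' @param tree a [taxon_tree()].
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "taxon_tree"))
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}
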
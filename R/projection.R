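#' Project feature abundances into compound-class space
#'
#' Each annotated feature contributes its abundance once to every ontology
#' term on its root-to-class path that matches the requested level:
#' `C[s, c] = sum over annotated features f with c on f's path of A[s, f]`.
#' Unannotated features contribute nothing.
#'
#' @param table a [feature_table()] (raw or transformed; the scale used is
#'   recorded in the `"abundance_scale"` attribute).
#' @param annotations annotation data.frame reduced to one row per feature
#'   (see [select_best_annotation()]).
#' @param ontology a [chem_ontology()].
#' @param level `"most_specific"` (each feature's own assigned class),
#'   `"superclass"` (the level-1 ancestor) or `"all"` (every term on the
#'   path, giving a hierarchy-conserving table).
#' @return samples x terms numeric matrix with attributes `"term_level"`
#'   (named integer) and `"abundance_scale"`.
#' @export
class_table <- function(table, annotations, ontology,
                        level = c("most_specific", "superclass", "all")) {
  stopifnot(inherits(table, "feature_table"), inherits(ontology, "chem_ontology"))
  level <- match.arg(level)
  ann <- validate_annotations(annotations, ontology)
  chk(!anyDuplicated(ann$feature_id),
      "annotations must be reduced to one row per feature (see select_best_annotation)")
  ann <- ann[ann$feature_id %in% table$features$feature_id, , drop = FALSE]
  lev <- stats::setNames(ontology$terms$level, ontology$terms$term_id)
  paths <- lapply(unique(ann$class_id), function(cid) ancestors(ontology, cid))
  names(paths) <- unique(ann$class_id)
  terms_of <- function(cid) {
    path <- paths[[cid]]
    switch(level,
           most_specific = cid,
           superclass = {
             sup <- path[lev[path] == 1L]
             if (length(sup) == 0L) character(0) else sup
           },
           all = path)
  }
  contrib <- lapply(seq_len(nrow(ann)), function(i) terms_of(ann$class_id[i]))
  all_terms <- sort(unique(unlist(contrib)))
  C <- matrix(0, nrow(table$abundance), length(all_terms),
              dimnames = list(rownames(table$abundance), all_terms))
  for (i in seq_len(nrow(ann))) {
    tm <- contrib[[i]]
    if (length(tm)) {
      C[, tm] <- C[, tm] + table$abundance[, ann$feature_id[i]]
    }
  }
  attr(C, "term_level") <- lev[all_terms]
  attr(C, "abundance_scale") <- if (table$transformed) "log" else "raw"
  C
}

#' Project feature abundances into molecular-descriptor space
#'
#' Plain matrix product `D = A_annotated %*% X`: `A_annotated` is the
#' samples x annotated-features abundance matrix and `X` the features x
#' descriptors matrix. Every descriptor row required by the table must be
#' present.
#'
#' @param table a [feature_table()] whose features are all covered by
#'   `descriptors` rows (restrict with [filter_to_annotated()] first).
#' @param descriptors numeric matrix, feature ids as rownames.
#' @return samples x descriptors numeric matrix.
#' @export
descriptor_table <- function(table, descriptors) {
  stopifnot(inherits(table, "feature_table"), is.matrix(descriptors))
  fids <- table$features$feature_id
  missing <- setdiff(fids, rownames(descriptors))
  chk(length(missing) == 0L, "descriptor rows missing for feature(s): ",
      paste(utils::head(missing, 5L), collapse = ", "))
  A <- table$abundance[, fids, drop = FALSE]
  X <- descriptors[fids, , drop = FALSE]
  A %*% X
}

#' Per-level compound-class counts for sunburst plots
#'
#' For every ontology term, counts the annotated features detected (per the
#' presence/absence call) in at least one sample of the group whose class
#' path contains the term. The root count therefore equals the number of
#' detected annotated features, and counts shrink towards the leaves.
#'
#' @param table a raw [feature_table()] (presence calls need raw abundances).
#' @param annotations reduced annotation data.frame.
#' @param ontology a [chem_ontology()].
#' @param group character vector of sample ids forming the group.
#' @param presence_fraction see [presence_absence()].
#' @return data.frame (term_id, name, level, count), ordered by level then
#'   term id; terms with count 0 are kept so sibling rings stay comparable.
#' @export
sunburst_counts <- function(table, annotations, ontology, group,
                            presence_fraction = 1e-8) {
  stopifnot(inherits(table, "feature_table"), inherits(ontology, "chem_ontology"))
  chk(length(group) > 0, "group must contain at least one sample")
  chk(all(group %in% table$samples$sample_id), "unknown sample id(s) in group")
  ann <- validate_annotations(annotations, ontology)
  chk(!anyDuplicated(ann$feature_id), "annotations must be one row per feature")
  pres <- presence_absence(table, presence_fraction)
  detected <- ann$feature_id %in% table$features$feature_id &
    vapply(ann$feature_id, function(f) {
      f %in% colnames(pres) && any(pres[group, f, drop = TRUE])
    }, logical(1))
  counts <- stats::setNames(integer(nrow(ontology$terms)), ontology$terms$term_id)
  for (cid in ann$class_id[detected]) {
    path <- ancestors(ontology, cid)
    counts[path] <- counts[path] + 1L
  }
  out <- data.frame(term_id = ontology$terms$term_id,
                    name = ontology$terms$name,
                    level = ontology$terms$level,
                    count = as.integer(counts[ontology$terms$term_id]))
  out[order(out$level, out$term_id), , drop = FALSE]
}
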
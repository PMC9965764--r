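#' Read / write annotation tables
#'
#' Annotation tables emulate SIRIUS/CANOPUS summary exports: one row per
#' candidate structure per feature, with a rank, an opaque structure id
#' (e.g. SMILES), a molecular formula, an optional confidence score (COSMIC
#' style) and the most specific ontology class.
#'
#' @param path TSV path with columns `feature_id`, `rank`, `structure_id`,
#'   `formula`, `score`, `class_id`.
#' @param ontology optional [chem_ontology()] used to check that every
#'   `class_id` resolves.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path, ontology = NULL) {
  chk(file.exists(path), "no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_annotations(df, ontology)
}

#' @rdname read_annotations
#' @param annotations annotation data.frame.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

validate_annotations <- function(df, ontology = NULL) {
  need <- c("feature_id", "rank", "structure_id", "formula", "score", "class_id")
  chk(all(need %in% names(df)), "annotations need columns: ",
      paste(need, collapse = ", "))
  df$feature_id <- as.character(df$feature_id)
  df$structure_id <- as.character(df$structure_id)
  df$class_id <- as.character(df$class_id)
  chk(all(df$rank >= 1 & df$rank == round(df$rank)), "rank must be a positive integer")
  chk(!anyDuplicated(df[c("feature_id", "rank")]),
      "duplicate (feature_id, rank) pair(s)")
  if (!is.null(ontology)) {
    bad <- setdiff(unique(df$class_id), ontology$terms$term_id)
    chk(length(bad) == 0L, "annotation class not in ontology: ",
        paste(bad, collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Reduce an annotation table to the best candidate per feature
#'
#' Mirrors the candidate selection used for SIRIUS output: when any
#' candidate of a feature has a confidence score the maximal-score candidate
#' is kept; otherwise the rank-1 candidate is kept. Ties break by lower
#' rank, then lexicographically smaller `structure_id`.
#'
#' @param annotations annotation data.frame (see [read_annotations()]).
#' @return data.frame with exactly one row per distinct input `feature_id`.
#' @export
select_best_annotation <- function(annotations) {
  df <- validate_annotations(annotations)
  if (nrow(df) == 0L) return(df)
  pick <- function(g) {
    if (any(!is.na(g$score))) {
      g <- g[!is.na(g$score), , drop = FALSE]
      g <- g[g$score == max(g$score), , drop = FALSE]
    } else {
      g <- g[g$rank == min(g$rank), , drop = FALSE]
    }
    g <- g[order(g$rank, g$structure_id), , drop = FALSE]
    g[1L, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(df, df$feature_id), pick))
  out <- out[order(match(out$feature_id, unique(df$feature_id))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a molecular-descriptor matrix
#'
#' Rows are annotated features, columns numeric molecular descriptors
#' (RDKit-style). Rows containing missing values are dropped with a message.
#'
#' @param path CSV path; first column `feature_id`, remaining columns numeric.
#' @return numeric matrix with feature ids as rownames.
#' @export
read_descriptors <- function(path) {
  chk(file.exists(path), "no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  chk(names(df)[1L] == "feature_id", "first column must be feature_id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$feature_id)
  chk(!anyDuplicated(rownames(m)), "duplicate feature ids in descriptor matrix")
  incomplete <- !stats::complete.cases(m) | apply(m, 1L, function(r) any(!is.finite(r)))
  if (any(incomplete)) {
    message(sprintf("read_descriptors: dropped %d incomplete row(s)", sum(incomplete)))
    m <- m[!incomplete, , drop = FALSE]
  }
  m
}

#' @rdname read_descriptors
#' @param descriptors numeric matrix with feature-id rownames.
#' @export
write_descriptors <- function(descriptors, path) {
  df <- data.frame(feature_id = rownames(descriptors), descriptors,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
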
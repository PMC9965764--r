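#' Construct a metabolite feature table
#'
#' The central container of the pipeline: a samples x features intensity
#' matrix with per-feature MS metadata (ion mode, m/z, retention time, MS2
#' acquisition flag) and per-sample design metadata (taxon, replicate).
#'
#' @param abundance numeric matrix, samples in rows, features in columns;
#'   dimnames must carry sample and feature ids.
#' @param samples data.frame with columns `sample_id`, `taxon`, `replicate`.
#' @param features data.frame with columns `feature_id`, `ion_mode`
#'   (`"pos"`/`"neg"`), `mz` (Da, > 0), `rt` (seconds, >= 0), `has_ms2`.
#' @param transformed logical; `TRUE` once intensities are log-scale.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(abundance, samples, features, transformed = FALSE) {
  chk(is.matrix(abundance) && is.numeric(abundance), "abundance must be a numeric matrix")
  chk(is.data.frame(samples) && all(c("sample_id", "taxon", "replicate") %in% names(samples)),
      "samples needs columns sample_id, taxon, replicate")
  chk(is.data.frame(features) && all(c("feature_id", "ion_mode", "mz", "rt", "has_ms2") %in% names(features)),
      "features needs columns feature_id, ion_mode, mz, rt, has_ms2")
  samples$sample_id <- as.character(samples$sample_id)
  samples$taxon <- as.character(samples$taxon)
  features$feature_id <- as.character(features$feature_id)
  chk(!anyDuplicated(samples$sample_id), "duplicate sample ids: ",
      paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  chk(!anyDuplicated(features$feature_id), "duplicate feature ids: ",
      paste(unique(features$feature_id[duplicated(features$feature_id)]), collapse = ", "))
  chk(nrow(abundance) == nrow(samples), "abundance rows != number of samples")
  chk(ncol(abundance) == nrow(features), "abundance columns != number of features")
  chk(all(is.finite(abundance)), "abundance must be finite")
  chk(all(features$ion_mode %in% c("pos", "neg")), "ion_mode must be 'pos' or 'neg'")
  chk(all(features$mz > 0), "m/z values must be positive")
  chk(all(features$rt >= 0), "retention times must be non-negative")
  chk(all(samples$replicate >= 1 & samples$replicate == round(samples$replicate)),
      "replicate must be a positive integer")
  chk(all(nzchar(samples$taxon)), "every sample needs a taxon label")
  if (!transformed && any(abundance < 0)) {
    bad <- which(abundance < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative raw intensity at sample '%s', feature '%s'",
                 samples$sample_id[bad[1L]], features$feature_id[bad[2L]]), call. = FALSE)
  }
  dimnames(abundance) <- list(samples$sample_id, features$feature_id)
  structure(list(abundance = abundance, samples = samples, features = features,
                 transformed = isTRUE(transformed)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%s scale)\n",
              nrow(x$abundance), ncol(x$abundance),
              if (x$transformed) "log" else "raw"))
  cat(sprintf("  taxa: %s\n", paste(unique(x$samples$taxon), collapse = ", ")))
  cat(sprintf("  ion modes: %d pos / %d neg; %d features with MS2\n",
              sum(x$features$ion_mode == "pos"), sum(x$features$ion_mode == "neg"),
              sum(x$features$has_ms2)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$abundance)

#' Subset a feature table by sample and/or feature ids
#'
#' @param table a [feature_table()].
#' @param samples,features character vectors of ids to keep (order preserved
#'   from the original table); `NULL` keeps everything.
#' @return a `feature_table`.
#' @export
subset_features <- function(table, samples = NULL, features = NULL) {
  stopifnot(inherits(table, "feature_table"))
  si <- if (is.null(samples)) seq_len(nrow(table$abundance)) else {
    chk(all(samples %in% table$samples$sample_id), "unknown sample id(s)")
    which(table$samples$sample_id %in% samples)
  }
  fi <- if (is.null(features)) seq_len(ncol(table$abundance)) else {
    chk(all(features %in% table$features$feature_id), "unknown feature id(s)")
    which(table$features$feature_id %in% features)
  }
  feature_table(table$abundance[si, fi, drop = FALSE],
                table$samples[si, , drop = FALSE],
                table$features[fi, , drop = FALSE],
                transformed = table$transformed)
}

#' Write / read a feature table as delimited text
#'
#' Layout: the main file holds one row per sample with columns `sample_id`,
#' `taxon`, `replicate` followed by one column per feature; the sidecar file
#' is a TSV of per-feature metadata (`feature_id`, `ion_mode`, `mz`, `rt`,
#' `has_ms2`). Empty abundance cells load as 0 (zero imputation) and the
#' number of imputed cells is reported via a message and the `"n_imputed"`
#' attribute.
#'
#' @param table a [feature_table()].
#' @param path main table path (`.csv` or `.tsv`; the delimiter follows the
#'   extension unless `dialect` is given).
#' @param meta_path sidecar path; defaults to `<path>` with a `_meta.tsv`
#'   suffix.
#' @param dialect `"csv"` or `"tsv"`; `NULL` = infer from extension.
#' @param transformed logical passed on to validation when reading.
#' @return `read_feature_table()` returns a validated `feature_table`.
#' @export
write_feature_table <- function(table, path, meta_path = default_meta_path(path),
                                dialect = NULL) {
  stopifnot(inherits(table, "feature_table"))
  sep <- dialect_sep(path, dialect)
  df <- data.frame(sample_id = table$samples$sample_id,
                   taxon = table$samples$taxon,
                   replicate = table$samples$replicate,
                   table$abundance, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, qmethod = "double")
  utils::write.table(table$features, meta_path, sep = "\t", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, meta_path = default_meta_path(path),
                               dialect = NULL, transformed = FALSE) {
  chk(file.exists(path), "no such file: ", path)
  chk(file.exists(meta_path), "no such feature metadata file: ", meta_path)
  sep <- dialect_sep(path, dialect)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  chk(all(c("sample_id", "taxon", "replicate") == names(df)[1:3]),
      "first three columns must be sample_id, taxon, replicate")
  fid <- names(df)[-(1:3)]
  if (anyDuplicated(fid)) {
    stop("duplicated feature column(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  }
  ab <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(ab) <- "double"
  n_imputed <- sum(is.na(ab))
  if (n_imputed > 0) {
    ab[is.na(ab)] <- 0
    message(sprintf("read_feature_table: imputed %d missing cell(s) with 0", n_imputed))
  }
  meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  meta$feature_id <- as.character(meta$feature_id)
  chk(setequal(meta$feature_id, fid) && !anyDuplicated(meta$feature_id),
      "feature metadata does not match the feature columns")
  meta <- meta[match(fid, meta$feature_id), , drop = FALSE]
  rownames(meta) <- NULL
  out <- feature_table(ab, df[, 1:3], meta, transformed = transformed)
  attr(out, "n_imputed") <- n_imputed
  out
}

default_meta_path <- function(path) {
  sub("\\.(csv|tsv)$", "_meta.tsv", path)
}

dialect_sep <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  chk(dialect %in% c("csv", "tsv"), "dialect must be 'csv' or 'tsv'")
  if (dialect == "tsv") "\t" else ","
}
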
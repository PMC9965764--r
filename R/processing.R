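#' Retention-time filter
#'
#' Keeps features eluting strictly before `rt_max` seconds (the conditioning
#' step applied before statistical analysis; late-eluting features are
#' column-wash artefacts). Feature order and all sample metadata are
#' preserved.
#'
#' @param table a [feature_table()].
#' @param rt_max cutoff in seconds (default 1020); features with
#'   `rt < rt_max` are retained.
#' @return a `feature_table`.
#' @export
filter_rt <- function(table, rt_max = 1020) {
  stopifnot(inherits(table, "feature_table"))
  chk(is.numeric(rt_max) && length(rt_max) == 1L && rt_max > 0, "rt_max must be > 0")
  keep <- table$features$rt < rt_max
  if (!any(keep)) message("filter_rt: no features retained")
  feature_table(table$abundance[, keep, drop = FALSE], table$samples,
                table$features[keep, , drop = FALSE], transformed = table$transformed)
}

#' Log-transform a raw feature table
#'
#' Applies `x -> log(1 + x)` elementwise, so zero-imputed missing values stay
#' exactly 0 and no entry becomes `-Inf`. Applying it twice is a state error.
#'
#' @param table a raw [feature_table()].
#' @return a `feature_table` with `transformed = TRUE`.
#' @export
log_transform <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$transformed) stop("table is already log-transformed", call. = FALSE)
  feature_table(log1p(table$abundance), table$samples, table$features,
                transformed = TRUE)
}

#' Presence/absence calls on a raw feature table
#'
#' A feature is absent in a sample when its abundance is less than
#' `presence_fraction` percent of the global median of non-zero raw
#' abundances (default 1e-8 %). Entries equal to the threshold count as
#' present.
#'
#' @param table a raw [feature_table()].
#' @param presence_fraction threshold as a percent of the median non-zero
#'   abundance (default `1e-8`).
#' @return logical matrix (samples x features) with the numeric threshold in
#'   attribute `"threshold"`.
#' @export
presence_absence <- function(table, presence_fraction = 1e-8) {
  stopifnot(inherits(table, "feature_table"))
  chk(!table$transformed, "presence/absence is defined on raw abundances")
  chk(is.numeric(presence_fraction) && presence_fraction >= 0,
      "presence_fraction must be >= 0")
  nz <- table$abundance[table$abundance > 0]
  if (length(nz) == 0L) stop("all abundances are zero; median undefined", call. = FALSE)
  t0 <- stats::median(nz) * presence_fraction / 100
  out <- table$abundance >= t0
  attr(out, "threshold") <- t0
  out
}

#' Join positive- and negative-mode feature tables
#'
#' Feature ids get `pos_`/`neg_` prefixes so the joined table has no
#' collisions. Before joining, the relative deviation
#' `|a - b| / ((a + b) / 2)` of the two tables' medians of non-zero entries
#' (and likewise their variances of non-zero entries) is computed on the
#' scale of the supplied tables; if either exceeds `tolerance` the join
#' still proceeds but a warning is raised and the `"mode_join_warning"`
#' attribute is set.
#'
#' @param pos,neg [feature_table()] objects over the same samples in the
#'   same order, both raw or both transformed.
#' @param tolerance maximal relative deviation considered compatible
#'   (default 0.10).
#' @return a joined `feature_table` with attributes
#'   `"mode_join_deviation"` (named numeric: median, variance) and
#'   `"mode_join_warning"` (logical).
#' @export
join_modes <- function(pos, neg, tolerance = 0.10) {
  stopifnot(inherits(pos, "feature_table"), inherits(neg, "feature_table"))
  chk(is_prob(tolerance), "tolerance must be in [0, 1]")
  if (!identical(pos$samples$sample_id, neg$samples$sample_id)) {
    stop("sample sets differ between modes: ",
         paste(union(setdiff(pos$samples$sample_id, neg$samples$sample_id),
                     setdiff(neg$samples$sample_id, pos$samples$sample_id)),
               collapse = ", "), call. = FALSE)
  }
  chk(identical(pos$transformed, neg$transformed),
      "both tables must be on the same scale (raw or transformed)")
  rel_dev <- function(a, b) if (a == 0 && b == 0) 0 else abs(a - b) / ((a + b) / 2)
  nzp <- pos$abundance[pos$abundance != 0]
  nzn <- neg$abundance[neg$abundance != 0]
  dev <- c(median = rel_dev(stats::median(nzp), stats::median(nzn)),
           variance = rel_dev(stats::var(nzp), stats::var(nzn)))
  warn <- any(dev > tolerance)
  if (warn) {
    warning(sprintf("mode compatibility check failed: median dev %.3f, variance dev %.3f (tolerance %.2f)",
                    dev["median"], dev["variance"], tolerance), call. = FALSE)
  }
  fp <- pos$features; fp$feature_id <- paste0("pos_", fp$feature_id)
  fn <- neg$features; fn$feature_id <- paste0("neg_", fn$feature_id)
  ab <- cbind(pos$abundance, neg$abundance)
  colnames(ab) <- c(fp$feature_id, fn$feature_id)
  out <- feature_table(ab, pos$samples, rbind(fp, fn),
                       transformed = pos$transformed)
  attr(out, "mode_join_deviation") <- dev
  attr(out, "mode_join_warning") <- warn
  out
}

#' Restrict a feature table to MS2-backed (and optionally annotated) features
#'
#' @param table a [feature_table()].
#' @param annotations optional annotation data.frame; when given, features
#'   must additionally have an annotation row to be kept.
#' @return a `feature_table`.
#' @export
filter_to_annotated <- function(table, annotations = NULL) {
  stopifnot(inherits(table, "feature_table"))
  keep <- table$features$has_ms2
  if (!is.null(annotations)) {
    keep <- keep & table$features$feature_id %in% as.character(annotations$feature_id)
  }
  feature_table(table$abundance[, keep, drop = FALSE], table$samples,
                table$features[keep, , drop = FALSE], transformed = table$transformed)
}

#' PCA overview of a conditioned table
#'
#' Column-centered principal components of the abundance matrix, the usual
#' unsupervised diagnostic before supervised marker selection.
#'
#' @param table a transformed [feature_table()] (raw input is allowed but a
#'   message notes it).
#' @param n_components number of components to return; default
#'   `min(n_samples - 1, n_features)`.
#' @return list with `scores` (samples x components), `loadings`
#'   (features x components) and `explained` (variance fractions,
#'   non-increasing, summing to <= 1).
#' @export
pca_overview <- function(table, n_components = NULL) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$abundance)
  chk(n >= 2, "PCA needs at least 2 samples")
  if (!table$transformed) message("pca_overview: running on raw abundances")
  k_max <- min(n - 1L, ncol(table$abundance))
  if (is.null(n_components)) n_components <- k_max
  chk(is_count(n_components, 1) && n_components <= k_max,
      "n_components must be in [1, min(samples - 1, features)]")
  pc <- stats::prcomp(table$abundance, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = explained[seq_len(k)])
}
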
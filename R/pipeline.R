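#' Run the full chemotaxonomy pipeline on a synthetic or loaded bundle
#'
#' Stages: condition the feature table (RT filter, log transform, mode-join
#' bookkeeping), project to class/superclass/descriptor spaces, compute
#' diversity indices, select PLS-DA markers at the requested level, build
#' the chemotaxonomic tree and compare it to the reference phylogeny, and
#' (optionally) run the image-spectra dbRDA linkage. Every stage draws its
#' randomness from a named substream of the global seed, so results are
#' reproducible and independent of unrelated stages. All outputs are
#' written as plain text under `out_dir` together with a provenance
#' manifest.
#'
#' @param bundle a [synth_generate()] bundle, or a list with the same
#'   elements loaded from files (`feature_table`, `annotations`,
#'   `ontology`, `descriptors`, `true_tree`; `planted_markers` optional).
#' @param out_dir output directory (created).
#' @param seed global integer seed.
#' @param params list of stage parameters: `rt_max`, `presence_fraction`,
#'   `level` (marker-selection level: `"feature"`, `"class"`,
#'   `"superclass"`, `"descriptor"`), `quantile`, `k_folds`, `n_perm`,
#'   `aggregate`, `imaging` (logical), `pixels_per_image`.
#' @return (invisibly) a list with the main results: `processed`,
#'   `diversity`, `markers`, `metrics`, `tree`, `congruence`, `dbrda`.
#' @export
run_pipeline <- function(bundle, out_dir, seed = 1,
                         params = list()) {
  defaults <- list(rt_max = 1020, presence_fraction = 1e-8, level = "feature",
                   quantile = 0.995, k_folds = 10, n_perm = 999,
                   aggregate = "mean", imaging = TRUE, pixels_per_image = 32)
  params <- utils::modifyList(defaults, params)
  chk(is.list(bundle) && !is.null(bundle$feature_table), "bundle lacks feature_table")
  for (el in c("annotations", "ontology", "true_tree")) {
    chk(!is.null(bundle[[el]]), "bundle lacks ", el)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, params = params, warnings = character(0))

  ## conditioning
  raw <- filter_rt(bundle$feature_table, params$rt_max)
  pres <- presence_absence(raw, params$presence_fraction)
  logt <- log_transform(raw)
  write_feature_table(logt, file.path(out_dir, "processed.csv"))
  manifest$presence_threshold <- attr(pres, "threshold")
  manifest$n_features <- ncol(raw$abundance)

  ## projections
  best <- select_best_annotation(bundle$annotations)
  cls <- class_table(logt, best, bundle$ontology, level = "most_specific")
  sup <- class_table(logt, best, bundle$ontology, level = "superclass")
  ann_ft <- filter_to_annotated(logt, best)
  ann_ft <- subset_features(ann_ft,
                            features = intersect(ann_ft$features$feature_id,
                                                 rownames(bundle$descriptors)))
  desc <- descriptor_table(ann_ft, bundle$descriptors)
  utils::write.csv(cls, file.path(out_dir, "class_table.csv"))
  utils::write.csv(sup, file.path(out_dir, "superclass_table.csv"))
  utils::write.csv(desc, file.path(out_dir, "descriptor_table.csv"))

  ## diversity
  div <- diversity_table(raw, params$presence_fraction)
  utils::write.table(div$per_sample, file.path(out_dir, "diversity_per_sample.tsv"),
                     sep = "\t", row.names = FALSE)
  utils::write.table(div$per_taxon, file.path(out_dir, "diversity_per_taxon.tsv"),
                     sep = "\t", row.names = FALSE)

  ## marker selection
  Xsel <- switch(params$level,
                 feature = logt$abundance,
                 class = cls,
                 superclass = sup,
                 descriptor = desc,
                 stop("unknown selection level: ", params$level))
  y <- logt$samples$taxon
  model <- fit_plsda(Xsel, y, seed = stage_seed(seed, "select"))
  imp <- variable_importance(model)
  markers <- select_markers(imp, params$quantile)
  metrics <- evaluate_plsda(model, Xsel, y, k_folds = params$k_folds,
                            seed = stage_seed(seed, "select"))
  prov <- attr(markers, "provenance")
  utils::write.table(prov, file.path(out_dir, "markers.tsv"), sep = "\t",
                     row.names = FALSE)
  jsonlite::write_json(list(accuracy = metrics$accuracy, r2 = metrics$r2,
                            auc_macro = metrics$auc_macro,
                            auc_pr_macro = metrics$auc_pr_macro,
                            auc = as.list(metrics$auc),
                            k_folds_used = metrics$k_used,
                            n_components = model$ncomp),
                      file.path(out_dir, "metrics.json"),
                      auto_unbox = TRUE, digits = NA)
  if (length(markers) > 0) {
    hm <- heatmap_matrix(Xsel, markers, y, importance = imp)
    utils::write.csv(hm, file.path(out_dir, "heatmap.csv"))
  }

  ## tree + congruence
  cmp <- compare_to_reference(logt, bundle$true_tree, n_perm = params$n_perm,
                              seed = stage_seed(seed, "tree"),
                              aggregate = params$aggregate)
  write_newick(cmp$tree, file.path(out_dir, "chemo_tree.nwk"))
  jsonlite::write_json(cmp$report, file.path(out_dir, "congruence.json"),
                       auto_unbox = TRUE, digits = NA)

  ## imaging linkage
  dbr <- NULL
  if (isTRUE(params$imaging)) {
    imgs <- make_reference_images(bundle, pixels_per_image = params$pixels_per_image,
                                  seed = stage_seed(seed, "imaging"))
    traits <- spectral_trait_matrix(imgs)
    constraints <- cls[rownames(traits), , drop = FALSE]
    dbr <- dbrda_fit(traits, constraints)
    jsonlite::write_json(list(constrained_fraction = dbr$constrained_fraction,
                              negative_mass = dbr$negative_mass,
                              rank = dbr$rank),
                         file.path(out_dir, "dbrda.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest$files <- list.files(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(processed = logt, presence = pres, diversity = div,
                 class_table = cls, superclass_table = sup,
                 descriptor_table = desc, model = model, importance = imp,
                 markers = markers, metrics = metrics, tree = cmp$tree,
                 congruence = cmp$report, dbrda = dbr))
}
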
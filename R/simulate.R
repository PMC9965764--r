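#' Configuration for the synthetic chemotaxonomy data generator
#'
#' Defaults describe the study design the pipeline targets: a small clade
#' plus outgroup (4 taxa) with 3 biological replicates each, a shared core
#' metabolome of a few hundred MS1 features, species effects evolving by
#' Brownian motion on the log scale along a species tree, and a handful of
#' planted species-specific marker features with a four-fold abundance
#' effect.
#'
#' @param n_taxa number of taxa (>= 2).
#' @param n_replicates biological replicates per taxon (>= 2).
#' @param n_features number of MS1 features (>= 10).
#' @param frac_annotated fraction of features with an MS2 spectrum and an
#'   ontology annotation, in (0, 1].
#' @param n_markers_per_taxon planted species-specific markers per taxon.
#' @param marker_log_effect marker effect on natural-log intensity
#'   (default `log(4)`, i.e. four-fold).
#' @param brownian_sd Brownian-motion standard deviation per unit branch
#'   length on log intensity.
#' @param replicate_sd replicate (residual) standard deviation on log
#'   intensity.
#' @param baseline_log_mean grand mean of log intensity (default `log(1e5)`).
#' @param missing_rate probability an intensity is lost (set to 0), in [0, 1).
#' @param frac_negative_mode fraction of features measured in negative ion
#'   mode.
#' @param seed integer RNG seed; the whole bundle is a deterministic
#'   function of the config.
#' @param tree optional Newick string for the species tree; default is a
#'   random labelled topology with unit branch lengths.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_taxa = 4, n_replicates = 3, n_features = 300,
                         frac_annotated = 0.6, n_markers_per_taxon = 10,
                         marker_log_effect = log(4), brownian_sd = 0.5,
                         replicate_sd = 0.3, baseline_log_mean = log(1e5),
                         missing_rate = 0, frac_negative_mode = 0.3,
                         seed = 1, tree = NULL) {
  chk(is_count(n_taxa, 2), "n_taxa must be an integer >= 2")
  chk(is_count(n_replicates, 2), "n_replicates must be an integer >= 2")
  chk(is_count(n_features, 10), "n_features must be an integer >= 10")
  chk(is_prob(frac_annotated) && frac_annotated > 0, "frac_annotated must be in (0, 1]")
  chk(is_count(n_markers_per_taxon, 0), "n_markers_per_taxon must be an integer >= 0")
  chk(is.numeric(marker_log_effect) && is.finite(marker_log_effect),
      "marker_log_effect must be finite")
  chk(is.numeric(brownian_sd) && brownian_sd >= 0, "brownian_sd must be >= 0")
  chk(is.numeric(replicate_sd) && replicate_sd >= 0, "replicate_sd must be >= 0")
  chk(is_prob(missing_rate) && missing_rate < 1, "missing_rate must be in [0, 1)")
  chk(is_prob(frac_negative_mode), "frac_negative_mode must be in [0, 1]")
  chk(is_count(abs(seed)), "seed must be an integer")
  if (n_markers_per_taxon * n_taxa > n_features) {
    stop("n_markers_per_taxon x n_taxa exceeds n_features", call. = FALSE)
  }
  structure(list(n_taxa = as.integer(n_taxa), n_replicates = as.integer(n_replicates),
                 n_features = as.integer(n_features), frac_annotated = frac_annotated,
                 n_markers_per_taxon = as.integer(n_markers_per_taxon),
                 marker_log_effect = marker_log_effect, brownian_sd = brownian_sd,
                 replicate_sd = replicate_sd, baseline_log_mean = baseline_log_mean,
                 missing_rate = missing_rate, frac_negative_mode = frac_negative_mode,
                 seed = as.integer(seed), tree = tree),
            class = "synth_config")
}

# 3-level default ontology: root -> 4 superclasses -> 12 leaf classes
default_ontology <- function() {
  sup <- c("Lipids", "Phenylpropanoids", "Benzenoids", "Organic acids")
  leaves <- c("Fatty acyls", "Glycerolipids", "Prenol lipids",
              "Flavonoids", "Coumarins", "Stilbenes",
              "Phenols", "Benzene derivatives", "Naphthalenes",
              "Carboxylic acids", "Keto acids", "Hydroxy acids")
  terms <- rbind(
    data.frame(term_id = "CH:0", name = "Organic compounds",
               parent_id = NA_character_, level = 0L),
    data.frame(term_id = paste0("CH:", 1:4), name = sup,
               parent_id = "CH:0", level = 1L),
    data.frame(term_id = paste0("CH:", 5:16), name = leaves,
               parent_id = rep(paste0("CH:", 1:4), each = 3L), level = 2L)
  )
  chem_ontology(terms)
}

#' Generate a synthetic chemotaxonomy bundle
#'
#' Log intensity of feature f in replicate r of taxon t is
#' `mu0 + u_f + b_tf + m_tf + eps`, with `u_f ~ N(0, 1)` a per-feature
#' baseline, `b_tf` Brownian motion along the species tree (variance
#' `brownian_sd^2 * branch length`), `m_tf = marker_log_effect` iff f is a
#' planted marker of t, and `eps ~ N(0, replicate_sd^2)`. Intensities are
#' `exp()` of that; entries are then zeroed independently with probability
#' `missing_rate` (missing completely at random). An annotated subset of
#' features gets leaf ontology classes uniformly at random and descriptor
#' values equal to a class-specific mean vector plus N(0, 1) noise.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_bundle` with elements `feature_table`,
#'   `annotations`, `ontology`, `descriptors`, `true_tree`,
#'   `planted_markers` (named list taxon -> feature ids) and `config`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_t <- config$n_taxa; n_r <- config$n_replicates; n_f <- config$n_features
  taxa <- sprintf("taxon_%02d", seq_len(n_t))

  if (is.null(config$tree)) {
    phy <- ape::rtree(n_t, rooted = TRUE, tip.label = taxa,
                      br = function(k) rep(1, k))
  } else {
    phy <- ape::read.tree(text = config$tree)
    chk(length(phy$tip.label) == n_t, "supplied tree tip count != n_taxa")
    taxa <- phy$tip.label
  }
  true_tree <- taxon_tree(phy, kind = "phylogram")

  feature_ids <- sprintf("F%04d", seq_len(n_f))
  u_f <- stats::rnorm(n_f)

  # Brownian species effects: rows taxa, cols features
  b <- matrix(0, n_t, n_f, dimnames = list(taxa, feature_ids))
  if (config$brownian_sd > 0) {
    C <- ape::vcv(phy)[taxa, taxa]
    L <- chol(C + diag(1e-10, n_t))
    b <- config$brownian_sd * t(L) %*% matrix(stats::rnorm(n_t * n_f), n_t, n_f)
    dimnames(b) <- list(taxa, feature_ids)
  }

  # planted markers: disjoint feature sets per taxon
  planted <- stats::setNames(vector("list", n_t), taxa)
  if (config$n_markers_per_taxon > 0) {
    pool <- sample(feature_ids, config$n_markers_per_taxon * n_t)
    for (i in seq_len(n_t)) {
      planted[[i]] <- sort(pool[((i - 1) * config$n_markers_per_taxon + 1):(i * config$n_markers_per_taxon)])
    }
  } else {
    planted[] <- list(character(0))
  }

  samples <- data.frame(
    sample_id = sprintf("%s_r%d", rep(taxa, each = n_r), rep(seq_len(n_r), n_t)),
    taxon = rep(taxa, each = n_r),
    replicate = rep(seq_len(n_r), n_t))

  logI <- matrix(config$baseline_log_mean, nrow(samples), n_f,
                 dimnames = list(samples$sample_id, feature_ids))
  logI <- sweep(logI, 2L, -u_f, "-")
  for (i in seq_len(nrow(samples))) {
    t_i <- samples$taxon[i]
    logI[i, ] <- logI[i, ] + b[t_i, ]
    if (length(planted[[t_i]])) {
      logI[i, planted[[t_i]]] <- logI[i, planted[[t_i]]] + config$marker_log_effect
    }
  }
  logI <- logI + matrix(stats::rnorm(length(logI), sd = config$replicate_sd),
                        nrow(logI), ncol(logI))
  intensity <- exp(logI)
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(length(intensity)) < config$missing_rate,
                   nrow(intensity), ncol(intensity))
    intensity[drop] <- 0
  }

  n_neg <- round(config$frac_negative_mode * n_f)
  mode <- rep("pos", n_f)
  if (n_neg > 0) mode[sample.int(n_f, n_neg)] <- "neg"

  ontology <- default_ontology()
  leaf_ids <- terms_at_level(ontology, max(ontology$terms$level))
  n_ann <- max(1L, round(config$frac_annotated * n_f))
  annotated <- sort(sample.int(n_f, n_ann))
  classes <- sample(leaf_ids, n_ann, replace = TRUE)

  features <- data.frame(
    feature_id = feature_ids,
    ion_mode = mode,
    mz = round(stats::runif(n_f, 100, 1000), 4),
    rt = round(stats::runif(n_f, 60, 960), 1),
    has_ms2 = seq_len(n_f) %in% annotated)

  annotations <- data.frame(
    feature_id = feature_ids[annotated],
    rank = 1L,
    structure_id = sprintf("STRUCT_%04d", annotated),
    formula = sprintf("C%dH%dO%d", sample(6:30, n_ann, TRUE),
                      sample(6:40, n_ann, TRUE), sample(1:12, n_ann, TRUE)),
    score = round(stats::runif(n_ann, 0.1, 1), 4),
    class_id = classes)

  # descriptors: class-specific mean vector + unit noise
  n_desc <- 8L
  desc_names <- sprintf("desc_%02d", seq_len(n_desc))
  class_means <- matrix(stats::rnorm(length(leaf_ids) * n_desc, sd = 2),
                        length(leaf_ids), n_desc, dimnames = list(leaf_ids, desc_names))
  descriptors <- class_means[classes, , drop = FALSE] +
    matrix(stats::rnorm(n_ann * n_desc), n_ann, n_desc)
  dimnames(descriptors) <- list(feature_ids[annotated], desc_names)

  ft <- feature_table(intensity, samples, features, transformed = FALSE)
  structure(list(feature_table = ft, annotations = annotations,
                 ontology = ontology, descriptors = descriptors,
                 true_tree = true_tree, planted_markers = planted,
                 config = config),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf("synth_bundle: %d taxa x %d replicates, %d features (%d annotated), seed %d\n",
              x$config$n_taxa, x$config$n_replicates, x$config$n_features,
              nrow(x$annotations), x$config$seed))
  invisible(x)
}

#' Write a synthetic bundle to plain-text files
#'
#' Emits `feature_table.csv` + `feature_table_meta.tsv`, `annotations.tsv`,
#' `ontology.tsv`, `descriptors.csv`, `true_tree.nwk` and `markers.json`
#' under `dir`.
#'
#' @param bundle a [synth_generate()] result.
#' @param dir output directory (created if needed).
#' @export
write_synth_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(bundle$feature_table, file.path(dir, "feature_table.csv"))
  write_annotations(bundle$annotations, file.path(dir, "annotations.tsv"))
  write_ontology(bundle$ontology, file.path(dir, "ontology.tsv"))
  write_descriptors(bundle$descriptors, file.path(dir, "descriptors.csv"))
  write_newick(bundle$true_tree, file.path(dir, "true_tree.nwk"))
  jsonlite::write_json(bundle$planted_markers, file.path(dir, "markers.json"))
  invisible(dir)
}

# affine map from log2 class abundance to mean channel value; slope is the
# shift in mean channel per doubling of class abundance
IMG_CHANNEL_SLOPE <- 0.04

#' Render reference phenotype images for a synthetic bundle
#'
#' One square RGB image per sample. The mean value of each colour channel
#' over the retained (non-border) pixels is an affine function of the
#' sample's mean raw abundance in three designated leaf classes of the
#' bundle ontology: `channel_c = min(1, 0.04 * log2(1 + mean abundance in
#' class c))`, so doubling a class abundance shifts that channel by 0.04.
#' The first pixel row is pure black and the last pure white, emulating
#' segmentation background that downstream histogram extraction must drop.
#'
#' @param bundle a [synth_generate()] result.
#' @param pixels_per_image side length of each square image (>= 16).
#' @param seed RNG seed for the per-pixel noise.
#' @param noise_sd per-pixel Gaussian noise standard deviation.
#' @return named list of H x W x 3 arrays in \[0, 1\] (one per sample), with
#'   attributes `manifest` (sample -> taxon data.frame) and
#'   `designated_classes` (3 leaf term ids driving R, G, B).
#' @export
make_reference_images <- function(bundle, pixels_per_image = 32, seed = 1,
                                  noise_sd = 0.005) {
  stopifnot(inherits(bundle, "synth_bundle"))
  chk(is_count(pixels_per_image) && pixels_per_image >= 16,
      "pixels_per_image must be an integer >= 16")
  set.seed(seed)
  ft <- bundle$feature_table
  leaf_ids <- terms_at_level(bundle$ontology, max(bundle$ontology$terms$level))
  designated <- leaf_ids[1:3]
  # per-sample mean raw abundance in each designated class
  cls <- stats::setNames(bundle$annotations$class_id, bundle$annotations$feature_id)
  class_mean <- sapply(designated, function(cid) {
    f <- names(cls)[cls == cid]
    if (length(f) == 0L) return(rep(0, nrow(ft$abundance)))
    rowMeans(ft$abundance[, f, drop = FALSE])
  })
  p <- pixels_per_image
  imgs <- lapply(seq_len(nrow(ft$abundance)), function(i) {
    mu <- pmin(1, IMG_CHANNEL_SLOPE * log2(1 + class_mean[i, ]))
    img <- array(0, dim = c(p, p, 3))
    for (ch in 1:3) {
      body <- matrix(pmin(0.998, pmax(0.002, mu[ch] +
        stats::rnorm((p - 2) * p, sd = noise_sd))), p - 2, p)
      img[2:(p - 1), , ch] <- body
    }
    img[p, , ] <- 1  # white border row; first row stays black
    img
  })
  names(imgs) <- ft$samples$sample_id
  attr(imgs, "manifest") <- data.frame(sample_id = ft$samples$sample_id,
                                       taxon = ft$samples$taxon)
  attr(imgs, "designated_classes") <- designated
  imgs
}

#' @rdname make_reference_images
#' @param images result of `make_reference_images()`.
#' @param dir output directory for PNG files (one per sample).
#' @export
write_reference_images <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(images)) {
    png::writePNG(images[[nm]], file.path(dir, paste0(nm, ".png")))
  }
  manifest <- attr(images, "manifest")
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE)
  invisible(dir)
}
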
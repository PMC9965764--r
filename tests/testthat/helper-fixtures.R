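# small in-code fixtures shared across test files

tiny_table <- function(ab = NULL, n_s = 2L, n_f = 2L, transformed = FALSE,
                       taxa = NULL, rt = NULL, has_ms2 = NULL, mode = NULL) {
  if (is.null(ab)) ab <- matrix(seq_len(n_s * n_f) * 10, n_s, n_f)
  n_s <- nrow(ab); n_f <- ncol(ab)
  if (is.null(taxa)) taxa <- rep(c("A", "B"), length.out = n_s)
  reps <- stats::ave(seq_len(n_s), taxa, FUN = seq_along)
  samples <- data.frame(sample_id = sprintf("s%d", seq_len(n_s)),
                        taxon = taxa, replicate = reps)
  features <- data.frame(feature_id = sprintf("F%d", seq_len(n_f)),
                         ion_mode = if (is.null(mode)) rep("pos", n_f) else mode,
                         mz = seq(100, 100 + n_f - 1),
                         rt = if (is.null(rt)) rep(300, n_f) else rt,
                         has_ms2 = if (is.null(has_ms2)) rep(TRUE, n_f) else has_ms2)
  feature_table(ab, samples, features, transformed = transformed)
}

tiny_ontology <- function() {
  chem_ontology(data.frame(
    term_id = c("root", "L", "P", "FA", "GL", "FL", "CM"),
    name = c("Organic compounds", "Lipids", "Phenylpropanoids",
             "Fatty acyls", "Glycerolipids", "Flavonoids", "Coumarins"),
    parent_id = c(NA, "root", "root", "L", "L", "P", "P"),
    level = c(0L, 1L, 1L, 2L, 2L, 2L, 2L)))
}

tiny_annotations <- function(feature_id, class_id, score = NA_real_, rank = 1L) {
  data.frame(feature_id = feature_id, rank = rank,
             structure_id = paste0("S_", feature_id), formula = "C6H6O",
             score = score, class_id = class_id)
}

# independent enumeration of all permutations of 1..n (test-side oracle,
# distinct from the package's internal implementation)
perms_oracle <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (k in seq_len(n)) {
    for (s in perms_oracle(n - 1L)) {
      rest <- setdiff(seq_len(n), k)
      out[[length(out) + 1L]] <- c(k, rest[s])
    }
  }
  out
}

labelled_dist <- function(X, labels = NULL) {
  D <- as.matrix(dist(X))
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))
  dimnames(D) <- list(labels, labels)
  D
}
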
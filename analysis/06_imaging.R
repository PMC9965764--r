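#!/usr/bin/env Rscript
# Step 6 — link image spectra to compound-class composition.
#
# Extracts RGB histograms from the segmented phenotype images (pure black
# and pure white pixels excluded), runs dbRDA of the spectral traits on the
# compound-class table with forward selection of constraints, and reports
# envfit-style goodness of fit for the selected classes.

suppressMessages(library(chemophen))

manifest <- utils::read.table("results/data/images/manifest.tsv", sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
paths <- setNames(file.path("results/data/images",
                            paste0(manifest$sample_id, ".png")),
                  manifest$sample_id)
traits <- spectral_trait_matrix(as.list(paths))
cat("Extracted", ncol(traits), "spectral trait bins from", nrow(traits), "images\n")

logt <- read_feature_table("results/processed.csv", transformed = TRUE)
ont <- read_ontology("results/data/ontology.tsv")
ann <- select_best_annotation(read_annotations("results/data/annotations.tsv", ont))
cls <- class_table(logt, ann, ont, level = "most_specific")
cls <- cls[rownames(traits), , drop = FALSE]

sel <- forward_select(traits, cls, alpha = 0.05, n_perm = 199, seed = 1)
cat("Forward-selected classes:", if (length(sel)) paste(sel, collapse = ", ") else "(none)", "\n")

constraints <- if (length(sel) >= 1) cls[, sel, drop = FALSE] else cls
dbr <- suppressWarnings(dbrda_fit(traits, constraints))
cat(sprintf("dbRDA constrained inertia fraction: %.3f\n", dbr$constrained_fraction))

fits <- lapply(colnames(constraints), function(v)
  envfit_r2(dbr$site_scores, constraints[, v], n_perm = 199, seed = 1))
gof <- data.frame(class = colnames(constraints),
                  r2 = vapply(fits, `[[`, numeric(1), "r2"),
                  p = vapply(fits, `[[`, numeric(1), "p"))
print(gof)
utils::write.csv(gof, "results/envfit_goodness.csv", row.names = FALSE)
utils::write.csv(dbr$site_scores, "results/dbrda_site_scores.csv")
jsonlite::write_json(list(constrained_fraction = dbr$constrained_fraction,
                          selected = as.character(sel)),
                     "results/dbrda.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/dbrda.json, site scores and goodness-of-fit table\n")
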
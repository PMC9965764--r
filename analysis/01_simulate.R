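#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study dataset.
#
# Emulates the study design downstream steps assume: a 4-taxon clade
# (3 focal taxa + 1 outgroup-like tip) with 3 biological replicates each,
# 300 MS1 features in two ion modes, a shared core metabolome with
# Brownian species effects along the species tree, 10 planted
# species-specific marker features per taxon (four-fold effect), ontology
# annotations for 60% of features, and RDKit-style descriptors. Writes
# everything as plain text under results/data/.

suppressMessages(library(chemophen))

seed <- 1
out <- "results/data"
# a little MCAR missingness is switched on for this walk-through so the
# presence/absence, uniqueness and sunburst steps have something to do;
# zero-imputed missing values are a strong noise source on the log scale
# (see the methods vignette), so the rate is kept low
cfg <- synth_config(seed = seed, missing_rate = 0.02)
bundle <- synth_generate(cfg)
write_synth_bundle(bundle, out)

imgs <- make_reference_images(bundle, pixels_per_image = 32, seed = seed)
write_reference_images(imgs, file.path(out, "images"))

cat("Simulated", nrow(bundle$feature_table$samples), "samples x",
    nrow(bundle$feature_table$features), "features;",
    nrow(bundle$annotations), "annotated;",
    length(unlist(bundle$planted_markers)), "planted markers.\n")
cat("Species tree:", ape::write.tree(bundle$true_tree$phylo), "\n")
cat("Wrote bundle and", length(imgs), "phenotype images to", out, "\n")
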
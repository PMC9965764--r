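#!/usr/bin/env Rscript
# Step 3 — chemodiversity: richness, unique variables, Shannon H', Pielou J,
# ANOVA + Tukey HSD among taxa, and per-level sunburst counts over the
# compound-class ontology.

suppressMessages(library(chemophen))

raw <- filter_rt(read_feature_table("results/data/feature_table.csv"), 1020)
ont <- read_ontology("results/data/ontology.tsv")
ann <- select_best_annotation(read_annotations("results/data/annotations.tsv", ont))

div <- diversity_table(raw)
utils::write.table(div$per_sample, "results/diversity_per_sample.tsv",
                   sep = "\t", row.names = FALSE)
utils::write.table(div$per_taxon, "results/diversity_per_taxon.tsv",
                   sep = "\t", row.names = FALSE)
cat("Per-taxon unique features:\n")
print(div$per_taxon)

at <- anova_tukey(div$per_sample$shannon_H, div$per_sample$taxon)
cat(sprintf("Shannon H' ANOVA: F = %.3f, p = %.4f\n", at$F, at$p))
utils::write.table(at$tukey, "results/tukey_shannon.tsv", sep = "\t",
                   row.names = FALSE)

counts <- do.call(rbind, lapply(unique(raw$samples$taxon), function(tx) {
  grp <- raw$samples$sample_id[raw$samples$taxon == tx]
  cbind(taxon = tx, sunburst_counts(raw, ann, ont, grp))
}))
utils::write.table(counts, "results/sunburst_counts.tsv", sep = "\t",
                   row.names = FALSE)
cat("Wrote diversity tables and sunburst counts under results/\n")
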
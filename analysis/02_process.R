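#!/usr/bin/env Rscript
# Step 2 — condition the MS1 feature table.
#
# Retention-time filter (< 1020 s), ln(1+x) transform with zero-imputed
# missing values, presence/absence calls at 1e-8 % of the median non-zero
# abundance, a positive/negative mode compatibility check on the joined
# table, and a PCA overview of the conditioned data.

suppressMessages(library(chemophen))

raw <- read_feature_table("results/data/feature_table.csv")
raw <- filter_rt(raw, 1020)
cat("After RT filter:", ncol(raw$abundance), "features\n")

pres <- presence_absence(raw)
cat(sprintf("Presence threshold: %.3g (%.1f%% of calls present)\n",
            attr(pres, "threshold"), 100 * mean(pres)))

logt <- log_transform(raw)

# mode compatibility on the log scale: split by ion mode, compare the
# medians/variances of non-zero entries, re-join with prefixed ids
pos <- subset_features(logt, features = logt$features$feature_id[logt$features$ion_mode == "pos"])
neg <- subset_features(logt, features = logt$features$feature_id[logt$features$ion_mode == "neg"])
joined <- join_modes(pos, neg)
dev <- attr(joined, "mode_join_deviation")
cat(sprintf("Mode join: median deviation %.3f, variance deviation %.3f (%s)\n",
            dev["median"], dev["variance"],
            if (attr(joined, "mode_join_warning")) "WARNING: above 10%" else "compatible"))

write_feature_table(logt, "results/processed.csv")

pc <- pca_overview(logt, n_components = 4)
cat("PCA explained variance fractions:",
    paste(sprintf("%.3f", pc$explained), collapse = ", "), "\n")
utils::write.csv(data.frame(sample_id = rownames(pc$scores),
                            taxon = logt$samples$taxon, pc$scores),
                 "results/pca_scores.csv", row.names = FALSE)
cat("Wrote results/processed.csv and results/pca_scores.csv\n")
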
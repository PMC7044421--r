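#!/usr/bin/env Rscript

# Stage 1: simulate the study cohort.
#
# Generates the default synthetic profile — 283 polar metabolites measured in
# 15 animals (8 condition-A "MS", 7 condition-B "LD") mixed from 5 planted
# metabolic signatures with multiplicative 10% noise — together with a toy
# pathway library in which half the sets track one planted signature each.
# Writes the abundance table, sample metadata, GMT library and the planted
# ground truth under results/data/.

suppressPackageStartupMessages(library(metabosig))

seed <- 11
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

gt <- generate_ground_truth(seed = seed)
x <- render_matrix(gt)
lib <- generate_pathway_library(gt, n_sets = 10, set_size = 15,
                                aligned_fraction = 0.5, seed = seed)

write_abundance_table(x, file.path(out, "abundance.tsv"),
                      metadata = file.path(out, "metadata.tsv"))
write_gmt(lib, file.path(out, "pathways.gmt"))
jsonlite::write_json(
  list(seed = gt$seed, noise_sigma = gt$noise_sigma, separation = gt$separation,
       dominant = as.list(gt$dominant), group_labels = as.list(gt$group_labels)),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("cohort: %d metabolites x %d samples (%d A, %d B), %d planted signatures\n",
            nrow(x$values), ncol(x$values), sum(gt$group_labels == "A"),
            sum(gt$group_labels == "B"), ncol(gt$true_signatures)))
cat(sprintf("abundance range: %.3g .. %.3g; pathway sets: %d (aligned: %d)\n",
            min(x$values), max(x$values), length(lib$sets),
            sum(grepl("^aligned", names(lib$sets)))))
cat("written to", out, "\n")
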
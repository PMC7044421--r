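#!/usr/bin/env Rscript

# Stage 3: sample structure.
#
# Clusters the 15 samples on their signature weight profiles (correlation
# distance, average linkage), validates the dendrogram by its cophenetic
# correlation coefficient, cuts it automatically by silhouette, compares the
# clusters with the known condition groups, and writes the Newick tree,
# cluster labels and per-cluster signature centroids (%).

suppressPackageStartupMessages(library(metabosig))

wdf <- utils::read.delim("results/signatures/weights.tsv", check.names = FALSE)
w <- as.matrix(wdf[, -1])
rownames(w) <- wdf[[1]]
meta <- read_sample_metadata("results/data/metadata.tsv")
dir.create("results/clusters", recursive = TRUE, showWarnings = FALSE)

sc <- cluster_samples(w)
print(sc)
lab <- cut_clusters(sc)
cent <- cluster_centroids(w, lab)

cat(sprintf("auto cut: %d clusters\n", attr(lab, "k")))
tab <- table(cluster = lab, group = meta[colnames(w)])
print(tab)
cat("cluster centroids (%):\n")
print(round(cent, 1))

write_dendrogram_newick(sc, "results/clusters/dendrogram.nwk")
utils::write.table(
  data.frame(sample_id = names(lab), cluster = as.integer(lab),
             group = unname(meta[names(lab)])),
  "results/clusters/labels.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(cluster = rownames(cent), round(cent, 4), check.names = FALSE),
  "results/clusters/centroids.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("cophenetic correlation coefficient: %.3f\n", sc$cophenetic_coefficient))
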
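#!/usr/bin/env Rscript

# Stage 5: per-metabolite group comparison and ratio analyses.
#
# Runs the two-sided Student t-test on every metabolite between the two
# condition groups (means +/- SD, fold change, star codes, no multiplicity
# correction in the main table, mirroring conventional metabolomics
# reporting), and illustrates the precursor-to-product ratio analysis
# (product as % of precursor, means +/- SEM) on a metabolite pair drawn from
# the dominant signatures of the two groups.

suppressPackageStartupMessages(library(metabosig))

x <- read_abundance_table("results/data/abundance.tsv",
                          metadata = "results/data/metadata.tsv")
dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)

res <- differential_abundance(x, "A", "B", test = "student", append_bh = TRUE)
utils::write.table(res, "results/stats/differential.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

sig_hits <- res[res$p < 0.05, ]
cat(sprintf("%d / %d metabolites at p < 0.05 (Student t, two-sided)\n",
            nrow(sig_hits), nrow(res)))
top <- res[order(res$p), ][1:5, c("metabolite", "mean_a", "mean_b",
                                  "fold_change", "p", "stars")]
cat("strongest group differences:\n")
print(top, row.names = FALSE)

# ratio analysis on the two most group-discriminating metabolites with
# strictly positive precursor values
cand <- res[order(res$p), "metabolite"]
pre <- cand[1]
prod <- cand[2]
rr <- precursor_product_ratio(x, pre, prod)
print(rr)
utils::write.table(
  cbind(precursor = pre, product = prod, rr$summary,
        t = rr$t, df = rr$df, p = rr$p),
  "results/stats/ratio.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
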
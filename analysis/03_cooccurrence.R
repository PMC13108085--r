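#!/usr/bin/env Rscript
# Stage 3 — intra-protein co-occurrence of the anchor protein's own sites.
#
# For every ordered pair of callable anchor-protein sites, tallies the
# II/ID/DI/DD direction combinations over shared differential datasets and
# reports the positive and negative co-modulation ratios (long format,
# ready for a triangular heat-map layout).

suppressPackageStartupMessages(library(phosphocomod))

corpus <- read_corpus("results/fixture/profiling.tsv",
                      "results/fixture/differential.tsv")
mat <- cooccurrence_matrix(corpus, "P07947")
write_results_table(mat, "results/cooccurrence.tsv")

cat("Ordered site pairs:", nrow(mat), "\n")
anchor_rows <- mat[mat$site_a == "Y426", ]
anchor_rows$total <- with(anchor_rows, n_cc + n_cd + n_dc + n_dd)
top <- anchor_rows[order(-anchor_rows$total), ][1:5, ]
cat("Strongest co-occurrence partners of Y426 (by shared callable datasets):\n")
print(as.data.frame(top[, c("site_b", "n_cc", "n_cd", "n_dc", "n_dd",
                            "pos_ratio")]))
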
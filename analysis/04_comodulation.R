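#!/usr/bin/env Rscript
# Stage 4 — anchor-versus-partners co-modulation with high-confidence filters.
#
# Categorizes every phosphosite on other proteins against the anchor's
# per-dataset direction calls, applies one-sided Fisher's exact tests to the
# concordance tables, computes co-modulation ratios, and flags
# high-confidence partners (p < 0.05, ratio above 10% of the anchor's
# callable-dataset count, support from >= 3 studies and >= 3 conditions).

suppressPackageStartupMessages(library(phosphocomod))

corpus <- read_corpus("results/fixture/profiling.tsv",
                      "results/fixture/differential.tsv")
res <- run_comodulation(corpus, "P07947:Y426")
write_results_table(res, "results/comodulation.tsv")

cat("Anchor callable in", attr(res, "n_anchor_datasets"),
    "differential datasets; ratio cutoff",
    attr(res, "cutoff"), "\n")
hc <- res[res$high_confidence, ]
cat("Partner sites evaluated:", nrow(res), "\n")
cat("High-confidence positive:", sum(hc$sign_class == "positive"),
    "| negative:", sum(hc$sign_class == "negative"), "\n")

overlaps <- condition_set_overlap(
  res, list(c("metformin", "il-33", "caffeine"),
            c("metformin", "il-33", "caffeine", "egf"),
            c("metformin", "il-33", "her2")),
  corpus = corpus)
write_results_table(overlaps, "results/condition_overlaps.tsv")
cat("\nHigh-confidence partners shared across condition-code subsets:\n")
print(as.data.frame(overlaps))
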
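#!/usr/bin/env Rscript
# Stage 2 — nominate the predominant anchor-protein phosphosite.
#
# Counts, for every site of the anchor protein, the distinct profiling
# datasets reporting it as Class-1 and the distinct differential datasets
# reporting it (plus those where it actually carries a direction call),
# then ranks the sites by the product of max-normalized frequencies.

suppressPackageStartupMessages(library(phosphocomod))

corpus <- read_corpus("results/fixture/profiling.tsv",
                      "results/fixture/differential.tsv")
freqs <- site_frequencies(corpus, "P07947")
ranked <- rank_predominance(freqs)
write_results_table(ranked, "results/predominance.tsv")

cat("Site frequencies for P07947 (YES1-like anchor protein):\n")
print(as.data.frame(ranked[, c("site", "profile_count", "differential_count",
                               "callable_count", "predominance_score")]))
cat("\nNominated predominant site:", ranked$site[1], "\n")
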
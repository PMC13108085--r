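#!/usr/bin/env Rscript
# Stage 5 — annotation overlays and the site-resolved network.
#
# Joins the high-confidence co-modulation table against the curated
# annotation fixtures: binary interactors of the anchor protein, upstream
# regulators (kinases of the anchor site itself), candidate downstream
# substrates, kinase/phosphatase classes with site-effect labels, and
# disease-biomarker overlaps. Also runs the one-command pipeline to emit
# the full bundle (TSVs + SIF network + manifest) under results/pipeline/.

suppressPackageStartupMessages(library(phosphocomod))

corpus <- read_corpus("results/fixture/profiling.tsv",
                      "results/fixture/differential.tsv")
res <- run_comodulation(corpus, "P07947:Y426")
ann <- "results/fixture/annotations"
ints <- read_interactions(file.path(ann, "interactions.tsv"))
ks <- read_kinase_substrates(file.path(ann, "kinase_substrate.tsv"))
enz <- read_enzyme_annotations(file.path(ann, "enzymes.tsv"))
bm <- read_biomarkers(file.path(ann, "biomarkers.tsv"))

interactors <- tag_binary_interactors(res, ints, "P07947")
upstream <- identify_upstream_regulators(res, ks, "P07947:Y426")
substrates <- identify_downstream_substrates(res, ks, "P07947")
enzymes <- classify_enzyme_partners(res, enz)
bm_pos <- biomarker_overlap(res, bm, "positive")

write_results_table(interactors, "results/interactors.tsv")
write_results_table(upstream, "results/upstream.tsv")
write_results_table(substrates, "results/substrates.tsv")
write_results_table(enzymes, "results/enzymes.tsv")
write_results_table(bm_pos, "results/biomarker_overlap_positive.tsv")

cat("High-confidence binary interactor sites:", nrow(interactors),
    "on", length(unique(interactors$accession)), "proteins\n")
cat("Upstream regulators of the anchor site:",
    paste(unique(upstream$gene), collapse = ", "), "\n")
cat("Candidate downstream substrates:",
    paste(paste0(substrates$gene, "-", substrates$residue,
                 substrates$position), collapse = ", "), "\n")
cat("Kinase sites:", sum(enzymes$enzyme_class == "kinase"),
    "| phosphatase sites:", sum(enzymes$enzyme_class == "phosphatase"), "\n")
cat("Biomarker overlaps (positive sign):", nrow(bm_pos), "rows across",
    length(unique(bm_pos$disease)), "diseases\n")

# full pipeline bundle for comparison with the stage-by-stage outputs
run_pipeline(profile_path = "results/fixture/profiling.tsv",
             differential_path = "results/fixture/differential.tsv",
             anchor_protein = "P07947", annotations_dir = ann,
             out_dir = "results/pipeline", verbose = TRUE)
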
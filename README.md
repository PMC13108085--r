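# phosphocomod

Site-resolved co-modulation analysis of compiled phosphoproteomic corpora.

## The problem

Large numbers of published human LC-MS/MS phosphoproteomics experiments each
report fold changes and p-values for whatever confidently localized
("Class-1") phosphosites they happened to detect. Meta-analysing such a
corpus around one **anchor phosphosite** — for example the Src-family-kinase
activation-loop site YES1 Y426 — can reveal which other phosphosites move
*with* it (positive co-modulation) or *against* it (negative co-modulation)
across many unrelated biological conditions, and how those partners sit in
the surrounding interaction, kinase-substrate, phosphatase and
disease-biomarker networks.

`phosphocomod` implements that pipeline for anyone with corpus tables in the
package's TSV dialect (or the shipped synthetic generator):

1. **QC / calling.** An observation is Class-1 when localization probability
   ≥ 0.75 *or* A-score ≥ 13; it is called *increased* when additionally
   p < 0.05 and fold change ≥ 1.3, *decreased* when p < 0.05 and fold
   change ≤ 0.76, otherwise *not callable*.
2. **Predominance.** Sites of the anchor protein are ranked by the product
   of max-normalized detection frequencies in the profiling and
   differential corpora; the top site is the anchor.
3. **Co-occurrence.** Intra-protein pairs are tallied over shared
   differential datasets into II/ID/DI/DD counts with ratios
   (nII + nDD)/(nID + nDI) and its reciprocal.
4. **Co-modulation.** Every phosphosite on another protein (PsOP) forms a
   2×2 concordance table against the anchor (rows = anchor
   increased/decreased, columns = partner increased/decreased). A one-sided
   Fisher's exact test on each tail classifies the pair as positively or
   negatively co-modulated; *high-confidence* partners additionally need a
   co-modulation ratio exceeding 10% of the anchor's callable-dataset count
   (72 datasets → cutoff 7.2) and support from ≥ 3 distinct studies and
   ≥ 3 distinct experimental conditions.
5. **Overlays.** High-confidence partners are joined against binary
   interactors, site-specific kinase-substrate records (upstream regulators
   and candidate downstream substrates), kinase/phosphatase annotations with
   functional site effects, and disease biomarker gene lists; everything is
   exported as TSV plus a SIF network.

A seeded synthetic-corpus generator with a machine-readable truth record
makes every stage testable without downloading anything.

## Worked example

The numbered drivers under `analysis/` run the whole study on the default
synthetic fixture (72 differential datasets, anchor `P07947:Y426`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_predominance.R
Rscript analysis/04_comodulation.R
```

which prints (seed 4261):

```
Nominated predominant site: P07947:Y426

Anchor callable in 72 differential datasets; ratio cutoff 7.2
Partner sites evaluated: 560
High-confidence positive: 37 | negative: 9
```

Equivalently, in R:

```r
library(phosphocomod)
sim <- generate_corpus(default_generator_config(seed = 4261))
res <- run_comodulation(sim$corpus, "P07947:Y426")
attr(res, "cutoff")          # 7.2 = 0.10 * 72 callable anchor datasets
sum(res$high_confidence)     # 46 high-confidence partner sites
```

Each result row carries the four concordance counts (`n_cc`, `n_cd`,
`n_dc`, `n_dd` — the ItIo/ItDo/DtIo/DtDo tallies), both one-sided exact-test
p-values, both ratios, BH q-values (auxiliary), the sign class, and the
redundancy support. `run_pipeline()` composes all stages in one call and
writes the TSV/SIF/manifest bundle.

## Layout

- `R/` — the package: corpus I/O and validation, QC filters, predominance,
  co-occurrence, co-modulation, annotation overlays, synthetic generator,
  pipeline.
- `analysis/` — numbered narrative drivers writing tables under `results/`.
- `inst/extdata/annotations/` — synthetic curated annotation fixtures
  (interactors, kinase-substrate, enzymes, biomarkers).
- `vignettes/phosphosite-comodulation.Rmd` — the methods vignette: model,
  assumptions, parameter choices, generator design, numerical decisions and
  known limitations.
- `tests/testthat/` — unit, property and end-to-end acceptance tests.
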
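---
title: "Phosphosite co-modulation analysis: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphosite co-modulation analysis: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphocomod)
```

## The setting

A compiled phosphoproteomic corpus is a collection of many small,
heterogeneous experiments. Two kinds of dataset enter the analysis:
*qualitative profiling* datasets, which merely report which Class-1
phosphosites were detected, and *quantitative differential* datasets, which
compare a test condition against a control and report, per site, a linear
fold change and a p-value from the original study's own statistics. Raw
intensities are not re-analysed: the corpus is taken at face value, each
dataset contributing at most one retained observation per site.

All pairwise statistics in the package are built from one primitive, the
per-dataset **direction call**: a site in a differential dataset is
*increased* when it is confidently localized (localization probability
≥ 0.75 **or** A-score ≥ 13), significant (p < 0.05) and its fold change is
≥ 1.3; *decreased* with fold change ≤ 0.76; and *not callable* otherwise.
Not-callable observations contribute to nothing downstream — there is no
"unchanged" category, because a non-significant or mid-range fold change in
a heterogeneous corpus is evidence of absence, not absence of change.

The disjunctive Class-1 rule deserves a note: parts of the source
literature phrase the localization requirement conjunctively. The
definitional convention for Class-1 sites is the disjunction, which is the
default here (`filter_thresholds(class1_rule = "or")`); the conjunctive
variant is available by configuration and tightening to it can only remove
calls (a monotonicity property the test suite checks).

## Thresholds

All thresholds live in a single `filter_thresholds()` record:

| parameter | default | meaning |
|---|---|---|
| `loc_prob_min` | 0.75 | minimum localization probability (inclusive) |
| `a_score_min` | 13 | minimum A-score (inclusive) |
| `p_max` | 0.05 | calls require p strictly below this |
| `fc_up_min` | 1.3 | linear fold change for an increase (inclusive) |
| `fc_down_max` | 0.76 | linear fold change for a decrease (inclusive) |

Fold changes are linear test/control ratios throughout; no log transform is
applied because the calling bounds are themselves stated on the linear
scale. Note the default down-bound 0.76 is *not* exactly 1/1.3 ≈ 0.769, so
the default calling is slightly asymmetric under fold-change inversion;
`filter_thresholds(fc_down_max = 1/1.3)` restores exact symmetry, and the
suite tests the inversion property under that symmetric configuration.

## Predominance

The anchor site should be one reported frequently in **both** corpora. Each
site of the anchor protein gets two frequencies — distinct profiling
datasets reporting it as Class-1, and distinct differential datasets
reporting it as Class-1 (the count of datasets where it actually carries a
direction call is reported separately, since the two readings of
"detected" differ and both are informative). `rank_predominance()` scores
each site by the product of max-normalized frequencies,

$$\mathrm{score} = \frac{n_\text{profile}}{\max n_\text{profile}} \times
  \frac{n_\text{differential}}{\max n_\text{differential}},$$

higher is better, ties broken by the larger differential count and then by
sequence position. We considered the plain rank product of the two
frequency lists, but it over-rewards topping a single list: a site leading
the profiling corpus while being nearly absent from the differential corpus
can outrank a site that is strong in both, which inverts the intended
meaning of "predominant in both corpora" precisely in the situation the
statistic exists for (a well-profiled N-terminal site versus an
activation-loop site that dominates the differential corpus). The
normalized-frequency product is scale-free across corpus sizes, gives a
lone site the score 1, and requires genuine weight in both lists. Dense
per-corpus ranks are still emitted for inspection.

## Co-modulation statistics

For an anchor site $t$ and a partner site $o$ on another protein, every
differential dataset in which **both** carry a direction call falls in one
of four cells: ItIo ($n_{cc}$, both increased), ItDo ($n_{cd}$), DtIo
($n_{dc}$), DtDo ($n_{dd}$). These four tallies form a 2×2 contingency
table with rows = anchor direction and columns = partner direction — the
only 2×2 the four categories can populate. Association is tested with
one-sided Fisher's exact tests: the *concordant* alternative is the upper
hypergeometric tail on the $n_{cc}$ cell given the margins, the
*discordant* alternative the lower tail. Any zero margin makes the table
degenerate and returns p = 1. Since the two tails overlap in the observed
table, $p_{+} + p_{-} = 1 + P(X = n_{cc}) \ge 1$, so both can never be
significant at any $\alpha \le 0.5$ (asserted in code).

The effect size is the **co-modulation ratio**
$(n_{cc}+n_{dd})/(n_{cd}+n_{dc})$ (positive form; the negative form is its
reciprocal). Two degenerate outcomes are deliberately distinct markers: a
zero denominator with concordant evidence yields `Inf` (passes any finite
cutoff), while an all-zero table yields `NA` (no shared evidence; never
high-confidence).

A partner is **high-confidence** when three conditions hold:

1. its one-sided p-value is below `alpha` (default 0.05, raw — BH q-values
   are emitted per tail family as an auxiliary column but intentionally do
   not enter the classification);
2. the ratio for its sign strictly exceeds `cutoff_fraction` (default
   0.10) times the number of datasets in which the *anchor* carries a
   direction call — an anchor callable in 72 datasets gives the cutoff
   7.2. This rule compares a dimensionless ratio against a fraction of a
   dataset count; the pairing of units is heterodox, and it is implemented
   literally because it is the defining rule of the procedure, not an
   aesthetic choice of ours;
3. it is supported by at least `min_studies` (3) distinct study ids and
   `min_conditions` (3) distinct normalized condition codes among the
   co-callable datasets — the redundancy filter that prevents one
   multi-timepoint study or one recycled condition from fabricating
   confidence.

### Symmetries

The construction has exact symmetries that the suite verifies: inverting
every partner call swaps the two tails and the positive/negative
classification; inverting the anchor's calls does the same (concordance is
relative, so an anchor-only flip is equivalent to a partner-only flip and
maps the counts $(n_{cc},n_{cd},n_{dc},n_{dd}) \to
(n_{dc},n_{dd},n_{cc},n_{cd})$); and inverting the global direction
convention — every call of every site — leaves every statistic invariant.
High-confidence membership is invariant under all three flips, because the
signed ratio follows its sign class.

### The cutoff is aggressive near its design point

One structural property worth knowing: with the anchor callable in $n$
datasets, the 10% rule demands a concordant *fraction* above
$0.1n/(0.1n+1)$ among co-observed datasets. At $n = 72$ that is
$7.2/8.2 = 0.878$. A partner whose true concordance is 0.9 — already a
strong biological signal — sits less than one binomial standard deviation
($\sqrt{0.9 \cdot 0.1/72} \approx 0.035$) above that bar, so roughly a
quarter to a third of such partners fall below the cutoff by sampling noise
alone whenever the anchor count is near 72. The filter is therefore
*conservative by design at exactly the corpus scale that motivates it*;
recovery of concordance-0.9 partners is reliable only when the required
fraction is comfortably below the true concordance (e.g. 40 anchor
datasets → cutoff 4 → required fraction 0.8, where the suite demonstrates
≥ 90% sensitivity). Users who need sensitivity at larger anchor counts
should lower `cutoff_fraction`; we keep the literal rule as the default
because it is the procedure's own definition.

## The synthetic generator

`generate_corpus()` emulates exactly the structure the analysis consumes:

* each differential dataset gets a study id and a condition code
  round-robin over `n_studies`/`n_conditions` (5 and 6 in the default
  fixture, so redundancy support accumulates quickly, as it does in a real
  corpus where popular conditions recur);
* the anchor is callable in a controlled set of datasets with direction
  drawn Bernoulli(`anchor_up_probability`); the default fixture pins the
  anchor count by using 72 differential datasets with callable fraction 1,
  so the cutoff is 7.2 by construction rather than by sampling;
* each planted partner co-observes an anchor call with probability
  `coobservation` (0.9 in the default fixture — the fixture is a
  strong-co-measurement bundle meant to exercise recovery, not to mimic
  the much sparser overlap of real repositories) and matches the anchor's
  direction with probability `concordance` (0.9 for the 50 positive
  plants, 0.1 for the 10 negative ones);
* 500 background sites on their own proteins draw directions independently
  of the anchor (observation probability 0.2);
* directions are drawn **first**, and fold changes, p-values and
  localization metrics are then sampled conditionally so that every
  emitted row classifies back to its drawn direction under the default
  thresholds — boundary flakiness is impossible by construction, which is
  the point: the tests target the analysis, not threshold jitter. About
  20% of rows carry only an A-score so both Class-1 clauses stay
  exercised.

The truth record (per-dataset anchor directions, per-site directions,
expected pair tallies, planted sign classes) is exactly recomputable from
the emitted tables, and the suite checks that it is.

What the generator does **not** emulate: peptide-level evidence and
multi-phosphorylated peptides, realistic intensity distributions, batch
structure between studies, non-Class-1 noise rows, or correlated
missingness. Passing tests on this corpus therefore demonstrate the
correctness of the counting, testing and filtering machinery under the
model's own assumptions — not robustness to everything a real compiled
corpus contains.

## Numerical and degenerate-input decisions

* Exact tests use the hypergeometric tail directly (`phyper`); the suite
  cross-checks every table with margins up to 12 against an independent
  enumeration oracle (agreement < 1e-10) and against
  `stats::fisher.test`.
* Duplicate (dataset, site) differential rows keep the smallest p-value;
  duplicates with *conflicting* directions drop the site from that dataset
  entirely (conservative, and logged). Profiling duplicates keep the
  best-localized row.
* Condition codes are normalized by trimming and case-folding before
  uniqueness counts; no fuzzy matching is attempted.
* Positions are 1-based on the canonical sequence; there is no isoform
  arithmetic.
* Predominance ties break by larger differential count, then smaller
  position — deterministic output regardless of input order.
* The empty corpus, header-only tables, one-site proteins and partners
  with no shared callable dataset all return empty-but-typed results
  rather than errors.

## Problem sizes

The shipped analyses and tests run at desk scale, chosen to exercise every
code path with comfortable statistical resolution: 72 differential + 60
profiling datasets, 560 partner sites (60 planted + 500 background) in the
default fixture; 2,000 simulated independent pairs for the type-I-error
check; exhaustive enumeration of all 2×2 tables with margins ≤ 12 for the
exact-test oracle. Headline partner counts from corpora of thousands of
datasets are not reproducible at this scale and are not targets of the
test suite.

## Known limitations

* The analysis inherits every bias of the compiled corpus: study-centric
  statistics, heterogeneous platforms, and selective reporting. The
  redundancy filter mitigates, not removes, over-representation.
* The cutoff's unit-heterodox definition (ratio vs. fraction of a count)
  makes its stringency scale with corpus size, as discussed above.
* Upstream/downstream annotation joins are only as site-specific as the
  annotation tables; predicted records are passed through with their
  evidence class, not re-scored.
* The package deliberately does not render figures; outputs are TSV and
  SIF for external viewers.
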
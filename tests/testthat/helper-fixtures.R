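# hand-built corpus used across unit tests: 6 differential datasets over 3
# studies and 3 conditions, an anchor site with 5 direction calls, one
# concordant partner, one discordant partner and one anchor co-site.
#
#   dataset  study  cond   anchor Y426   AAA1:S10   BBB1:S20   cosite T427
#   d1       P1     c1     increased     increased  decreased  increased
#   d2       P2     c2     increased     increased  .          .
#   d3       P1     c2     increased     .          .          .
#   d4       P3     c3     decreased     decreased  increased  decreased
#   d5       P2     c3     decreased     .          .          .
#   d6       P3     c1     not_callable  .          .          .
hand_meta <- function() {
  tibble::tribble(
    ~dataset_id, ~study_id, ~condition_code,
    "d1", "P1", "c1",
    "d2", "P2", "c2",
    "d3", "P1", "c2",
    "d4", "P3", "c3",
    "d5", "P2", "c3",
    "d6", "P3", "c1"
  )
}

hand_row <- function(dataset, acc, gene, residue, position, dir) {
  vals <- switch(dir,
    increased = list(fc = 2.0, p = 0.01),
    decreased = list(fc = 0.5, p = 0.01),
    not_callable = list(fc = 1.0, p = 0.5)
  )
  meta <- hand_meta()
  m <- meta[meta$dataset_id == dataset, ]
  tibble::tibble(
    dataset_id = dataset, study_id = m$study_id,
    condition_code = m$condition_code, enrichment = "STY",
    accession = acc, gene = gene, residue = residue,
    position = as.integer(position),
    loc_prob = 0.9, a_score = NA_real_,
    fold_change = vals$fc, p_value = vals$p
  )
}

make_hand_corpus <- function() {
  rows <- dplyr::bind_rows(
    hand_row("d1", "P07947", "YES1", "Y", 426, "increased"),
    hand_row("d2", "P07947", "YES1", "Y", 426, "increased"),
    hand_row("d3", "P07947", "YES1", "Y", 426, "increased"),
    hand_row("d4", "P07947", "YES1", "Y", 426, "decreased"),
    hand_row("d5", "P07947", "YES1", "Y", 426, "decreased"),
    hand_row("d6", "P07947", "YES1", "Y", 426, "not_callable"),
    hand_row("d1", "AAA1", "GENA", "S", 10, "increased"),
    hand_row("d2", "AAA1", "GENA", "S", 10, "increased"),
    hand_row("d4", "AAA1", "GENA", "S", 10, "decreased"),
    hand_row("d1", "BBB1", "GENB", "S", 20, "decreased"),
    hand_row("d4", "BBB1", "GENB", "S", 20, "increased"),
    hand_row("d1", "P07947", "YES1", "T", 427, "increased"),
    hand_row("d4", "P07947", "YES1", "T", 427, "decreased")
  )
  prof <- tibble::tibble(
    dataset_id = c("pr1", "pr1", "pr2"),
    study_id = c("P9", "P9", "P8"),
    condition_code = c("c9", "c9", "c8"), enrichment = "STY",
    accession = c("P07947", "AAA1", "P07947"),
    gene = c("YES1", "GENA", "YES1"),
    residue = c("Y", "S", "Y"), position = c(426L, 10L, 426L),
    loc_prob = 0.9, a_score = NA_real_
  )
  phospho_corpus(profile_obs = prof, differential_obs = rows)
}

# independent exact-test oracle: exhaustive enumeration over all 2x2 tables
# sharing the observed margins, probabilities from binomial coefficients
enum_fisher <- function(a, b, c, d, alternative) {
  r1 <- a + b
  c1 <- a + c
  c2 <- b + d
  N <- a + b + c + d
  if (N == 0 || r1 == 0 || c + d == 0 || c1 == 0 || c2 == 0) return(1)
  xs <- max(0, r1 - c2):min(r1, c1)
  probs <- choose(c1, xs) * choose(c2, r1 - xs) / choose(N, r1)
  if (alternative == "concordant") sum(probs[xs >= a]) else sum(probs[xs <= a])
}

# brute-force pair tally straight from a corpus (independent of
# direction_matrix/pair_counts internals beyond classify_abundance)
brute_pair_counts <- function(corpus, site_a, site_b,
                              thresholds = filter_thresholds()) {
  obs <- corpus$differential_obs
  obs$dir <- classify_abundance(obs$fold_change, obs$p_value,
                                obs$loc_prob, obs$a_score, thresholds)
  get <- function(lab) {
    x <- obs[obs$site == lab & obs$dir %in% c("increased", "decreased"), ]
    stats::setNames(x$dir, x$dataset_id)
  }
  da <- get(site_a)
  db <- get(site_b)
  shared <- intersect(names(da), names(db))
  c(n_cc = sum(da[shared] == "increased" & db[shared] == "increased"),
    n_cd = sum(da[shared] == "increased" & db[shared] == "decreased"),
    n_dc = sum(da[shared] == "decreased" & db[shared] == "increased"),
    n_dd = sum(da[shared] == "decreased" & db[shared] == "decreased"))
}

write_tmp_tsv <- function(tbl, na = ".") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(tbl, path, na = na, progress = FALSE)
  path
}
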
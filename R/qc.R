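#' Site-level quality and significance thresholds
#'
#' Defaults are the conventional Class-1 / differential-abundance settings:
#' localization probability >= 0.75 or A-score >= 13 for confident site
#' localization; fold change >= 1.3 (increased) or <= 0.76 (decreased) with
#' p < 0.05 for a direction call. Fold changes are linear test/control
#' ratios; no log transform is applied.
#'
#' @param loc_prob_min Minimum localization probability, in \[0, 1\].
#' @param a_score_min Minimum A-score.
#' @param p_max Significance threshold (calls require p strictly below it).
#' @param fc_up_min Minimum fold change for an "increased" call (inclusive).
#' @param fc_down_max Maximum fold change for a "decreased" call (inclusive).
#' @param class1_rule `"or"` (default) combines the two localization metrics
#'   disjunctively; `"and"` requires both.
#' @return An object of class `filter_thresholds`.
#' @examples
#' filter_thresholds()                     # defaults
#' filter_thresholds(fc_down_max = 1 / 1.3)  # direction-symmetric bounds
#' @export
filter_thresholds <- function(loc_prob_min = 0.75, a_score_min = 13,
                              p_max = 0.05, fc_up_min = 1.3,
                              fc_down_max = 0.76,
                              class1_rule = c("or", "and")) {
  class1_rule <- match.arg(class1_rule)
  stopifnot(
    loc_prob_min >= 0, loc_prob_min <= 1,
    p_max > 0, p_max <= 1,
    fc_down_max > 0, fc_down_max < 1, fc_up_min > 1
  )
  structure(
    list(loc_prob_min = loc_prob_min, a_score_min = a_score_min,
         p_max = p_max, fc_up_min = fc_up_min, fc_down_max = fc_down_max,
         class1_rule = class1_rule),
    class = "filter_thresholds"
  )
}

#' Class-1 localization test
#'
#' A site observation is Class-1 when its localization probability meets
#' `loc_prob_min` or its A-score meets `a_score_min` (boundaries inclusive).
#' A missing metric fails its own clause, so an observation with neither
#' metric is never Class-1. With `class1_rule = "and"` both clauses must
#' hold.
#'
#' @param loc_prob Numeric vector of localization probabilities (NA = missing).
#' @param a_score Numeric vector of A-scores (NA = missing).
#' @param thresholds A [filter_thresholds()].
#' @return Logical vector.
#' @export
is_class1 <- function(loc_prob, a_score, thresholds = filter_thresholds()) {
  lp_ok <- !is.na(loc_prob) & loc_prob >= thresholds$loc_prob_min
  as_ok <- !is.na(a_score) & a_score >= thresholds$a_score_min
  if (thresholds$class1_rule == "and") lp_ok & as_ok else lp_ok | as_ok
}

#' Three-way differential-abundance classification
#'
#' An observation is called `"increased"` when it is Class-1, significant
#' (p < `p_max`) and its fold change is at least `fc_up_min`; `"decreased"`
#' when Class-1, significant and at most `fc_down_max`; otherwise
#' `"not_callable"` (which covers non-Class-1 rows, non-significant rows and
#' fold changes between the two bounds).
#'
#' @param fold_change Positive numeric vector, linear test/control ratio.
#' @param p_value Numeric vector in \[0, 1\].
#' @param loc_prob,a_score Localization metrics (NA = missing).
#' @param thresholds A [filter_thresholds()].
#' @return Character vector with values `"increased"`, `"decreased"`,
#'   `"not_callable"`.
#' @examples
#' th <- filter_thresholds()
#' classify_abundance(c(1.3, 0.76, 1.0), c(0.01, 0.01, 0.001),
#'                    loc_prob = c(0.9, 0.9, 0.99), a_score = NA, th)
#' @export
classify_abundance <- function(fold_change, p_value, loc_prob = NA_real_,
                               a_score = NA_real_,
                               thresholds = filter_thresholds()) {
  stopifnot(all(fold_change > 0, na.rm = TRUE))
  n <- length(fold_change)
  loc_prob <- rep_len(loc_prob, n)
  a_score <- rep_len(a_score, n)
  p_value <- rep_len(p_value, n)
  callable <- is_class1(loc_prob, a_score, thresholds) &
    !is.na(p_value) & p_value < thresholds$p_max
  out <- rep("not_callable", n)
  out[callable & fold_change >= thresholds$fc_up_min] <- "increased"
  out[callable & fold_change <= thresholds$fc_down_max] <- "decreased"
  out
}

#' Direction-call matrix for a corpus
#'
#' One direction call per retained (differential dataset, site) observation.
#'
#' @param corpus A [phospho_corpus()].
#' @param thresholds A [filter_thresholds()].
#' @return Tibble with columns `dataset_id`, `accession`, `gene`, `residue`,
#'   `position`, `site`, `direction`.
#' @export
direction_matrix <- function(corpus, thresholds = filter_thresholds()) {
  stopifnot(inherits(corpus, "phospho_corpus"))
  obs <- corpus$differential_obs
  tibble::tibble(
    dataset_id = obs$dataset_id,
    accession = obs$accession, gene = obs$gene,
    residue = obs$residue, position = obs$position,
    site = obs$site,
    direction = if (nrow(obs)) {
      classify_abundance(obs$fold_change, obs$p_value,
                         obs$loc_prob, obs$a_score, thresholds)
    } else character()
  )
}
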
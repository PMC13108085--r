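#' Co-modulation analysis settings
#'
#' @param alpha Significance level for the one-sided exact tests (calls
#'   require p strictly below `alpha`).
#' @param cutoff_fraction High-confidence ratio cutoff as a fraction of the
#'   anchor's callable-dataset count (default 0.10: the "10% rule").
#' @param min_studies,min_conditions Redundancy filter: minimum numbers of
#'   distinct studies (PubMed-style ids) and of unique normalized
#'   experimental-condition codes among the datasets supporting a partner.
#' @return An object of class `comod_config`.
#' @export
comod_config <- function(alpha = 0.05, cutoff_fraction = 0.10,
                         min_studies = 3L, min_conditions = 3L) {
  stopifnot(alpha > 0, alpha <= 1,
            cutoff_fraction > 0, cutoff_fraction <= 1,
            min_studies >= 1, min_conditions >= 1)
  structure(
    list(alpha = alpha, cutoff_fraction = cutoff_fraction,
         min_studies = as.integer(min_studies),
         min_conditions = as.integer(min_conditions)),
    class = "comod_config"
  )
}

#' One-sided Fisher's exact test on a concordance table
#'
#' The four concordance counts form a 2x2 contingency table with rows =
#' anchor direction (increased / decreased) and columns = partner direction:
#' \preformatted{
#'              partner I   partner D
#'   anchor I      n_cc        n_cd
#'   anchor D      n_dc        n_dd
#' }
#' `alternative = "concordant"` tests enrichment of the concordant diagonal
#' (upper hypergeometric tail on the `n_cc` cell given the margins);
#' `"discordant"` tests the opposite tail. Any zero margin makes the table
#' degenerate and returns p = 1.
#'
#' @param n_cc,n_cd,n_dc,n_dd Non-negative integer vectors (recycled).
#' @param alternative `"concordant"` or `"discordant"`.
#' @return Numeric vector of exact tail probabilities.
#' @examples
#' fisher_one_sided(3, 0, 0, 3, "concordant")  # 1/20
#' @export
fisher_one_sided <- function(n_cc, n_cd, n_dc, n_dd,
                             alternative = c("concordant", "discordant")) {
  alternative <- match.arg(alternative)
  n <- max(length(n_cc), length(n_cd), length(n_dc), length(n_dd))
  a <- rep_len(as.numeric(n_cc), n); b <- rep_len(as.numeric(n_cd), n)
  c_ <- rep_len(as.numeric(n_dc), n); d <- rep_len(as.numeric(n_dd), n)
  if (any(is.na(c(a, b, c_, d))) || any(c(a, b, c_, d) < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  r1 <- a + b; r2 <- c_ + d      # anchor margins
  c1 <- a + c_; c2 <- b + d      # partner margins
  p <- if (alternative == "concordant") {
    stats::phyper(a - 1, c1, c2, r1, lower.tail = FALSE)
  } else {
    stats::phyper(a, c1, c2, r1)
  }
  p[r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0] <- 1
  pmin(p, 1)
}

#' High-confidence ratio cutoff from the anchor's dataset count
#'
#' The high-confidence rule compares a partner's co-modulation ratio to 10%
#' (by default) of the number of differential datasets in which the anchor
#' site carries a direction call; an anchor callable in 72 datasets yields
#' a cutoff of 7.2. The comparison downstream is strict (ratio must exceed
#' the cutoff). Note the rule compares a dimensionless ratio against a
#' fraction of a dataset count; this heterodox pairing of units is applied
#' literally, as defined.
#'
#' @param n_anchor_datasets Positive integer: anchor callable-dataset count.
#' @param cutoff_fraction Fraction of that count (default 0.10).
#' @return Positive numeric cutoff.
#' @examples
#' high_confidence_cutoff(72)  # 7.2
#' @export
high_confidence_cutoff <- function(n_anchor_datasets, cutoff_fraction = 0.10) {
  if (length(n_anchor_datasets) != 1L || is.na(n_anchor_datasets) ||
      n_anchor_datasets < 1) {
    stop("n_anchor_datasets must be a positive integer", call. = FALSE)
  }
  if (length(cutoff_fraction) != 1L || is.na(cutoff_fraction) ||
      cutoff_fraction <= 0) {
    stop("cutoff_fraction must be positive", call. = FALSE)
  }
  as.numeric(n_anchor_datasets) * cutoff_fraction
}

#' Concordance counts of one partner against the anchor
#'
#' Same tally semantics as [pair_counts()] with the anchor as first member;
#' rejects partners on the anchor's own protein (intra-protein pairs belong
#' to the co-occurrence analysis).
#'
#' @param directions A [direction_matrix()].
#' @param anchor,partner Site keys (or `"ACC:Y426"` strings).
#' @return One-row tibble with `n_cc`, `n_cd`, `n_dc`, `n_dd`.
#' @export
categorize_partner <- function(directions, anchor, partner) {
  anchor <- as_site_key(anchor)
  partner <- as_site_key(partner)
  if (identical(anchor$accession, partner$accession)) {
    stop("partner is on the anchor protein; use the co-occurrence analysis ",
         "for intra-protein pairs", call. = FALSE)
  }
  pair_counts(directions, anchor, partner)
}

#' Co-modulation analysis from a precomputed direction matrix
#'
#' The computational core behind [run_comodulation()], operating directly
#' on a [direction_matrix()]. Exposed so that direction-level
#' transformations (label flips, sensitivity analyses) can be studied
#' without re-deriving calls from measurement values.
#'
#' @param directions A [direction_matrix()].
#' @param datasets The corpus `datasets` metadata tibble.
#' @param anchor Anchor site key (or `"ACC:Y426"` string).
#' @param config A [comod_config()].
#' @return As [run_comodulation()].
#' @export
comod_from_directions <- function(directions, datasets, anchor,
                                  config = comod_config()) {
  anchor <- as_site_key(anchor)
  anchor_lab <- format(anchor)
  callable <- directions[directions$direction %in% c("increased", "decreased"), ]
  anchor_calls <- callable[callable$site == anchor_lab,
                           c("dataset_id", "direction")]
  names(anchor_calls)[2] <- "anchor_direction"
  n_anchor <- nrow(anchor_calls)
  if (n_anchor == 0L) {
    rlang::abort(paste0("anchor site ", anchor_lab,
                        " has no direction call in any differential dataset"),
                 class = "phosphocomod_missing_anchor")
  }
  partners <- callable[callable$accession != anchor$accession, ]
  joined <- dplyr::inner_join(partners, anchor_calls, by = "dataset_id")
  joined <- dplyr::left_join(
    joined, datasets[, c("dataset_id", "study_id", "condition_code")],
    by = "dataset_id"
  )
  res <- joined |>
    dplyr::group_by(.data$accession, .data$gene, .data$residue,
                    .data$position, .data$site) |>
    dplyr::summarise(
      n_cc = sum(.data$anchor_direction == "increased" &
                   .data$direction == "increased"),
      n_cd = sum(.data$anchor_direction == "increased" &
                   .data$direction == "decreased"),
      n_dc = sum(.data$anchor_direction == "decreased" &
                   .data$direction == "increased"),
      n_dd = sum(.data$anchor_direction == "decreased" &
                   .data$direction == "decreased"),
      n_studies = dplyr::n_distinct(.data$study_id),
      n_conditions = dplyr::n_distinct(.data$condition_code),
      supporting_studies = list(sort(unique(.data$study_id))),
      supporting_conditions = list(sort(unique(.data$condition_code))),
      .groups = "drop"
    )
  res$p_positive <- fisher_one_sided(res$n_cc, res$n_cd, res$n_dc, res$n_dd,
                                     "concordant")
  res$p_negative <- fisher_one_sided(res$n_cc, res$n_cd, res$n_dc, res$n_dd,
                                     "discordant")
  # both one-sided tails below alpha is impossible for alpha <= 0.5:
  # p_pos + p_neg = 1 + P(X = n_cc) >= 1
  stopifnot(!any(res$p_positive < config$alpha & res$p_negative < config$alpha))
  res$ratio_positive <- comod_ratio(res$n_cc, res$n_cd, res$n_dc, res$n_dd,
                                    "positive")
  res$ratio_negative <- comod_ratio(res$n_cc, res$n_cd, res$n_dc, res$n_dd,
                                    "negative")
  res$sign_class <- ifelse(res$p_positive < config$alpha, "positive",
                           ifelse(res$p_negative < config$alpha, "negative",
                                  "none"))
  res$bh_q_positive <- stats::p.adjust(res$p_positive, method = "BH")
  res$bh_q_negative <- stats::p.adjust(res$p_negative, method = "BH")
  res$bh_q_value <- ifelse(res$sign_class == "positive", res$bh_q_positive,
                           ifelse(res$sign_class == "negative",
                                  res$bh_q_negative, NA_real_))
  cutoff <- high_confidence_cutoff(n_anchor, config$cutoff_fraction)
  signed_ratio <- ifelse(res$sign_class == "positive", res$ratio_positive,
                         ifelse(res$sign_class == "negative",
                                res$ratio_negative, NA_real_))
  res$passes_redundancy <- res$n_studies >= config$min_studies &
    res$n_conditions >= config$min_conditions
  res$high_confidence <- res$sign_class != "none" &
    !is.na(signed_ratio) & signed_ratio > cutoff &
    res$passes_redundancy
  res <- dplyr::arrange(res, .data$bh_q_value, .data$accession, .data$position)
  attr(res, "anchor") <- anchor
  attr(res, "n_anchor_datasets") <- n_anchor
  attr(res, "cutoff") <- cutoff
  attr(res, "config") <- config
  class(res) <- c("comod_result", class(res))
  res
}

#' Run the anchor-versus-partners co-modulation analysis
#'
#' The core analysis: every phosphosite on other proteins (PsOP) that is
#' ever co-callable with the anchor site gets one result row with its four
#' concordance counts, one-sided exact-test p-values for the concordant and
#' discordant alternatives, co-modulation ratios, a sign class (positive /
#' negative / none, by whichever one-sided p falls below `alpha`),
#' Benjamini-Hochberg q-values per tail family (auxiliary only; the
#' classification uses raw p-values), its study/condition redundancy
#' support, and the high-confidence flag (sign assigned, corresponding
#' ratio strictly above [high_confidence_cutoff()], and redundancy
#' satisfied).
#'
#' @param corpus A [phospho_corpus()].
#' @param anchor Anchor site key (or `"ACC:Y426"` string); must carry at
#'   least one direction call in the corpus.
#' @param thresholds A [filter_thresholds()].
#' @param config A [comod_config()].
#' @return Tibble of class `comod_result`, one row per partner site, with
#'   attributes `anchor`, `n_anchor_datasets`, `cutoff` and `config`.
#' @export
run_comodulation <- function(corpus, anchor,
                             thresholds = filter_thresholds(),
                             config = comod_config()) {
  stopifnot(inherits(corpus, "phospho_corpus"))
  dirs <- direction_matrix(corpus, thresholds)
  comod_from_directions(dirs, corpus$datasets, anchor, config)
}

#' Study/condition redundancy support for one partner
#'
#' Counts distinct study ids and unique normalized condition codes among
#' the differential datasets contributing to the partner's concordance
#' counts (datasets where both the anchor and the partner carry a direction
#' call).
#'
#' @param directions A [direction_matrix()].
#' @param datasets The corpus `datasets` metadata tibble.
#' @param anchor,partner Site keys (or strings).
#' @return One-row tibble with `n_studies`, `n_conditions`.
#' @export
redundancy_support <- function(directions, datasets, anchor, partner) {
  anchor <- as_site_key(anchor)
  partner <- as_site_key(partner)
  callable <- directions[directions$direction %in% c("increased", "decreased"), ]
  shared <- intersect(
    callable$dataset_id[callable$site == format(anchor)],
    callable$dataset_id[callable$site == format(partner)]
  )
  meta <- datasets[datasets$dataset_id %in% shared, ]
  tibble::tibble(
    n_studies = dplyr::n_distinct(meta$study_id),
    n_conditions = dplyr::n_distinct(meta$condition_code)
  )
}

#' Experimental-condition intersection counts
#'
#' For each requested subset of condition codes, counts the high-confidence
#' partners supported (co-callable with the anchor) under every code of the
#' subset. Pure set algebra over the per-partner supporting-condition sets
#' carried in the result table.
#'
#' @param results A `comod_result` from [run_comodulation()].
#' @param subsets A character vector (one subset) or a list of character
#'   vectors of condition codes; codes are normalized (trim + case-fold)
#'   before matching.
#' @param corpus Optional [phospho_corpus()] used to validate the requested
#'   codes; when omitted, codes are validated against the union of codes
#'   supporting any partner.
#' @return Tibble with `codes` (collapsed label), `n_codes`, `n_common`.
#' @export
condition_set_overlap <- function(results, subsets, corpus = NULL) {
  if (is.character(subsets)) subsets <- list(subsets)
  known <- if (!is.null(corpus)) {
    unique(corpus$datasets$condition_code)
  } else {
    unique(unlist(results$supporting_conditions))
  }
  hc <- results[results$high_confidence, ]
  out <- lapply(subsets, function(codes) {
    codes <- normalize_condition(codes)
    unknown <- setdiff(codes, known)
    if (length(unknown)) {
      stop("unknown condition code(s): ", paste(unknown, collapse = ", "),
           "; known codes: ", paste(sort(known), collapse = ", "),
           call. = FALSE)
    }
    n <- sum(vapply(hc$supporting_conditions,
                    function(s) all(codes %in% s), logical(1)))
    label <- paste(codes, collapse = " & ")
    k <- length(codes)
    tibble::tibble(codes = label, n_codes = k, n_common = n)
  })
  dplyr::bind_rows(out)
}

#' @export
print.comod_result <- function(x, ...) {
  anchor <- attr(x, "anchor")
  cat("<comod_result> anchor ", format(anchor),
      " callable in ", attr(x, "n_anchor_datasets"),
      " differential dataset(s); ratio cutoff ", attr(x, "cutoff"), "\n",
      sep = "")
  cat("  partners: ", nrow(x),
      " (high-confidence: ", sum(x$high_confidence & x$sign_class == "positive"),
      " positive, ", sum(x$high_confidence & x$sign_class == "negative"),
      " negative)\n", sep = "")
  NextMethod()
}
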
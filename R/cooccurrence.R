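#' Direction-concordance counts for a site pair
#'
#' Tallies, over the differential datasets in which BOTH sites carry a
#' direction call, the four direction combinations: `n_cc` (both
#' increased), `n_cd` (first increased, second decreased), `n_dc`, `n_dd`
#' (both decreased). For an anchor/partner pair these are the ItIo, ItDo,
#' DtIo, DtDo counts; for two sites of the same protein the II, ID, DI, DD
#' co-occurrence counts.
#'
#' @param directions A [direction_matrix()].
#' @param site_a,site_b Site keys (or `"ACC:Y426"` strings); must differ.
#' @return One-row tibble with `n_cc`, `n_cd`, `n_dc`, `n_dd`.
#' @export
pair_counts <- function(directions, site_a, site_b) {
  a <- as_site_key(site_a)
  b <- as_site_key(site_b)
  la <- format(a)
  lb <- format(b)
  if (identical(la, lb)) stop("site_a and site_b must differ", call. = FALSE)
  callable <- directions[directions$direction %in% c("increased", "decreased"), ]
  da <- callable[callable$site == la, c("dataset_id", "direction")]
  db <- callable[callable$site == lb, c("dataset_id", "direction")]
  m <- dplyr::inner_join(da, db, by = "dataset_id", suffix = c("_a", "_b"))
  tibble::tibble(
    n_cc = sum(m$direction_a == "increased" & m$direction_b == "increased"),
    n_cd = sum(m$direction_a == "increased" & m$direction_b == "decreased"),
    n_dc = sum(m$direction_a == "decreased" & m$direction_b == "increased"),
    n_dd = sum(m$direction_a == "decreased" & m$direction_b == "decreased")
  )
}

#' Co-modulation ratio
#'
#' Positive form: concordant over discordant counts,
#' `(n_cc + n_dd) / (n_cd + n_dc)`; negative form is the reciprocal. A zero
#' denominator with a positive numerator yields `Inf` (all evidence
#' concordant for the requested sign); all four counts zero yields `NA`
#' (no shared evidence). The two markers are distinct on purpose so that
#' downstream thresholding can treat "no data" and "fully concordant"
#' differently.
#'
#' @param n_cc,n_cd,n_dc,n_dd Non-negative integer vectors (recycled).
#' @param sign `"positive"` or `"negative"`.
#' @return Numeric vector (with `Inf`/`NA` markers).
#' @examples
#' comod_ratio(5, 1, 1, 3, "positive")  # 4
#' comod_ratio(5, 1, 1, 3, "negative")  # 0.25
#' comod_ratio(2, 0, 0, 0, "positive")  # Inf
#' @export
comod_ratio <- function(n_cc, n_cd, n_dc, n_dd,
                        sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  stopifnot(all(c(n_cc, n_cd, n_dc, n_dd) >= 0))
  conc <- n_cc + n_dd
  disc <- n_cd + n_dc
  num <- if (sign == "positive") conc else disc
  den <- if (sign == "positive") disc else conc
  out <- num / den                 # x/0 -> Inf, 0/0 -> NaN
  out[num == 0 & den == 0] <- NA_real_
  out
}

#' @rdname comod_ratio
#' @export
cooccur_ratio <- comod_ratio

#' Intra-protein co-occurrence matrix
#'
#' All ordered pairs of a protein's own callable phosphosites with their
#' concordance counts and both co-modulation ratios, in long format. Total
#' counts are symmetric under pair reversal and `n_cd`/`n_dc` transpose, so
#' the table supports the usual triangular heat-map layout (positive ratios
#' in one triangle, negative in the other).
#'
#' @param corpus A [phospho_corpus()].
#' @param protein Protein accession.
#' @param thresholds A [filter_thresholds()].
#' @return Tibble with `site_a`, `site_b` (residue-position labels, e.g.
#'   `"Y426"`), the four counts, `pos_ratio`, `neg_ratio`.
#' @export
cooccurrence_matrix <- function(corpus, protein,
                                thresholds = filter_thresholds()) {
  dirs <- direction_matrix(corpus, thresholds)
  own <- dirs[dirs$accession == protein &
                dirs$direction %in% c("increased", "decreased"), ]
  sites <- own |>
    dplyr::distinct(.data$residue, .data$position) |>
    dplyr::arrange(.data$position, .data$residue)
  labels <- paste0(sites$residue, sites$position)
  if (length(labels) < 2L) {
    return(tibble::tibble(site_a = character(), site_b = character(),
                          n_cc = integer(), n_cd = integer(),
                          n_dc = integer(), n_dd = integer(),
                          pos_ratio = double(), neg_ratio = double()))
  }
  own$label <- paste0(own$residue, own$position)
  m <- dplyr::inner_join(
    own[, c("dataset_id", "label", "direction")],
    own[, c("dataset_id", "label", "direction")],
    by = "dataset_id", suffix = c("_a", "_b"),
    relationship = "many-to-many"
  )
  m <- m[m$label_a != m$label_b, ]
  tallied <- m |>
    dplyr::count(.data$label_a, .data$label_b,
                 .data$direction_a, .data$direction_b)
  grid <- tidyr::expand_grid(site_a = labels, site_b = labels)
  grid <- grid[grid$site_a != grid$site_b, ]
  cell <- function(dir_a, dir_b) {
    x <- tallied[tallied$direction_a == dir_a & tallied$direction_b == dir_b,
                 c("label_a", "label_b", "n")]
    names(x) <- c("site_a", "site_b", "n")
    out <- dplyr::left_join(grid, x, by = c("site_a", "site_b"))
    tidyr::replace_na(out$n, 0L)
  }
  out <- grid
  out$n_cc <- cell("increased", "increased")
  out$n_cd <- cell("increased", "decreased")
  out$n_dc <- cell("decreased", "increased")
  out$n_dd <- cell("decreased", "decreased")
  out$pos_ratio <- comod_ratio(out$n_cc, out$n_cd, out$n_dc, out$n_dd, "positive")
  out$neg_ratio <- comod_ratio(out$n_cc, out$n_cd, out$n_dc, out$n_dd, "negative")
  out
}
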
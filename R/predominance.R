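#' Detection frequencies of a protein's phosphosites
#'
#' Counts, for every phosphosite of `protein`, the number of distinct
#' qualitative profiling datasets in which the site is reported as Class-1
#' (`profile_count`), the number of distinct quantitative differential
#' datasets reporting it as Class-1 regardless of direction
#' (`differential_count`), and the number of differential datasets in which
#' it actually carries a direction call (`callable_count`).
#'
#' @param corpus A [phospho_corpus()].
#' @param protein Protein accession.
#' @param thresholds A [filter_thresholds()].
#' @return Tibble with one row per site: `accession, gene, residue,
#'   position, site, profile_count, differential_count, callable_count`.
#'   Zero rows if the protein is absent from the corpus.
#' @export
site_frequencies <- function(corpus, protein,
                             thresholds = filter_thresholds()) {
  stopifnot(inherits(corpus, "phospho_corpus"))
  count_distinct <- function(obs) {
    obs <- obs[obs$accession == protein &
                 is_class1(obs$loc_prob, obs$a_score, thresholds), , drop = FALSE]
    obs |>
      dplyr::distinct(.data$dataset_id, .data$accession, .data$gene,
                      .data$residue, .data$position, .data$site) |>
      dplyr::count(.data$accession, .data$gene, .data$residue,
                   .data$position, .data$site)
  }
  prof <- count_distinct(corpus$profile_obs) |>
    dplyr::rename(profile_count = "n")
  diff <- count_distinct(corpus$differential_obs) |>
    dplyr::rename(differential_count = "n")
  dirs <- direction_matrix(corpus, thresholds)
  call <- dirs[dirs$accession == protein &
                 dirs$direction %in% c("increased", "decreased"), , drop = FALSE] |>
    dplyr::distinct(.data$dataset_id, .data$accession, .data$gene,
                    .data$residue, .data$position, .data$site) |>
    dplyr::count(.data$accession, .data$gene, .data$residue,
                 .data$position, .data$site) |>
    dplyr::rename(callable_count = "n")
  keys <- c("accession", "gene", "residue", "position", "site")
  out <- prof |>
    dplyr::full_join(diff, by = keys) |>
    dplyr::full_join(call, by = keys) |>
    dplyr::mutate(dplyr::across(dplyr::ends_with("_count"),
                                ~ tidyr::replace_na(.x, 0L)))
  dplyr::arrange(out, .data$position)
}

#' Rank sites by predominance
#'
#' A predominant site is one reported frequently in BOTH the profiling and
#' the differential corpora. Each frequency is normalized by the largest
#' frequency of its own corpus (making the score independent of the two
#' corpus sizes) and the two normalized frequencies are multiplied:
#' `predominance_score = (profile_count / max profile_count) *
#' (differential_count / max differential_count)`, in (0, 1], higher is
#' better; a lone site scores 1. The multiplicative combination means a
#' site must carry weight in both corpora — topping one list cannot
#' compensate for near-absence from the other, which is what distinguishes
#' an activation-loop site seen across differential experiments from a
#' merely well-profiled site. Dense 1-based per-corpus ranks are also
#' reported. Output is sorted by descending score; ties are broken by
#' larger `differential_count`, then by position. The top row is the
#' nominated predominant phosphosite.
#'
#' @param freqs Output of [site_frequencies()] (at least one row).
#' @return `freqs` with `profile_rank`, `differential_rank`,
#'   `predominance_score` added, sorted by predominance.
#' @examples
#' freqs <- tibble::tibble(
#'   accession = "P07947", gene = "YES1",
#'   residue = c("S", "Y", "Y"), position = c(40L, 194L, 426L),
#'   site = c("P07947:S40", "P07947:Y194", "P07947:Y426"),
#'   profile_count = c(210L, 159L, 142L),
#'   differential_count = c(10L, 8L, 72L),
#'   callable_count = c(9L, 6L, 72L)
#' )
#' rank_predominance(freqs)  # Y426 ranks first
#' @export
rank_predominance <- function(freqs) {
  if (nrow(freqs) == 0L) {
    stop("cannot rank predominance of zero sites", call. = FALSE)
  }
  norm <- function(x) x / max(x, 1L)
  out <- freqs |>
    dplyr::mutate(
      profile_rank = dplyr::dense_rank(dplyr::desc(.data$profile_count)),
      differential_rank = dplyr::dense_rank(dplyr::desc(.data$differential_count)),
      predominance_score = norm(.data$profile_count) *
        norm(.data$differential_count)
    ) |>
    dplyr::arrange(dplyr::desc(.data$predominance_score),
                   dplyr::desc(.data$differential_count), .data$position)
  out
}

#' Nominate the predominant phosphosite of a protein
#'
#' Convenience wrapper: [site_frequencies()] then [rank_predominance()],
#' returning the top-ranked site as a [site_key()].
#'
#' @inheritParams site_frequencies
#' @return A `site_key` for the predominant site.
#' @export
predominant_site <- function(corpus, protein,
                             thresholds = filter_thresholds()) {
  freqs <- site_frequencies(corpus, protein, thresholds)
  if (nrow(freqs) == 0L) {
    stop("protein '", protein, "' has no sites in the corpus", call. = FALSE)
  }
  top <- rank_predominance(freqs)[1L, ]
  site_key(top$accession, top$residue, top$position, gene = top$gene)
}
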
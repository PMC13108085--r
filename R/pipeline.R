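#' Run the full co-modulation pipeline
#'
#' One-command composition of the stages: read/validate the corpus,
#' rank the anchor protein's sites and select the anchor (explicit site or
#' auto-selected predominant site), build the intra-protein co-occurrence
#' matrix, run the anchor-versus-partners co-modulation analysis, apply the
#' annotation overlays when annotation tables are supplied, and write all
#' result TSVs, a SIF edge list and a machine-readable JSON manifest
#' (package version, configuration echo, input checksums, stage record
#' counts). The pipeline is deterministic for fixed inputs and
#' configuration; the manifest carries no timestamps so reruns are
#' byte-identical.
#'
#' Pipeline output equals composing the stage functions manually with the
#' same configuration; `run_pipeline()` adds only orchestration, logging
#' and serialization.
#'
#' @param profile_path,differential_path Corpus TSV paths (either may be
#'   `NULL`); ignored when `corpus` is given.
#' @param corpus Optionally, an already-assembled [phospho_corpus()].
#' @param anchor_protein Accession of the anchor protein.
#' @param anchor_site Optional explicit anchor site (`"ACC:Y426"` or
#'   [site_key()]); when `NULL` the top predominance-ranked site of
#'   `anchor_protein` is used. An explicit site must exist in the corpus.
#' @param thresholds A [filter_thresholds()].
#' @param config A [comod_config()].
#' @param annotations_dir Optional directory holding `interactions.tsv`,
#'   `kinase_substrate.tsv`, `enzymes.tsv`, `biomarkers.tsv` (see
#'   [write_annotation_fixtures()] for the schemas).
#' @param out_dir Output directory (created if needed).
#' @param verbose Emit stage logs via `message()`.
#' @return Invisibly, a list with the in-memory stage results
#'   (`predominance`, `anchor`, `cooccurrence`, `comodulation`, `overlays`,
#'   `manifest`).
#' @export
run_pipeline <- function(profile_path = NULL, differential_path = NULL,
                         corpus = NULL, anchor_protein,
                         anchor_site = NULL,
                         thresholds = filter_thresholds(),
                         config = comod_config(),
                         annotations_dir = NULL,
                         out_dir, verbose = TRUE) {
  say <- function(...) if (verbose) message("[phosphocomod] ", ...)
  input_paths <- c(profile = profile_path, differential = differential_path)
  if (is.null(corpus)) {
    corpus <- read_corpus(profile_path, differential_path,
                          thresholds = thresholds)
  }
  report <- validate_corpus(corpus)
  say("corpus: ", report$n_datasets, " datasets, ", report$n_sites,
      " sites, ", report$n_profile_obs + report$n_differential_obs,
      " observations",
      if (length(report$problems)) paste0(" (",
        paste(report$problems, collapse = "; "), ")") else "")

  freqs <- site_frequencies(corpus, anchor_protein, thresholds)
  if (nrow(freqs) == 0L) {
    rlang::abort(paste0("anchor protein '", anchor_protein,
                        "' absent from the corpus"),
                 class = "phosphocomod_missing_anchor")
  }
  ranked <- rank_predominance(freqs)
  if (is.null(anchor_site)) {
    anchor <- site_key(ranked$accession[1], ranked$residue[1],
                       ranked$position[1], gene = ranked$gene[1])
    say("auto-selected predominant anchor site: ", format(anchor))
  } else {
    anchor <- as_site_key(anchor_site)
    if (!format(anchor) %in% c(corpus$profile_obs$site,
                               corpus$differential_obs$site)) {
      rlang::abort(paste0("explicit anchor site ", format(anchor),
                          " not present in the corpus"),
                   class = "phosphocomod_missing_anchor")
    }
  }

  cooc <- cooccurrence_matrix(corpus, anchor_protein, thresholds)
  say("co-occurrence: ", nrow(cooc), " ordered intra-protein pairs")

  comod <- run_comodulation(corpus, anchor, thresholds, config)
  say("co-modulation: ", nrow(comod), " partner sites; cutoff ",
      attr(comod, "cutoff"), "; high-confidence ",
      sum(comod$high_confidence & comod$sign_class == "positive"),
      " positive / ",
      sum(comod$high_confidence & comod$sign_class == "negative"),
      " negative")

  overlays <- NULL
  if (!is.null(annotations_dir)) {
    ints <- read_interactions(file.path(annotations_dir, "interactions.tsv"))
    ks <- read_kinase_substrates(file.path(annotations_dir,
                                           "kinase_substrate.tsv"))
    enz <- read_enzyme_annotations(file.path(annotations_dir, "enzymes.tsv"))
    bm <- read_biomarkers(file.path(annotations_dir, "biomarkers.tsv"))
    overlays <- list(
      interactors = tag_binary_interactors(comod, ints, anchor$accession),
      upstream = identify_upstream_regulators(comod, ks, anchor),
      substrates = identify_downstream_substrates(comod, ks, anchor$accession),
      enzymes = classify_enzyme_partners(comod, enz),
      biomarker_positive = biomarker_overlap(comod, bm, "positive"),
      biomarker_negative = biomarker_overlap(comod, bm, "negative")
    )
    say("overlays: ", nrow(overlays$interactors), " interactor sites, ",
        nrow(overlays$upstream), " upstream, ",
        nrow(overlays$substrates), " substrates, ",
        sum(overlays$enzymes$enzyme_class == "kinase"), " kinase / ",
        sum(overlays$enzymes$enzyme_class == "phosphatase"),
        " phosphatase sites")
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(ranked, file.path(out_dir, "predominance.tsv"))
  write_results_table(cooc, file.path(out_dir, "cooccurrence.tsv"))
  write_results_table(comod, file.path(out_dir, "comodulation.tsv"))
  if (!is.null(overlays)) {
    write_results_table(overlays$interactors,
                        file.path(out_dir, "interactors.tsv"))
    write_results_table(overlays$upstream, file.path(out_dir, "upstream.tsv"))
    write_results_table(overlays$substrates,
                        file.path(out_dir, "substrates.tsv"))
    write_results_table(overlays$enzymes, file.path(out_dir, "enzymes.tsv"))
    write_results_table(overlays$biomarker_positive,
                        file.path(out_dir, "biomarker_overlap_positive.tsv"))
    write_results_table(overlays$biomarker_negative,
                        file.path(out_dir, "biomarker_overlap_negative.tsv"))
  }

  hc <- comod[comod$high_confidence, ]
  edges <- tibble::tibble(source = rep(format(anchor), nrow(hc)),
                          relation = hc$sign_class, target = hc$site)
  if (!is.null(overlays)) {
    if (nrow(overlays$upstream)) {
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        source = overlays$upstream$site, relation = "upstream_of",
        target = format(anchor)))
    }
    if (nrow(overlays$substrates)) {
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        source = format(anchor), relation = "phosphorylates",
        target = overlays$substrates$site))
    }
    if (nrow(overlays$interactors)) {
      edges <- dplyr::bind_rows(edges, dplyr::distinct(tibble::tibble(
        source = anchor$accession, relation = "interacts_with",
        target = overlays$interactors$accession)))
    }
  }
  write_sif(edges, file.path(out_dir, "network.sif"))

  checksums <- if (length(input_paths)) {
    as.list(tools::md5sum(unlist(input_paths)))
  } else NULL
  manifest <- list(
    package = "phosphocomod",
    version = as.character(utils::packageVersion("phosphocomod")),
    anchor = format(anchor),
    anchor_protein = anchor_protein,
    n_anchor_datasets = attr(comod, "n_anchor_datasets"),
    cutoff = attr(comod, "cutoff"),
    thresholds = unclass(thresholds),
    config = unclass(config),
    input_checksums = checksums,
    counts = list(
      datasets = report$n_datasets,
      sites = report$n_sites,
      partners = nrow(comod),
      high_confidence_positive = sum(hc$sign_class == "positive"),
      high_confidence_negative = sum(hc$sign_class == "negative")
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote results to ", out_dir)
  invisible(list(predominance = ranked, anchor = anchor, cooccurrence = cooc,
                 comodulation = comod, overlays = overlays,
                 manifest = manifest))
}
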
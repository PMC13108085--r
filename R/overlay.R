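#' Read annotation tables
#'
#' Curated annotation fixtures are plain TSVs (UTF-8, header, `"."` =
#' missing). Four schemas are supported:
#' \describe{
#'   \item{interactions}{`anchor_accession, partner_accession, partner_gene,
#'     source, evidence` — binary protein-protein interaction records with
#'     unordered-pair semantics.}
#'   \item{kinase-substrate}{`kinase_accession, kinase_gene,
#'     substrate_accession, substrate_gene, substrate_residue,
#'     substrate_position, evidence_class, source` — site-resolved
#'     kinase-substrate relations; `evidence_class` is one of
#'     `experimental`, `predicted`, `screen`.}
#'   \item{enzymes}{`accession, gene, enzyme_class, residue, position,
#'     site_effect` — protein-level rows (`residue = "."`) assign the class
#'     (`kinase` / `phosphatase`); site-level rows add the functional effect
#'     of phosphorylation at that site (`induces`, `inhibits`, `both`,
#'     `unknown`).}
#'   \item{biomarkers}{`disease, gene, source` — disease biomarker gene
#'     lists.}
#' }
#'
#' @param path Path to the TSV.
#' @return A tibble with the validated schema.
#' @name read_annotations
NULL

read_annotation_table <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "."), progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(tbl[, required])
}

#' @rdname read_annotations
#' @export
read_interactions <- function(path) {
  read_annotation_table(path, c("anchor_accession", "partner_accession",
                                "partner_gene", "source", "evidence"))
}

#' @rdname read_annotations
#' @export
read_kinase_substrates <- function(path) {
  tbl <- read_annotation_table(path, c("kinase_accession", "kinase_gene",
                                       "substrate_accession", "substrate_gene",
                                       "substrate_residue", "substrate_position",
                                       "evidence_class", "source"))
  tbl$substrate_position <- as.integer(tbl$substrate_position)
  stopifnot(all(tbl$substrate_residue %in% c("S", "T", "Y")),
            all(tbl$substrate_position >= 1L),
            all(tbl$evidence_class %in% c("experimental", "predicted", "screen")))
  tbl
}

#' @rdname read_annotations
#' @export
read_enzyme_annotations <- function(path) {
  tbl <- read_annotation_table(path, c("accession", "gene", "enzyme_class",
                                       "residue", "position", "site_effect"))
  tbl$position <- as.integer(tbl$position)
  stopifnot(all(tbl$enzyme_class %in% c("kinase", "phosphatase")),
            all(is.na(tbl$residue) | tbl$residue %in% c("S", "T", "Y")),
            all(is.na(tbl$site_effect) |
                  tbl$site_effect %in% c("induces", "inhibits", "both", "unknown")))
  tbl
}

#' @rdname read_annotations
#' @export
read_biomarkers <- function(path) {
  read_annotation_table(path, c("disease", "gene", "source"))
}

hc_subset <- function(results) {
  results[results$high_confidence, , drop = FALSE]
}

#' Tag high-confidence partners that are binary interactors of the anchor
#'
#' A partner site is tagged when its protein appears in an interaction
#' record together with the anchor protein (either orientation). All
#' high-confidence sites of an interactor are tagged, so coordinated
#' modulation of several sites on one interactor is visible by grouping on
#' accession. A pure filter/join: counts, p-values and ratios are passed
#' through unchanged.
#'
#' @param results A `comod_result` from [run_comodulation()].
#' @param interactions Interaction records, see [read_interactions()].
#' @param anchor_accession Anchor protein accession.
#' @return The tagged subset with `interaction_source` added.
#' @export
tag_binary_interactors <- function(results, interactions, anchor_accession) {
  with_anchor <- interactions[
    interactions$anchor_accession == anchor_accession |
      interactions$partner_accession == anchor_accession, , drop = FALSE]
  other <- ifelse(with_anchor$anchor_accession == anchor_accession,
                  with_anchor$partner_accession, with_anchor$anchor_accession)
  src <- vapply(split(with_anchor$source, other),
                function(s) paste(sort(unique(s)), collapse = ";"), character(1))
  hc <- hc_subset(results)
  out <- hc[hc$accession %in% other, , drop = FALSE]
  out$interaction_source <- unname(src[out$accession])
  out
}

#' Identify upstream regulators among high-confidence partners
#'
#' An upstream regulator is a high-confidence partner whose protein is
#' annotated as a kinase of the anchor's specific residue/position (not
#' merely a kinase of the anchor protein).
#'
#' @param results A `comod_result`.
#' @param ks_records Kinase-substrate records, see [read_kinase_substrates()].
#' @param anchor Anchor site key (or `"ACC:Y426"` string).
#' @return The matching subset with `evidence_class` and `ks_source` added.
#' @export
identify_upstream_regulators <- function(results, ks_records, anchor) {
  anchor <- as_site_key(anchor)
  recs <- ks_records[
    ks_records$substrate_accession == anchor$accession &
      ks_records$substrate_residue == anchor$residue &
      ks_records$substrate_position == anchor$position, , drop = FALSE]
  ev <- vapply(split(recs$evidence_class, recs$kinase_accession),
               function(s) paste(sort(unique(s)), collapse = ";"), character(1))
  src <- vapply(split(recs$source, recs$kinase_accession),
                function(s) paste(sort(unique(s)), collapse = ";"), character(1))
  hc <- hc_subset(results)
  out <- hc[hc$accession %in% recs$kinase_accession, , drop = FALSE]
  out$evidence_class <- unname(ev[out$accession])
  out$ks_source <- unname(src[out$accession])
  out
}

#' Identify candidate downstream substrates among high-confidence partners
#'
#' A candidate downstream substrate is a high-confidence partner whose own
#' site (accession, residue, position) is annotated as a substrate site of
#' the anchor protein's kinase activity.
#'
#' @inheritParams identify_upstream_regulators
#' @param anchor_accession Anchor protein accession.
#' @return The matching subset with `evidence_class` and `ks_source` added.
#' @export
identify_downstream_substrates <- function(results, ks_records,
                                           anchor_accession) {
  recs <- ks_records[ks_records$kinase_accession == anchor_accession, ,
                     drop = FALSE]
  recs$target <- site_label(recs$substrate_accession, recs$substrate_residue,
                            recs$substrate_position)
  ev <- vapply(split(recs$evidence_class, recs$target),
               function(s) paste(sort(unique(s)), collapse = ";"), character(1))
  src <- vapply(split(recs$source, recs$target),
                function(s) paste(sort(unique(s)), collapse = ";"), character(1))
  hc <- hc_subset(results)
  out <- hc[hc$site %in% recs$target, , drop = FALSE]
  out$evidence_class <- unname(ev[out$site])
  out$ks_source <- unname(src[out$site])
  out
}

#' Partition high-confidence partners by enzyme class
#'
#' Joins the enzyme annotation table: every high-confidence partner gets an
#' `enzyme_class` (`kinase`, `phosphatase`, or `none` when its protein is
#' not annotated) and, for annotated enzymes, the functional effect of
#' phosphorylation at its specific site (`induces` / `inhibits` / `both`,
#' or `unknown` when the site itself is unannotated).
#'
#' @param results A `comod_result`.
#' @param enzymes Enzyme annotations, see [read_enzyme_annotations()].
#' @return All high-confidence partners with `enzyme_class` and
#'   `site_effect` added.
#' @export
classify_enzyme_partners <- function(results, enzymes) {
  protein_class <- dplyr::distinct(enzymes[, c("accession", "enzyme_class")])
  if (anyDuplicated(protein_class$accession)) {
    stop("conflicting enzyme_class annotations for: ",
         paste(unique(protein_class$accession[
           duplicated(protein_class$accession)]), collapse = ", "),
         call. = FALSE)
  }
  site_rows <- enzymes[!is.na(enzymes$residue) & !is.na(enzymes$position), ,
                       drop = FALSE]
  site_rows$site <- site_label(site_rows$accession, site_rows$residue,
                               site_rows$position)
  out <- hc_subset(results)
  out <- dplyr::left_join(out, protein_class, by = "accession")
  out$enzyme_class[is.na(out$enzyme_class)] <- "none"
  out <- dplyr::left_join(
    out, site_rows[, c("site", "site_effect")], by = "site")
  unannotated <- out$enzyme_class != "none" & is.na(out$site_effect)
  out$site_effect[unannotated] <- "unknown"
  out
}

#' Overlap high-confidence partners with disease biomarker genes
#'
#' For each disease, reports the genes shared between the biomarker table
#' and the high-confidence partners of the chosen sign, retaining the
#' specific phosphosites. Gene symbols are matched case-insensitively.
#'
#' @param results A `comod_result`.
#' @param biomarkers Biomarker records, see [read_biomarkers()].
#' @param sign `"positive"` or `"negative"`: which co-modulation sign to
#'   intersect.
#' @return Tibble with `disease`, `gene`, `accession`, `residue`,
#'   `position`, `site`, `biomarker_source`.
#' @export
biomarker_overlap <- function(results, biomarkers,
                              sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  hc <- hc_subset(results)
  hc <- hc[hc$sign_class == sign, , drop = FALSE]
  hc$gene_fold <- tolower(hc$gene)
  bm <- biomarkers
  bm$gene_fold <- tolower(bm$gene)
  joined <- dplyr::inner_join(
    bm[, c("disease", "gene", "source", "gene_fold")],
    hc[, c("gene_fold", "accession", "residue", "position", "site")],
    by = "gene_fold", relationship = "many-to-many"
  )
  joined$gene_fold <- NULL
  names(joined)[names(joined) == "source"] <- "biomarker_source"
  dplyr::arrange(joined, .data$disease, .data$gene, .data$position)
}
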
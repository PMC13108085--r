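#' Curated annotation fixture tables
#'
#' Synthetic curated annotation tables shipped with the package (also
#' written to `inst/extdata/annotations` and by
#' [write_annotation_fixtures()]). They are not database exports: content
#' is a compact stand-in mirroring well-known site-resolved annotations of
#' the Src-family anchor used by the default fixture — 24 binary
#' interactors, kinase-substrate records for the anchor's activation-loop
#' site and its candidate substrates, kinase/phosphatase class and
#' site-effect labels, and disease biomarker gene lists.
#'
#' @return Named list of tibbles: `interactions`, `kinase_substrates`,
#'   `enzymes`, `biomarkers`.
#' @export
annotation_fixtures <- function() {
  interactions <- tibble::tribble(
    ~partner_accession, ~partner_gene,
    "P07948", "LYN",
    "P06239", "LCK",
    "P04626", "ERBB2",
    "P22681", "CBL",
    "Q13263", "TRIM28",
    "Q13435", "SF3B2",
    "P15311", "EZR",
    "P04792", "HSPB1",
    "Q9UHB6", "LIMA1",
    "P17987", "TCP1",
    "P55196", "AFDN",
    "O15042", "U2SURP",
    "Q4G0J3", "LARP7",
    "P40227", "CCT6A",
    "Q96I25", "RBM17",
    "P02794", "FTH1",
    "P17302", "GJA1",
    "Q13480", "GAB1",
    "Q13177", "PAK2",
    "Q9UPQ0", "LIMCH1",
    "P46937", "YAP1",
    "P35222", "CTNNB1",
    "P00533", "EGFR",
    "P12931", "SRC"
  )
  interactions$anchor_accession <- "P07947"
  interactions$source <- "synthetic-curated"
  interactions$evidence <- "binary"
  interactions <- interactions[, c("anchor_accession", "partner_accession",
                                   "partner_gene", "source", "evidence")]

  ks <- tibble::tribble(
    ~kinase_accession, ~kinase_gene, ~substrate_accession, ~substrate_gene,
    ~substrate_residue, ~substrate_position, ~evidence_class, ~source,
    # upstream of the anchor site P07947:Y426
    "P06239", "LCK", "P07947", "YES1", "Y", 426L, "screen", "synthetic-htp-screen",
    "P06239", "LCK", "P07947", "YES1", "Y", 426L, "predicted", "synthetic-motif-pred",
    "P07948", "LYN", "P07947", "YES1", "Y", 426L, "predicted", "synthetic-motif-pred",
    "P04626", "ERBB2", "P07947", "YES1", "Y", 426L, "predicted", "synthetic-motif-pred",
    # decoy targeting a different anchor-protein site: must never match
    "P12931", "SRC", "P07947", "YES1", "Y", 32L, "experimental", "synthetic-curated",
    # downstream substrates of the anchor kinase
    "P07947", "YES1", "P06239", "LCK", "Y", 394L, "predicted", "synthetic-motif-pred",
    "P07947", "YES1", "P07948", "LYN", "Y", 397L, "experimental", "synthetic-curated",
    "P07947", "YES1", "Q13443", "ADAM9", "Y", 769L, "predicted", "synthetic-motif-pred",
    "P07947", "YES1", "Q9NWQ8", "PAG1", "Y", 227L, "predicted", "synthetic-motif-pred",
    "P07947", "YES1", "P68104", "EEF1A1", "Y", 141L, "screen", "synthetic-htp-screen",
    "P07947", "YES1", "P10398", "ARAF", "Y", 155L, "predicted", "synthetic-motif-pred",
    "P07947", "YES1", "P52799", "EFNB2", "Y", 304L, "predicted", "synthetic-motif-pred",
    "P07947", "YES1", "Q6NZI2", "CAVIN1", "Y", 308L, "screen", "synthetic-htp-screen",
    # decoy substrate site at another position
    "P07947", "YES1", "P07948", "LYN", "Y", 306L, "predicted", "synthetic-motif-pred"
  )

  enzymes <- tibble::tribble(
    ~accession, ~gene, ~enzyme_class, ~residue, ~position, ~site_effect,
    "P07948", "LYN", "kinase", NA, NA, NA,
    "P07948", "LYN", "kinase", "Y", 397L, "induces",
    "P06239", "LCK", "kinase", NA, NA, NA,
    "P06239", "LCK", "kinase", "Y", 394L, "induces",
    "P15056", "BRAF", "kinase", NA, NA, NA,
    "P15056", "BRAF", "kinase", "S", 729L, "induces",
    "P27361", "MAPK3", "kinase", NA, NA, NA,
    "P27361", "MAPK3", "kinase", "T", 207L, "inhibits",
    "Q13131", "PRKAA1", "kinase", NA, NA, NA,
    "Q13131", "PRKAA1", "kinase", "S", 496L, "inhibits",
    "P35269", "GTF2F1", "kinase", NA, NA, NA,
    "P35269", "GTF2F1", "kinase", "S", 385L, "inhibits",
    "Q05655", "PRKCD", "kinase", NA, NA, NA,
    "Q13177", "PAK2", "kinase", NA, NA, NA,
    "P10398", "ARAF", "kinase", NA, NA, NA,
    "Q13233", "MAP3K1", "kinase", NA, NA, NA,
    "Q9H792", "PEAK1", "kinase", NA, NA, NA,
    "Q96GX5", "MASTL", "kinase", NA, NA, NA,
    "O00750", "PIK3C2B", "kinase", NA, NA, NA,
    "P04626", "ERBB2", "kinase", NA, NA, NA,
    "P18669", "PGAM1", "phosphatase", NA, NA, NA,
    "Q9C0I1", "MTMR12", "phosphatase", NA, NA, NA,
    "O15355", "PPM1G", "phosphatase", NA, NA, NA,
    "Q05209", "PTPN12", "phosphatase", NA, NA, NA,
    "Q96T60", "PNKP", "phosphatase", NA, NA, NA,
    "Q96T60", "PNKP", "phosphatase", "S", 114L, "both",
    "Q92539", "LPIN2", "phosphatase", NA, NA, NA
  )
  enzymes$position <- as.integer(enzymes$position)

  biomarkers <- tibble::tribble(
    ~disease, ~gene,
    "breast cancer", "YBX1",
    "breast cancer", "CRK",
    "breast cancer", "ERBB2",
    "leukemia", "LYN",
    "leukemia", "PRKCD",
    "leukemia", "ZFP36",
    "colorectal cancer", "BRAF",
    "colorectal cancer", "EXO1",
    "lung adenocarcinoma", "VDAC1",
    "lung adenocarcinoma", "MAPK3"
  )
  biomarkers$source <- "synthetic-curated"

  list(interactions = interactions, kinase_substrates = ks,
       enzymes = enzymes, biomarkers = biomarkers)
}

#' Write the annotation fixture TSVs
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of paths.
#' @export
write_annotation_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- annotation_fixtures()
  paths <- c(interactions = file.path(dir, "interactions.tsv"),
             kinase_substrates = file.path(dir, "kinase_substrate.tsv"),
             enzymes = file.path(dir, "enzymes.tsv"),
             biomarkers = file.path(dir, "biomarkers.tsv"))
  write_results_table(fx$interactions, paths[["interactions"]])
  write_results_table(fx$kinase_substrates, paths[["kinase_substrates"]])
  write_results_table(fx$enzymes, paths[["enzymes"]])
  write_results_table(fx$biomarkers, paths[["biomarkers"]])
  invisible(paths)
}
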
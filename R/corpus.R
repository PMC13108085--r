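#' Construct a phosphosite key
#'
#' A phosphosite is identified by a protein accession, the phosphoacceptor
#' residue (S, T or Y) and its 1-based position on the canonical sequence.
#' The gene symbol is carried for display and annotation joins but does not
#' enter site identity.
#'
#' @param accession Protein accession (e.g. a UniProt accession).
#' @param residue One of `"S"`, `"T"`, `"Y"`.
#' @param position Positive integer, 1-based residue index.
#' @param gene Optional HGNC-style gene symbol.
#' @return An object of class `site_key`: a named list with fields
#'   `accession`, `gene`, `residue`, `position`.
#' @examples
#' site_key("P07947", "Y", 426, gene = "YES1")
#' @export
site_key <- function(accession, residue, position, gene = NA_character_) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession))
  residue <- as.character(residue)
  if (!residue %in% c("S", "T", "Y")) {
    stop("residue must be one of 'S', 'T', 'Y', got '", residue, "'", call. = FALSE)
  }
  position <- as.integer(position)
  if (is.na(position) || position < 1L) {
    stop("position must be a positive integer", call. = FALSE)
  }
  structure(
    list(accession = accession, gene = as.character(gene),
         residue = residue, position = position),
    class = "site_key"
  )
}

#' Coerce to a site key
#'
#' Accepts a `site_key`, or a string of the form `"ACCESSION:Y426"`.
#'
#' @param x Object to coerce.
#' @return A `site_key`.
#' @export
as_site_key <- function(x) {
  if (inherits(x, "site_key")) return(x)
  if (is.character(x) && length(x) == 1L) {
    m <- regmatches(x, regexec("^([^:]+):([STY])([0-9]+)$", x))[[1]]
    if (length(m) == 4L) {
      return(site_key(m[2], m[3], as.integer(m[4])))
    }
  }
  stop("cannot interpret '", deparse(substitute(x)),
       "' as a site key; use site_key() or 'ACC:Y426' notation", call. = FALSE)
}

#' @export
format.site_key <- function(x, ...) {
  paste0(x$accession, ":", x$residue, x$position)
}

#' @export
print.site_key <- function(x, ...) {
  lab <- if (!is.na(x$gene)) paste0(" (", x$gene, "-", x$residue, x$position, ")") else ""
  cat("<site> ", format(x), lab, "\n", sep = "")
  invisible(x)
}

# canonical site label used as the grouping key throughout the package
site_label <- function(accession, residue, position) {
  paste0(accession, ":", residue, position)
}

# condition codes are compared after trimming and case-folding
normalize_condition <- function(x) {
  tolower(trimws(as.character(x)))
}

meta_cols <- c("dataset_id", "study_id", "condition_code", "enrichment")
site_cols <- c("accession", "gene", "residue", "position")

#' Assemble a phosphoproteomic corpus
#'
#' A corpus bundles dataset-level metadata with qualitative profiling
#' observations and quantitative differential observations. Observation
#' tables may carry the metadata columns inline (as read by
#' [read_profile_table()] / [read_differential_table()]); metadata is split
#' out and deduplicated by `dataset_id`.
#'
#' @param profile_obs Tibble of profiling observations with columns
#'   `dataset_id, study_id, condition_code, enrichment, accession, gene,
#'   residue, position, loc_prob, a_score`. May be `NULL`.
#' @param differential_obs Tibble of differential observations with the same
#'   columns plus `fold_change, p_value`. May be `NULL`.
#' @return An object of class `phospho_corpus`: a list with tibbles
#'   `datasets` (dataset_id, study_id, condition_code, enrichment, kind),
#'   `profile_obs` and `differential_obs` (metadata columns removed, a
#'   `site` label column added).
#' @export
phospho_corpus <- function(profile_obs = NULL, differential_obs = NULL) {
  empty_obs <- tibble::tibble(
    dataset_id = character(), accession = character(), gene = character(),
    residue = character(), position = integer(),
    loc_prob = double(), a_score = double()
  )
  split_one <- function(tbl, kind) {
    if (is.null(tbl) || nrow(tbl) == 0L) {
      meta <- tibble::tibble(
        dataset_id = character(), study_id = character(),
        condition_code = character(), enrichment = character(),
        kind = character()
      )
      obs <- empty_obs
      if (kind == "differential") {
        obs$fold_change <- double()
        obs$p_value <- double()
      }
      obs$site <- character()
      return(list(meta = meta, obs = obs))
    }
    tbl <- tibble::as_tibble(tbl)
    missing <- setdiff(c(meta_cols, site_cols), names(tbl))
    if (length(missing)) {
      stop("corpus ", kind, " table lacks column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    tbl$condition_code <- normalize_condition(tbl$condition_code)
    if (any(!nzchar(tbl$condition_code))) {
      stop("empty condition_code after normalization in ", kind, " table",
           call. = FALSE)
    }
    meta <- dplyr::distinct(tbl[, meta_cols])
    if (anyDuplicated(meta$dataset_id)) {
      dup <- unique(meta$dataset_id[duplicated(meta$dataset_id)])
      stop("conflicting metadata for dataset_id(s): ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
    meta$kind <- kind
    keep <- setdiff(names(tbl), setdiff(meta_cols, "dataset_id"))
    obs <- tbl[, keep]
    obs$site <- site_label(obs$accession, obs$residue, obs$position)
    list(meta = meta, obs = obs)
  }
  p <- split_one(profile_obs, "profile")
  d <- split_one(differential_obs, "differential")
  datasets <- dplyr::bind_rows(p$meta, d$meta)
  if (anyDuplicated(datasets$dataset_id)) {
    dup <- unique(datasets$dataset_id[duplicated(datasets$dataset_id)])
    stop("dataset_id(s) appear in both profile and differential tables: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(
    list(datasets = datasets, profile_obs = p$obs, differential_obs = d$obs),
    class = "phospho_corpus"
  )
}

#' @export
print.phospho_corpus <- function(x, ...) {
  nk <- table(factor(x$datasets$kind, levels = c("profile", "differential")))
  cat("<phospho_corpus>\n")
  cat("  datasets:     ", nk[["profile"]], " profile, ",
      nk[["differential"]], " differential\n", sep = "")
  cat("  observations: ", nrow(x$profile_obs), " profile, ",
      nrow(x$differential_obs), " differential\n", sep = "")
  nsites <- length(unique(c(x$profile_obs$site, x$differential_obs$site)))
  cat("  distinct sites:", nsites, "\n")
  invisible(x)
}

#' Validate a corpus
#'
#' Side-effect-free structural report: dataset/site/observation counts,
#' orphan observations (dataset_id absent from the metadata table) and
#' residual duplicate (dataset, site) observations. The corpus is not
#' modified; problems are listed, not raised.
#'
#' @param corpus A [phospho_corpus()].
#' @return A list of class `corpus_validation` with counts and a character
#'   vector `problems`.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "phospho_corpus"))
  known <- corpus$datasets$dataset_id
  orphan_p <- setdiff(unique(corpus$profile_obs$dataset_id), known)
  orphan_d <- setdiff(unique(corpus$differential_obs$dataset_id), known)
  n_orphans <- sum(corpus$profile_obs$dataset_id %in% orphan_p) +
    sum(corpus$differential_obs$dataset_id %in% orphan_d)
  dup_count <- function(obs) {
    if (nrow(obs) == 0L) return(0L)
    sum(duplicated(obs[, c("dataset_id", "site")]))
  }
  n_dup <- dup_count(corpus$profile_obs) + dup_count(corpus$differential_obs)
  problems <- character()
  if (n_orphans > 0) {
    problems <- c(problems, paste0(n_orphans, " orphan observation(s) in ",
                                   length(c(orphan_p, orphan_d)), " unknown dataset(s)"))
  }
  if (n_dup > 0) {
    problems <- c(problems, paste0(n_dup, " duplicate (dataset, site) observation(s)"))
  }
  structure(
    list(
      n_datasets = nrow(corpus$datasets),
      n_profile_datasets = sum(corpus$datasets$kind == "profile"),
      n_differential_datasets = sum(corpus$datasets$kind == "differential"),
      n_sites = length(unique(c(corpus$profile_obs$site,
                                corpus$differential_obs$site))),
      n_profile_obs = nrow(corpus$profile_obs),
      n_differential_obs = nrow(corpus$differential_obs),
      n_orphans = n_orphans,
      n_duplicates = n_dup,
      problems = problems
    ),
    class = "corpus_validation"
  )
}

#' @export
print.corpus_validation <- function(x, ...) {
  cat("<corpus validation>\n")
  for (f in setdiff(names(x), "problems")) cat("  ", f, ": ", x[[f]], "\n", sep = "")
  if (length(x$problems)) {
    cat("  problems:\n")
    for (p in x$problems) cat("    - ", p, "\n", sep = "")
  } else {
    cat("  problems: none\n")
  }
  invisible(x)
}
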
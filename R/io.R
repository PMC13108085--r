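#' Default column-name dialect
#'
#' Maps the canonical field names used by the package to the column names of
#' a TSV on disk. Supplying a modified copy of this vector lets tables from
#' other exports be read without renaming files.
#'
#' @param differential If `TRUE`, include the `fold_change`/`p_value` fields.
#' @return Named character vector: names are canonical fields, values are
#'   file column names.
#' @export
default_dialect <- function(differential = FALSE) {
  fields <- c(meta_cols, site_cols, "loc_prob", "a_score")
  if (differential) fields <- c(fields, "fold_change", "p_value")
  stats::setNames(fields, fields)
}

# shared reader for the two corpus table dialects; returns a tibble with
# canonical column names, validated and typed. Missing values: "." or empty.
read_corpus_table <- function(path, dialect, differential) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "."), progress = FALSE,
                         show_col_types = FALSE)
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl <- raw[, unname(dialect)]
  names(tbl) <- names(dialect)
  if (nrow(tbl) == 0L) return(tibble::as_tibble(tbl))
  tbl$.row <- seq_len(nrow(tbl)) + 1L  # file line numbers (header = line 1)

  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      rows <- tbl$.row[which(cond)]
      stop(what, " at row(s) ", paste(utils::head(rows, 10L), collapse = ", "),
           if (length(rows) > 10L) " ..." else "", " of ", basename(path),
           call. = FALSE)
    }
  }
  num <- function(col, required = FALSE) {
    x <- suppressWarnings(as.numeric(tbl[[col]]))
    bad(!is.na(tbl[[col]]) & is.na(x), paste0("non-numeric ", col))
    if (required) bad(is.na(tbl[[col]]), paste0("missing ", col))
    x
  }
  for (col in c("dataset_id", "study_id", "condition_code", "accession")) {
    bad(is.na(tbl[[col]]), paste0("missing ", col))
  }
  bad(!tbl$residue %in% c("S", "T", "Y"), "invalid residue (must be S, T or Y)")
  pos <- suppressWarnings(as.integer(tbl$position))
  bad(is.na(pos) | pos < 1L, "invalid position (positive integer required)")
  tbl$position <- pos
  tbl$loc_prob <- num("loc_prob")
  bad(!is.na(tbl$loc_prob) & (tbl$loc_prob < 0 | tbl$loc_prob > 1),
      "loc_prob outside [0, 1]")
  tbl$a_score <- num("a_score")
  bad(!is.na(tbl$a_score) & tbl$a_score < 0, "negative a_score")
  if (differential) {
    tbl$fold_change <- num("fold_change", required = TRUE)
    bad(tbl$fold_change <= 0, "non-positive fold_change")
    tbl$p_value <- num("p_value", required = TRUE)
    bad(tbl$p_value < 0 | tbl$p_value > 1, "p_value outside [0, 1]")
  }
  tbl$condition_code <- normalize_condition(tbl$condition_code)
  bad(!nzchar(tbl$condition_code), "empty condition_code")
  tbl$.row <- NULL
  tibble::as_tibble(tbl)
}

#' Read a qualitative profiling table
#'
#' Tab-separated, UTF-8, mandatory header; `"."` or an empty cell denotes a
#' missing value. Duplicate (dataset, site) rows are collapsed to the row
#' with the highest localization probability (then highest A-score), with a
#' warning.
#'
#' @param path Path to the TSV file.
#' @param dialect Column-name mapping, see [default_dialect()].
#' @return Tibble of profiling observations with metadata columns inline.
#' @export
read_profile_table <- function(path, dialect = default_dialect()) {
  tbl <- read_corpus_table(path, dialect, differential = FALSE)
  if (nrow(tbl) == 0L) return(tbl)
  key <- paste(tbl$dataset_id, site_label(tbl$accession, tbl$residue, tbl$position))
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    warning(n_dup, " duplicate (dataset, site) profiling row(s) collapsed ",
            "(keeping best-localized)", call. = FALSE)
    ord <- order(-ifelse(is.na(tbl$loc_prob), -Inf, tbl$loc_prob),
                 -ifelse(is.na(tbl$a_score), -Inf, tbl$a_score))
    tbl <- tbl[ord, ][!duplicated(key[ord]), ]
  }
  tbl
}

#' Read a quantitative differential table
#'
#' As [read_profile_table()], with `fold_change` (linear test/control ratio,
#' strictly positive) and `p_value` required. Duplicate (dataset, site) rows
#' are resolved by keeping the smallest p-value; if duplicates carry
#' conflicting direction calls (one increased, one decreased under
#' `thresholds`), the site is dropped from that dataset, with a warning.
#'
#' @param path Path to the TSV file.
#' @param dialect Column-name mapping, see [default_dialect()].
#' @param thresholds [filter_thresholds()] used only to detect conflicting
#'   duplicate directions.
#' @return Tibble of differential observations with metadata columns inline.
#' @export
read_differential_table <- function(path,
                                    dialect = default_dialect(differential = TRUE),
                                    thresholds = filter_thresholds()) {
  tbl <- read_corpus_table(path, dialect, differential = TRUE)
  dedup_differential(tbl, thresholds)
}

# duplicate policy for differential observations (see read_differential_table)
dedup_differential <- function(tbl, thresholds = filter_thresholds()) {
  if (nrow(tbl) == 0L) return(tbl)
  key <- paste(tbl$dataset_id, site_label(tbl$accession, tbl$residue, tbl$position))
  if (!anyDuplicated(key)) return(tbl)
  dir <- classify_abundance(tbl$fold_change, tbl$p_value,
                            tbl$loc_prob, tbl$a_score, thresholds)
  keep <- rep(TRUE, nrow(tbl))
  dropped_conflicts <- 0L
  collapsed <- 0L
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    calls <- dir[idx]
    if (all(c("increased", "decreased") %in% calls)) {
      keep[idx] <- FALSE
      dropped_conflicts <- dropped_conflicts + 1L
    } else {
      best <- idx[which.min(tbl$p_value[idx])]
      keep[setdiff(idx, best)] <- FALSE
      collapsed <- collapsed + 1L
    }
  }
  msg <- character()
  if (collapsed > 0L) {
    msg <- c(msg, paste0(collapsed, " duplicated (dataset, site) pair(s) collapsed to the smallest p-value"))
  }
  if (dropped_conflicts > 0L) {
    msg <- c(msg, paste0(dropped_conflicts, " pair(s) dropped for conflicting duplicate directions"))
  }
  warning(paste(msg, collapse = "; "), call. = FALSE)
  tbl[keep, ]
}

#' Read profiling and differential tables into a corpus
#'
#' @param profile_path,differential_path Paths to the two TSVs; either may
#'   be `NULL`.
#' @param thresholds Passed to [read_differential_table()] for the duplicate
#'   policy.
#' @return A [phospho_corpus()].
#' @export
read_corpus <- function(profile_path = NULL, differential_path = NULL,
                        thresholds = filter_thresholds()) {
  p <- if (!is.null(profile_path)) read_profile_table(profile_path) else NULL
  d <- if (!is.null(differential_path)) {
    read_differential_table(differential_path, thresholds = thresholds)
  } else NULL
  phospho_corpus(profile_obs = p, differential_obs = d)
}

#' Write a corpus back to profiling/differential TSVs
#'
#' Inverse of [read_corpus()]: metadata columns are re-joined inline so the
#' written tables round-trip through the readers.
#'
#' @param corpus A [phospho_corpus()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "phospho_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rejoin <- function(obs) {
    out <- dplyr::inner_join(corpus$datasets, obs, by = "dataset_id")
    out$kind <- NULL
    out$site <- NULL
    out
  }
  paths <- c(profile = file.path(dir, "profiling.tsv"),
             differential = file.path(dir, "differential.tsv"))
  write_results_table(rejoin(corpus$profile_obs), paths[["profile"]])
  write_results_table(rejoin(corpus$differential_obs), paths[["differential"]])
  invisible(paths)
}

#' Write a results table as TSV
#'
#' UTF-8 TSV with header; missing values are written as `"."`, infinite
#' ratios as `"Inf"`. List columns (e.g. supporting study sets) are
#' collapsed with `";"`.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(x, path) {
  x <- tibble::as_tibble(x)
  is_list <- vapply(x, is.list, logical(1))
  for (col in names(x)[is_list]) {
    x[[col]] <- vapply(x[[col]], function(v) paste(v, collapse = ";"), character(1))
  }
  readr::write_tsv(x, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Write a SIF edge list
#'
#' Simple interaction format consumable by network viewers: one line per
#' edge, `source <tab> relation <tab> target`.
#'
#' @param edges Data frame with columns `source`, `relation`, `target`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sif <- function(edges, path) {
  stopifnot(all(c("source", "relation", "target") %in% names(edges)))
  lines <- paste(edges$source, edges$relation, edges$target, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
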
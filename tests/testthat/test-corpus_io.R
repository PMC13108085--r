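test_that("corpus tables round-trip through write and read", {
  corpus <- make_hand_corpus()
  dir <- withr::local_tempdir()
  suppressWarnings(write_corpus(corpus, dir))
  back <- read_corpus(file.path(dir, "profiling.tsv"),
                      file.path(dir, "differential.tsv"))
  sort_obs <- function(x) dplyr::arrange(x, .data$dataset_id, .data$site)
  expect_equal(sort_obs(back$differential_obs),
               sort_obs(corpus$differential_obs))
  expect_equal(sort_obs(back$profile_obs), sort_obs(corpus$profile_obs))
  expect_equal(dplyr::arrange(back$datasets, .data$dataset_id),
               dplyr::arrange(corpus$datasets, .data$dataset_id))
})

test_that("header-only tables yield empty collections", {
  cols <- as.list(stats::setNames(character(0)[1:0], character(0)))
  hdr <- tibble::as_tibble(sapply(default_dialect(differential = TRUE),
                                  function(x) character(0),
                                  simplify = FALSE))
  path <- write_tmp_tsv(hdr)
  expect_identical(nrow(read_differential_table(path)), 0L)
  hdr_p <- hdr[, default_dialect()]
  path_p <- write_tmp_tsv(hdr_p)
  expect_identical(nrow(read_profile_table(path_p)), 0L)
})

test_that("malformed rows and missing columns are rejected with context", {
  base <- tibble::tibble(
    dataset_id = "d1", study_id = "P1", condition_code = "c1",
    enrichment = "STY", accession = "A1", gene = "G1",
    residue = "S", position = 10L, loc_prob = 0.9, a_score = NA_real_,
    fold_change = 2, p_value = 0.01
  )
  bad_res <- base; bad_res$residue <- "X"
  expect_error(read_differential_table(write_tmp_tsv(bad_res)),
               "invalid residue")
  bad_fc <- base; bad_fc$fold_change <- -1
  expect_error(read_differential_table(write_tmp_tsv(bad_fc)),
               "non-positive fold_change")
  bad_p <- base; bad_p$p_value <- 1.5
  expect_error(read_differential_table(write_tmp_tsv(bad_p)),
               "p_value outside")
  bad_num <- base; bad_num$loc_prob <- "high"
  expect_error(read_differential_table(write_tmp_tsv(bad_num)),
               "non-numeric loc_prob")
  no_col <- base[, setdiff(names(base), "p_value")]
  expect_error(read_differential_table(write_tmp_tsv(no_col)), "p_value")
  ok <- read_differential_table(write_tmp_tsv(base))
  expect_identical(nrow(ok), 1L)
})

test_that("duplicate differential rows keep the smallest p-value", {
  dup <- dplyr::bind_rows(
    hand_row("d1", "A1", "G1", "S", 10, "increased"),
    hand_row("d1", "A1", "G1", "S", 10, "increased")
  )
  dup$p_value <- c(0.04, 0.001)
  expect_warning(out <- phosphocomod:::dedup_differential(dup), "collapsed")
  expect_identical(nrow(out), 1L)
  expect_identical(out$p_value, 0.001)
})

test_that("conflicting duplicate directions drop the site from the dataset", {
  dup <- dplyr::bind_rows(
    hand_row("d1", "A1", "G1", "S", 10, "increased"),
    hand_row("d1", "A1", "G1", "S", 10, "decreased"),
    hand_row("d1", "A2", "G2", "S", 5, "increased")
  )
  expect_warning(out <- phosphocomod:::dedup_differential(dup), "conflicting")
  expect_identical(out$accession, "A2")
})

test_that("parsing is order-independent (set semantics)", {
  corpus <- make_hand_corpus()
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  tbl <- readr::read_tsv(file.path(dir, "differential.tsv"),
                         col_types = readr::cols(.default = "c"),
                         na = ".", show_col_types = FALSE)
  set.seed(7)
  perm <- tbl[sample.int(nrow(tbl)), ]
  path <- write_tmp_tsv(perm)
  back <- read_differential_table(path)
  orig <- read_differential_table(file.path(dir, "differential.tsv"))
  key <- function(x) dplyr::arrange(x, .data$dataset_id, .data$accession,
                                    .data$residue, .data$position)
  expect_equal(key(back), key(orig))
})

test_that("validate_corpus reports counts, orphans and duplicates", {
  empty <- phospho_corpus()
  rep0 <- validate_corpus(empty)
  expect_identical(rep0$n_datasets, 0L)
  expect_identical(rep0$n_sites, 0L)
  expect_identical(rep0$n_orphans, 0L)
  expect_length(rep0$problems, 0)

  corpus <- make_hand_corpus()
  tampered <- corpus
  tampered$profile_obs$dataset_id[1] <- "ghost"
  rep1 <- validate_corpus(tampered)
  expect_identical(rep1$n_orphans, 1L)
  expect_match(rep1$problems, "orphan", all = FALSE)

  sim <- generate_corpus(default_generator_config(seed = 11))
  repg <- validate_corpus(sim$corpus)
  expect_identical(repg$n_differential_datasets, 72L)
  expect_identical(repg$n_differential_obs, nrow(sim$corpus$differential_obs))
  expect_identical(repg$n_duplicates, 0L)
})
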
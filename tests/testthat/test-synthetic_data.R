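test_that("the generator is deterministic given the seed", {
  cfg <- default_generator_config(seed = 99)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_equal(a$corpus, b$corpus)
  expect_equal(a$truth, b$truth)
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  write_default_fixture(dir_a, seed = 99)
  write_default_fixture(dir_b, seed = 99)
  for (f in c("profiling.tsv", "differential.tsv", "truth.json")) {
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)))
  }
  c_ <- generate_corpus(default_generator_config(seed = 100))
  expect_false(identical(a$corpus$differential_obs,
                         c_$corpus$differential_obs))
})

test_that("every emitted differential row classifies to its recorded direction", {
  sim <- generate_corpus(default_generator_config(seed = 7))
  dirs <- direction_matrix(sim$corpus)
  truth <- sim$truth$site_directions
  joined <- dplyr::inner_join(dirs, truth, by = c("site", "dataset_id"),
                              suffix = c("", "_truth"))
  expect_identical(nrow(joined), nrow(truth))
  expect_identical(joined$direction, joined$direction_truth)
  anchor <- sim$truth$anchor_direction
  a <- dirs[dirs$site == "P07947:Y426", ]
  m <- dplyr::inner_join(a, anchor, by = "dataset_id",
                         suffix = c("", "_truth"))
  expect_identical(m$direction, m$direction_truth)
})

test_that("re-tallying pair counts from the emitted corpus equals the truth record", {
  sim <- generate_corpus(default_generator_config(seed = 17))
  dirs <- direction_matrix(sim$corpus)
  truth <- sim$truth$planted
  set.seed(171)
  pick <- truth[sample.int(nrow(truth), 8), ]
  for (i in seq_len(nrow(pick))) {
    got <- unlist(pair_counts(dirs, "P07947:Y426", pick$site[i]))
    want <- unlist(pick[i, c("n_cc", "n_cd", "n_dc", "n_dd")])
    expect_equal(unname(got), unname(as.integer(want)))
  }
})

test_that("forced concordance forbids discordant cells", {
  partners <- tibble::tibble(accession = "PX1", gene = "GX1", residue = "S",
                             position = 5L, concordance = 1.0,
                             coobservation = 1.0)
  cfg <- generator_config(n_differential_datasets = 30L,
                          n_profile_datasets = 0L,
                          planted_partners = partners,
                          n_background_sites = 0L, seed = 5L)
  sim <- generate_corpus(cfg)
  tal <- sim$truth$planted
  expect_identical(as.integer(tal$n_cd + tal$n_dc), 0L)
  expect_identical(as.integer(tal$n_cc + tal$n_dd), 30L)
})

test_that("intermediate concordance lands in its binomial 99% interval", {
  partners <- tibble::tibble(accession = "PX1", gene = "GX1", residue = "S",
                             position = 5L, concordance = 0.5,
                             coobservation = 1.0)
  cfg <- generator_config(n_differential_datasets = 400L,
                          n_profile_datasets = 0L,
                          planted_partners = partners,
                          n_background_sites = 0L, seed = 23L)
  sim <- generate_corpus(cfg)
  tal <- sim$truth$planted
  conc <- tal$n_cc + tal$n_dd
  n <- conc + tal$n_cd + tal$n_dc
  band <- 2.58 * sqrt(0.25 / n)
  expect_lt(abs(conc / n - 0.5), band)
})

test_that("invalid generator configurations fail before generating", {
  expect_error(generator_config(anchor_callable_fraction = 1.5),
               "probabilities")
  bad_partner <- tibble::tibble(accession = "P07947", gene = "YES1",
                                residue = "S", position = 40L,
                                concordance = 0.9, coobservation = 0.9)
  expect_error(generator_config(planted_partners = bad_partner),
               "anchor_cosites")
  bg_clash <- tibble::tibble(accession = "BGP0001", gene = "G", residue = "S",
                             position = 1L, concordance = 0.9,
                             coobservation = 0.9)
  expect_error(generator_config(planted_partners = bg_clash), "BGP")
})

test_that("the default fixture carries the documented study conditions", {
  cfg <- default_generator_config()
  expect_identical(cfg$n_differential_datasets, 72L)
  expect_identical(nrow(cfg$planted_partners), 60L)
  expect_identical(sum(cfg$planted_partners$concordance >= 0.5), 50L)
  expect_identical(cfg$n_background_sites, 500L)
  sim <- generate_corpus(cfg)
  expect_identical(sim$truth$n_anchor_callable, 72L)
  expect_identical(sum(sim$truth$planted$role == "partner"), 60L)
})
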
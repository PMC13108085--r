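test_that("frequencies count distinct datasets, not rows", {
  corpus <- make_hand_corpus()
  # duplicate a profiling observation within one dataset
  corpus$profile_obs <- dplyr::bind_rows(corpus$profile_obs,
                                         corpus$profile_obs[1, ])
  freqs <- site_frequencies(corpus, "P07947")
  y426 <- freqs[freqs$site == "P07947:Y426", ]
  expect_identical(y426$profile_count, 2L)      # pr1 and pr2, not 3 rows
  expect_identical(y426$differential_count, 6L) # reported in all 6 datasets
  expect_identical(y426$callable_count, 5L)     # d6 is not callable
  expect_identical(nrow(site_frequencies(corpus, "NOPE")), 0L)
})

test_that("a corpus without differential datasets gives zero differential counts", {
  corpus <- make_hand_corpus()
  prof_only <- phospho_corpus(
    profile_obs = dplyr::inner_join(corpus$datasets, corpus$profile_obs,
                                    by = "dataset_id")[, -5]
  )
  freqs <- site_frequencies(prof_only, "P07947")
  expect_true(all(freqs$differential_count == 0L))
  expect_true(all(freqs$callable_count == 0L))
})

test_that("the frequently-reported site in both corpora is nominated predominant", {
  freqs <- tibble::tibble(
    accession = "P07947", gene = "YES1",
    residue = c("S", "Y", "Y"), position = c(40L, 194L, 426L),
    site = c("P07947:S40", "P07947:Y194", "P07947:Y426"),
    profile_count = c(210L, 159L, 142L),
    differential_count = c(10L, 8L, 72L),
    callable_count = c(9L, 6L, 72L)
  )
  ranked <- rank_predominance(freqs)
  expect_identical(ranked$site[1], "P07947:Y426")
  expect_equal(ranked$predominance_score[1], (142 / 210) * (72 / 72))
  expect_identical(ranked$differential_rank[1], 1L)
  expect_identical(ranked$profile_rank[1], 3L)
  one <- rank_predominance(freqs[1, ])
  expect_identical(one$predominance_score, 1)
})

test_that("rank product agrees with a brute-force ordering oracle", {
  set.seed(201)
  for (rep in 1:20) {
    n <- 4L
    freqs <- tibble::tibble(
      accession = "A", gene = "G",
      residue = sample(c("S", "T", "Y"), n, replace = TRUE),
      position = sample.int(500L, n),
      profile_count = sample.int(50L, n),
      differential_count = sample.int(50L, n)
    )
    freqs$site <- phosphocomod:::site_label(freqs$accession, freqs$residue, freqs$position)
    freqs$callable_count <- freqs$differential_count
    ranked <- rank_predominance(freqs)
    # oracle: score and ordering recomputed with explicit loops
    score <- numeric(n)
    for (i in seq_len(n)) {
      score[i] <- (freqs$profile_count[i] / max(freqs$profile_count)) *
        (freqs$differential_count[i] / max(freqs$differential_count))
    }
    ord <- order(-score, -freqs$differential_count, freqs$position)
    expect_identical(ranked$site, freqs$site[ord])
    expect_equal(ranked$predominance_score, score[ord])
    dense <- function(x) {
      vapply(x, function(v) sum(unique(x) > v) + 1L, integer(1))
    }
    expect_identical(ranked$profile_rank,
                     dense(freqs$profile_count)[ord])
  }
})

test_that("ranking is permutation-invariant and monotone in added detections", {
  sim <- generate_corpus(default_generator_config(seed = 3))
  freqs <- site_frequencies(sim$corpus, "P07947")
  ranked <- rank_predominance(freqs)
  set.seed(202)
  shuffled <- rank_predominance(freqs[sample.int(nrow(freqs)), ])
  expect_equal(ranked, shuffled)

  # a new profiling dataset detecting only site s never worsens s's rank
  s <- ranked$site[3]
  corpus2 <- sim$corpus
  extra <- corpus2$profile_obs[corpus2$profile_obs$site == s, ][1, ]
  extra$dataset_id <- "PRX99"
  corpus2$profile_obs <- dplyr::bind_rows(corpus2$profile_obs, extra)
  corpus2$datasets <- dplyr::bind_rows(
    corpus2$datasets,
    tibble::tibble(dataset_id = "PRX99", study_id = "PMIDX",
                   condition_code = "cx", enrichment = "STY",
                   kind = "profile"))
  ranked2 <- rank_predominance(site_frequencies(corpus2, "P07947"))
  expect_lte(match(s, ranked2$site), match(s, ranked$site))
})

test_that("predominant_site returns the planted anchor on the default fixture", {
  sim <- generate_corpus(default_generator_config(seed = 13))
  top <- predominant_site(sim$corpus, "P07947")
  expect_identical(format(top), "P07947:Y426")
  expect_error(predominant_site(sim$corpus, "NOPE"), "no sites")
})
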
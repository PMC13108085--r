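test_that("the one-sided exact test matches enumeration and fisher.test", {
  # worked example: perfectly concordant 3+3 table
  expect_equal(fisher_one_sided(3, 0, 0, 3, "concordant"), 1 / 20)
  expect_equal(fisher_one_sided(0, 0, 0, 0, "concordant"), 1)
  expect_equal(fisher_one_sided(0, 0, 0, 0, "discordant"), 1)
  expect_error(fisher_one_sided(-1, 0, 0, 0), "non-negative")

  set.seed(401)
  for (i in 1:60) {
    tab <- rpois(4, 3)
    a <- tab[1]; b <- tab[2]; c_ <- tab[3]; d <- tab[4]
    p_conc <- fisher_one_sided(a, b, c_, d, "concordant")
    p_disc <- fisher_one_sided(a, b, c_, d, "discordant")
    expect_equal(p_conc, enum_fisher(a, b, c_, d, "concordant"),
                 tolerance = 1e-12)
    expect_equal(p_disc, enum_fisher(a, b, c_, d, "discordant"),
                 tolerance = 1e-12)
    if (all(c(a + b, c_ + d, a + c_, b + d) > 0)) {
      m <- matrix(c(a, c_, b, d), 2)
      expect_equal(p_conc,
                   stats::fisher.test(m, alternative = "greater")$p.value,
                   tolerance = 1e-10)
      expect_equal(p_disc,
                   stats::fisher.test(m, alternative = "less")$p.value,
                   tolerance = 1e-10)
    }
  }
})

test_that("degenerate margins give p = 1 in both tails", {
  for (tab in list(c(5, 3, 0, 0), c(0, 0, 2, 4), c(4, 0, 6, 0),
                   c(0, 3, 0, 1))) {
    expect_equal(fisher_one_sided(tab[1], tab[2], tab[3], tab[4],
                                  "concordant"), 1)
    expect_equal(fisher_one_sided(tab[1], tab[2], tab[3], tab[4],
                                  "discordant"), 1)
  }
})

test_that("the high-confidence cutoff applies the 10% rule", {
  expect_identical(high_confidence_cutoff(72, 0.10), 7.2)
  expect_identical(high_confidence_cutoff(10, 0.10), 1)
  expect_identical(high_confidence_cutoff(1, 0.10), 0.1)
  expect_error(high_confidence_cutoff(0), "positive")
  expect_error(high_confidence_cutoff(10, 0), "positive")
})

test_that("partner categorization matches pair tallies and rejects intra-protein pairs", {
  corpus <- make_hand_corpus()
  dirs <- direction_matrix(corpus)
  counts <- categorize_partner(dirs, "P07947:Y426", "AAA1:S10")
  expect_equal(unlist(counts), c(n_cc = 2L, n_cd = 0L, n_dc = 0L, n_dd = 1L))
  expect_error(categorize_partner(dirs, "P07947:Y426", "P07947:T427"),
               "anchor protein")
})

test_that("redundancy support counts distinct studies and conditions", {
  corpus <- make_hand_corpus()
  dirs <- direction_matrix(corpus)
  sup <- redundancy_support(dirs, corpus$datasets, "P07947:Y426", "AAA1:S10")
  expect_identical(sup$n_studies, 3L)     # P1, P2, P3 via d1, d2, d4
  expect_identical(sup$n_conditions, 3L)  # c1, c2, c3
  sup_b <- redundancy_support(dirs, corpus$datasets, "P07947:Y426", "BBB1:S20")
  expect_identical(sup_b$n_studies, 2L)
  none <- redundancy_support(dirs, corpus$datasets, "P07947:Y426", "ZZZ:S1")
  expect_identical(unlist(none), c(n_studies = 0L, n_conditions = 0L))
})

test_that("run_comodulation assembles counts, tests and filters coherently", {
  corpus <- make_hand_corpus()
  res <- run_comodulation(corpus, "P07947:Y426")
  expect_s3_class(res, "comod_result")
  expect_identical(attr(res, "n_anchor_datasets"), 5L)
  expect_equal(attr(res, "cutoff"), 0.5)
  aaa <- res[res$site == "AAA1:S10", ]
  expect_equal(unlist(aaa[, c("n_cc", "n_cd", "n_dc", "n_dd")]),
               c(n_cc = 2L, n_cd = 0L, n_dc = 0L, n_dd = 1L))
  expect_equal(aaa$p_positive, enum_fisher(2, 0, 0, 1, "concordant"))
  expect_identical(aaa$n_studies, 3L)
  expect_true(aaa$passes_redundancy)
  # an all-balanced partner is classified 'none'
  bbb <- res[res$site == "BBB1:S20", ]
  expect_identical(bbb$sign_class, "none")
  expect_false(bbb$high_confidence)
  expect_error(run_comodulation(corpus, "ZZZ:S1"),
               class = "phosphocomod_missing_anchor")
})

test_that("per-partner counts on the fixture equal the generator truth", {
  sim <- generate_corpus(default_generator_config(seed = 21))
  res <- run_comodulation(sim$corpus, "P07947:Y426")
  truth <- sim$truth$planted[sim$truth$planted$role == "partner", ]
  joined <- dplyr::inner_join(
    tibble::as_tibble(res)[, c("site", "n_cc", "n_cd", "n_dc", "n_dd")],
    truth[, c("site", "n_cc", "n_cd", "n_dc", "n_dd")],
    by = "site", suffix = c("", "_truth"))
  expect_identical(nrow(joined), nrow(truth))
  expect_identical(joined$n_cc, as.integer(joined$n_cc_truth))
  expect_identical(joined$n_cd, as.integer(joined$n_cd_truth))
  expect_identical(joined$n_dc, as.integer(joined$n_dc_truth))
  expect_identical(joined$n_dd, as.integer(joined$n_dd_truth))
})

test_that("flipping all anchor calls mirrors a partner flip: counts remap, tails swap", {
  sim <- generate_corpus(default_generator_config(seed = 31))
  dirs <- direction_matrix(sim$corpus)
  res <- comod_from_directions(dirs, sim$corpus$datasets, "P07947:Y426")
  flip <- c(increased = "decreased", decreased = "increased",
            not_callable = "not_callable")
  dirs_flip <- dirs
  is_anchor <- dirs_flip$site == "P07947:Y426"
  dirs_flip$direction[is_anchor] <- unname(flip[dirs$direction[is_anchor]])
  res_f <- comod_from_directions(dirs_flip, sim$corpus$datasets,
                                 "P07947:Y426")
  expect_identical(res$site, res_f$site)
  # counts map (cc,cd,dc,dd) -> (dc,dd,cc,cd): what was concordant becomes
  # discordant, so the two one-sided tails exchange exactly
  expect_identical(res_f$n_cc, res$n_dc)
  expect_identical(res_f$n_cd, res$n_dd)
  expect_identical(res_f$n_dc, res$n_cc)
  expect_identical(res_f$n_dd, res$n_cd)
  expect_equal(res_f$p_positive, res$p_negative)
  expect_equal(res_f$p_negative, res$p_positive)
  expect_identical(res_f$ratio_positive, res$ratio_negative)
  swap <- c(positive = "negative", negative = "positive", none = "none")
  expect_identical(res_f$sign_class, unname(swap[res$sign_class]))
  expect_identical(res_f$high_confidence, res$high_confidence)
})

test_that("inverting the global direction convention leaves the analysis invariant", {
  sim <- generate_corpus(default_generator_config(seed = 31))
  dirs <- direction_matrix(sim$corpus)
  res <- comod_from_directions(dirs, sim$corpus$datasets, "P07947:Y426")
  flip <- c(increased = "decreased", decreased = "increased",
            not_callable = "not_callable")
  dirs_flip <- dirs
  dirs_flip$direction <- unname(flip[dirs$direction])
  res_f <- comod_from_directions(dirs_flip, sim$corpus$datasets,
                                 "P07947:Y426")
  expect_identical(res$site, res_f$site)
  # (cc,cd,dc,dd) -> (dd,dc,cd,cc): concordant sums, p-values, ratios and
  # classifications are all unchanged
  expect_identical(res_f$n_cc, res$n_dd)
  expect_identical(res_f$n_cd, res$n_dc)
  expect_identical(res_f$n_cc + res_f$n_dd, res$n_cc + res$n_dd)
  expect_equal(res_f$p_positive, res$p_positive)
  expect_equal(res_f$p_negative, res$p_negative)
  expect_identical(res_f$ratio_positive, res$ratio_positive)
  expect_identical(res_f$sign_class, res$sign_class)
  expect_identical(res_f$high_confidence, res$high_confidence)
})

test_that("flipping all partner calls swaps the tails and the sign classes", {
  sim <- generate_corpus(default_generator_config(seed = 31))
  dirs <- direction_matrix(sim$corpus)
  res <- comod_from_directions(dirs, sim$corpus$datasets, "P07947:Y426")
  flip <- c(increased = "decreased", decreased = "increased",
            not_callable = "not_callable")
  dirs_flip <- dirs
  is_partner <- dirs_flip$accession != "P07947"
  dirs_flip$direction[is_partner] <- unname(flip[dirs$direction[is_partner]])
  res_f <- comod_from_directions(dirs_flip, sim$corpus$datasets,
                                 "P07947:Y426")
  expect_identical(res$site, res_f$site)
  expect_equal(res_f$p_positive, res$p_negative)
  expect_equal(res_f$p_negative, res$p_positive)
  swap <- c(positive = "negative", negative = "positive", none = "none")
  expect_identical(res_f$sign_class, unname(swap[res$sign_class]))
  expect_identical(res_f$high_confidence, res$high_confidence)
})

test_that("tightening any filter never adds a high-confidence partner", {
  sim <- generate_corpus(default_generator_config(seed = 41))
  base <- run_comodulation(sim$corpus, "P07947:Y426")
  hc_base <- base$site[base$high_confidence]
  for (cfg in list(comod_config(cutoff_fraction = 0.20),
                   comod_config(min_studies = 5),
                   comod_config(min_conditions = 5),
                   comod_config(alpha = 0.01))) {
    res <- run_comodulation(sim$corpus, "P07947:Y426", config = cfg)
    expect_true(all(res$site[res$high_confidence] %in% hc_base))
  }
})

test_that("planted partners are recovered at 40 anchor datasets (cutoff 4)", {
  partners <- tibble::tibble(
    accession = sprintf("PP%03d", 1:35), gene = sprintf("PG%03d", 1:35),
    residue = "S", position = 100L + 1:35,
    concordance = c(rep(0.9, 30), rep(0.1, 5)),
    coobservation = 0.9
  )
  cfg <- generator_config(
    n_differential_datasets = 40L, n_profile_datasets = 0L,
    planted_partners = partners, n_background_sites = 200L,
    background_observation_probability = 0.2,
    n_studies = 4L, n_conditions = 5L, seed = 77L
  )
  sim <- generate_corpus(cfg)
  res <- run_comodulation(sim$corpus, "P07947:Y426")
  expect_identical(attr(res, "n_anchor_datasets"), 40L)
  expect_equal(attr(res, "cutoff"), 4)
  truth <- sim$truth$planted
  pos <- truth$site[truth$sign == "positive"]
  co_observed <- with(res, n_cc + n_cd + n_dc + n_dd)
  eligible <- res$site[res$site %in% pos & co_observed >= 20]
  expect_gte(length(eligible), 20)
  hit <- res$high_confidence & res$sign_class == "positive"
  sens <- mean(eligible %in% res$site[hit])
  expect_gte(sens, 0.9)
  bg <- grepl("^BGP", res$accession)
  # independence-null false positives stay within a binomial 99% band of 5%
  expect_lte(mean(res$high_confidence[bg]),
             0.05 + 2.58 * sqrt(0.05 * 0.95 / sum(bg)))
})

test_that("condition-set overlaps equal brute-force set intersections", {
  sim <- generate_corpus(default_generator_config(seed = 51))
  res <- run_comodulation(sim$corpus, "P07947:Y426")
  hc <- res[res$high_confidence, ]
  codes <- list("metformin", c("metformin", "il-33"),
                c("metformin", "il-33", "caffeine"),
                c("Metformin ", "EGF"))  # needs normalization
  out <- condition_set_overlap(res, codes, corpus = sim$corpus)
  expect_identical(nrow(out), 4L)
  expect_identical(out$n_codes, lengths(codes))
  for (i in seq_along(codes)) {
    want <- sum(vapply(hc$supporting_conditions, function(s) {
      all(tolower(trimws(codes[[i]])) %in% s)
    }, logical(1)))
    expect_identical(out$n_common[i], want)
  }
  expect_true(out$n_common[2] <= out$n_common[1])
  expect_error(condition_set_overlap(res, "unheard-of", corpus = sim$corpus),
               "known codes")
})
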
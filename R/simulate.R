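#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' many small differential datasets, each covering a random subset of
#' sites; an anchor site callable in a controlled number of datasets;
#' planted partner sites whose direction matches the anchor's with a
#' tunable concordance; independent background sites; and fold changes,
#' p-values and localization metrics drawn conditionally on the intended
#' direction so that every emitted row classifies (under default
#' [filter_thresholds()]) exactly as planned. Directions are drawn first
#' and measurement values second, which keeps tests focused on the
#' analysis rather than on threshold boundary noise.
#'
#' @param n_differential_datasets,n_profile_datasets Corpus sizes.
#' @param anchor The anchor [site_key()].
#' @param anchor_callable_fraction Probability that the anchor is callable
#'   in a differential dataset (1 pins the callable count to the corpus
#'   size).
#' @param anchor_up_probability Direction balance of anchor calls.
#' @param planted_partners Tibble with columns `accession, gene, residue,
#'   position, concordance, coobservation`: partner sites on other
#'   proteins, each co-observed with an anchor call with probability
#'   `coobservation` and matching its direction with probability
#'   `concordance`.
#' @param anchor_cosites Tibble with columns `residue, position,
#'   concordance, coobservation, profile_probability`: additional sites on
#'   the anchor protein (for the intra-protein co-occurrence analysis and
#'   predominance ranking).
#' @param n_background_sites Number of independent background sites (one
#'   per synthetic background protein), observed in any differential
#'   dataset with probability `background_observation_probability` and
#'   assigned directions independently of the anchor.
#' @param background_observation_probability See above.
#' @param anchor_profile_probability,partner_profile_probability Detection
#'   probabilities in profiling datasets.
#' @param n_studies,n_conditions Study ids and normalized condition codes
#'   are assigned round-robin over this many distinct values.
#' @param condition_pool Optional character vector of condition codes
#'   (recycled); defaults to six treatment-style codes.
#' @param fc_sdlog Log-scale spread of fold changes beyond the calling
#'   thresholds.
#' @param loc_prob_missing_rate Fraction of rows carrying only an A-score
#'   (localization probability missing), exercising both Class-1 clauses.
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_differential_datasets = 72L,
                             n_profile_datasets = 60L,
                             anchor = site_key("P07947", "Y", 426, gene = "YES1"),
                             anchor_callable_fraction = 1.0,
                             anchor_up_probability = 0.5,
                             planted_partners = NULL,
                             anchor_cosites = NULL,
                             n_background_sites = 500L,
                             background_observation_probability = 0.2,
                             anchor_profile_probability = 0.85,
                             partner_profile_probability = 0.25,
                             n_studies = 5L,
                             n_conditions = 6L,
                             condition_pool = NULL,
                             fc_sdlog = 0.35,
                             loc_prob_missing_rate = 0.2,
                             seed = 4261L) {
  if (is.null(planted_partners)) {
    planted_partners <- tibble::tibble(
      accession = character(), gene = character(), residue = character(),
      position = integer(), concordance = double(), coobservation = double()
    )
  }
  if (is.null(anchor_cosites)) {
    anchor_cosites <- tibble::tibble(
      residue = character(), position = integer(), concordance = double(),
      coobservation = double(), profile_probability = double()
    )
  }
  if (is.null(condition_pool)) {
    condition_pool <- c("metformin", "il-33", "caffeine", "egf", "her2",
                        "dasatinib")
  }
  probs <- c(anchor_callable_fraction, anchor_up_probability,
             background_observation_probability, anchor_profile_probability,
             partner_profile_probability, loc_prob_missing_rate,
             planted_partners$concordance, planted_partners$coobservation,
             anchor_cosites$concordance, anchor_cosites$coobservation,
             anchor_cosites$profile_probability)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_differential_datasets >= 1, n_profile_datasets >= 0,
            n_background_sites >= 0, n_studies >= 1, n_conditions >= 1,
            inherits(anchor, "site_key"))
  planted_labels <- site_label(planted_partners$accession,
                               planted_partners$residue,
                               planted_partners$position)
  if (anyDuplicated(planted_labels)) {
    stop("duplicate planted partner sites", call. = FALSE)
  }
  if (format(anchor) %in% planted_labels ||
      any(planted_partners$accession == anchor$accession)) {
    stop("planted partners must lie on proteins other than the anchor's; ",
         "use anchor_cosites for intra-protein sites", call. = FALSE)
  }
  if (any(grepl("^BGP", planted_partners$accession))) {
    stop("planted partner accessions must not use the background 'BGP' prefix",
         call. = FALSE)
  }
  if (any(anchor_cosites$residue == anchor$residue &
            anchor_cosites$position == anchor$position)) {
    stop("anchor_cosites must differ from the anchor site", call. = FALSE)
  }
  structure(
    list(n_differential_datasets = as.integer(n_differential_datasets),
         n_profile_datasets = as.integer(n_profile_datasets),
         anchor = anchor,
         anchor_callable_fraction = anchor_callable_fraction,
         anchor_up_probability = anchor_up_probability,
         planted_partners = planted_partners,
         anchor_cosites = anchor_cosites,
         n_background_sites = as.integer(n_background_sites),
         background_observation_probability = background_observation_probability,
         anchor_profile_probability = anchor_profile_probability,
         partner_profile_probability = partner_profile_probability,
         n_studies = as.integer(n_studies),
         n_conditions = as.integer(n_conditions),
         condition_pool = condition_pool,
         fc_sdlog = fc_sdlog,
         loc_prob_missing_rate = loc_prob_missing_rate,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# measurement values consistent with a drawn direction under the default
# thresholds: an emitted "increased" row always classifies as increased.
draw_values <- function(n, direction, cfg) {
  th <- filter_thresholds()
  fc <- p <- numeric(n)
  up <- direction == "increased"
  dn <- direction == "decreased"
  nc <- direction == "not_callable"
  fc[up] <- th$fc_up_min * exp(abs(stats::rnorm(sum(up), 0, cfg$fc_sdlog)))
  fc[dn] <- th$fc_down_max * exp(-abs(stats::rnorm(sum(dn), 0, cfg$fc_sdlog)))
  fc[nc] <- stats::runif(sum(nc), th$fc_down_max + 0.04, th$fc_up_min - 0.05)
  p[up | dn] <- stats::runif(sum(up | dn), 0, th$p_max * 0.999)
  p[nc] <- stats::runif(sum(nc), th$p_max + 0.01, 0.9)
  miss <- stats::runif(n) < cfg$loc_prob_missing_rate
  loc_prob <- ifelse(miss, NA_real_, stats::runif(n, th$loc_prob_min, 1))
  a_score <- ifelse(miss | stats::runif(n) < 0.5,
                    stats::runif(n, th$a_score_min, 40), NA_real_)
  list(fold_change = fc, p_value = p, loc_prob = loc_prob, a_score = a_score)
}

#' Generate a synthetic corpus with a truth record
#'
#' Deterministic given `config` (the RNG state is saved and restored).
#' Study ids and condition codes are assigned round-robin; planted partner
#' and co-site directions are drawn against the anchor's per-dataset
#' direction; background sites draw directions independently.
#'
#' @param config A [generator_config()].
#' @return List with elements `corpus` (a [phospho_corpus()]), `truth`
#'   (anchor per-dataset directions, per-site per-dataset directions,
#'   expected pair tallies and planted sign classes) and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  anchor <- config$anchor
  nd <- config$n_differential_datasets

  diff_meta <- tibble::tibble(
    dataset_id = sprintf("DS%03d", seq_len(nd)),
    study_id = sprintf("PMID%07d", 1000000 + (seq_len(nd) - 1L) %% config$n_studies),
    condition_code = normalize_condition(
      config$condition_pool[(seq_len(nd) - 1L) %% config$n_conditions + 1L]),
    enrichment = "STY"
  )

  callable <- stats::runif(nd) < config$anchor_callable_fraction
  anchor_dir <- rep("not_callable", nd)
  anchor_dir[callable] <- ifelse(
    stats::runif(sum(callable)) < config$anchor_up_probability,
    "increased", "decreased")

  # planted sites: anchor co-sites (same protein) then partner sites
  cosites <- config$anchor_cosites
  partners <- config$planted_partners
  planted <- dplyr::bind_rows(
    if (nrow(cosites)) tibble::tibble(
      accession = anchor$accession, gene = anchor$gene,
      residue = cosites$residue, position = as.integer(cosites$position),
      concordance = cosites$concordance, coobservation = cosites$coobservation,
      role = "cosite"),
    if (nrow(partners)) tibble::tibble(
      accession = partners$accession, gene = partners$gene,
      residue = partners$residue, position = as.integer(partners$position),
      concordance = partners$concordance,
      coobservation = partners$coobservation, role = "partner")
  )

  rows <- list()
  truth_dirs <- list()
  flip <- c(increased = "decreased", decreased = "increased")

  # anchor rows: one per differential dataset (callable or not)
  rows[["anchor"]] <- tibble::tibble(
    dataset_id = diff_meta$dataset_id,
    accession = anchor$accession, gene = anchor$gene,
    residue = anchor$residue, position = anchor$position,
    direction = anchor_dir
  )

  if (!is.null(planted) && nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      idx <- which(callable & stats::runif(nd) < planted$coobservation[i])
      if (!length(idx)) next
      match_anchor <- stats::runif(length(idx)) < planted$concordance[i]
      dir <- ifelse(match_anchor, anchor_dir[idx],
                    unname(flip[anchor_dir[idx]]))
      rows[[paste0("planted", i)]] <- tibble::tibble(
        dataset_id = diff_meta$dataset_id[idx],
        accession = planted$accession[i], gene = planted$gene[i],
        residue = planted$residue[i], position = planted$position[i],
        direction = dir
      )
    }
  }

  if (config$n_background_sites > 0L) {
    j <- seq_len(config$n_background_sites)
    bg <- tibble::tibble(
      accession = sprintf("BGP%04d", j),
      gene = sprintf("BGG%04d", j),
      residue = sample(c("S", "T", "Y"), config$n_background_sites,
                       replace = TRUE, prob = c(0.8, 0.15, 0.05)),
      position = sample.int(999L, config$n_background_sites, replace = TRUE)
    )
    obs <- which(stats::runif(nd * config$n_background_sites) <
                   config$background_observation_probability)
    site_i <- (obs - 1L) %/% nd + 1L
    ds_i <- (obs - 1L) %% nd + 1L
    rows[["background"]] <- tibble::tibble(
      dataset_id = diff_meta$dataset_id[ds_i],
      accession = bg$accession[site_i], gene = bg$gene[site_i],
      residue = bg$residue[site_i], position = bg$position[site_i],
      direction = ifelse(stats::runif(length(obs)) < 0.5,
                         "increased", "decreased")
    )
  } else {
    bg <- NULL
  }

  diff_rows <- dplyr::bind_rows(rows)
  vals <- draw_values(nrow(diff_rows), diff_rows$direction, config)
  differential_obs <- dplyr::bind_cols(
    diff_rows,
    tibble::as_tibble(vals[c("loc_prob", "a_score", "fold_change", "p_value")])
  ) |>
    dplyr::left_join(diff_meta, by = "dataset_id") |>
    dplyr::select("dataset_id", "study_id", "condition_code", "enrichment",
                  "accession", "gene", "residue", "position",
                  "loc_prob", "a_score", "fold_change", "p_value",
                  "direction")

  # profiling datasets
  profile_obs <- NULL
  if (config$n_profile_datasets > 0L) {
    np <- config$n_profile_datasets
    prof_meta <- tibble::tibble(
      dataset_id = sprintf("PR%03d", seq_len(np)),
      study_id = sprintf("PMID%07d", 2000000 + (seq_len(np) - 1L) %% config$n_studies),
      condition_code = normalize_condition(
        config$condition_pool[(seq_len(np) - 1L) %% config$n_conditions + 1L]),
      enrichment = "STY"
    )
    site_pool <- dplyr::bind_rows(
      tibble::tibble(accession = anchor$accession, gene = anchor$gene,
                     residue = anchor$residue, position = anchor$position,
                     prob = config$anchor_profile_probability),
      if (!is.null(planted) && nrow(planted)) tibble::tibble(
        accession = planted$accession, gene = planted$gene,
        residue = planted$residue, position = planted$position,
        prob = ifelse(planted$role == "cosite",
                      config$anchor_cosites$profile_probability[
                        match(paste(planted$residue, planted$position),
                              paste(cosites$residue, cosites$position))],
                      config$partner_profile_probability)),
      if (!is.null(bg)) tibble::tibble(
        accession = bg$accession, gene = bg$gene, residue = bg$residue,
        position = bg$position,
        prob = config$background_observation_probability)
    )
    ns <- nrow(site_pool)
    hit <- which(stats::runif(np * ns) < rep(site_pool$prob, each = np))
    site_i <- (hit - 1L) %/% np + 1L
    ds_i <- (hit - 1L) %% np + 1L
    th <- filter_thresholds()
    miss <- stats::runif(length(hit)) < config$loc_prob_missing_rate
    profile_obs <- tibble::tibble(
      dataset_id = prof_meta$dataset_id[ds_i],
      accession = site_pool$accession[site_i],
      gene = site_pool$gene[site_i],
      residue = site_pool$residue[site_i],
      position = site_pool$position[site_i],
      loc_prob = ifelse(miss, NA_real_,
                        stats::runif(length(hit), th$loc_prob_min, 1)),
      a_score = ifelse(miss | stats::runif(length(hit)) < 0.5,
                       stats::runif(length(hit), th$a_score_min, 40),
                       NA_real_)
    ) |>
      dplyr::left_join(prof_meta, by = "dataset_id") |>
      dplyr::select("dataset_id", "study_id", "condition_code", "enrichment",
                    "accession", "gene", "residue", "position",
                    "loc_prob", "a_score")
  }

  # truth record
  site_directions <- differential_obs |>
    dplyr::transmute(site = site_label(.data$accession, .data$residue,
                                       .data$position),
                     dataset_id = .data$dataset_id,
                     direction = .data$direction)
  anchor_truth <- tibble::tibble(dataset_id = diff_meta$dataset_id,
                                 direction = anchor_dir)
  pair_tallies <- NULL
  if (!is.null(planted) && nrow(planted)) {
    anchor_lab <- format(anchor)
    tal <- site_directions |>
      dplyr::filter(.data$site != anchor_lab,
                    .data$site %in% site_label(planted$accession,
                                               planted$residue,
                                               planted$position)) |>
      dplyr::inner_join(anchor_truth, by = "dataset_id",
                        suffix = c("", "_anchor")) |>
      dplyr::filter(.data$direction_anchor != "not_callable")
    pair_tallies <- tal |>
      dplyr::group_by(.data$site) |>
      dplyr::summarise(
        n_cc = sum(.data$direction_anchor == "increased" &
                     .data$direction == "increased"),
        n_cd = sum(.data$direction_anchor == "increased" &
                     .data$direction == "decreased"),
        n_dc = sum(.data$direction_anchor == "decreased" &
                     .data$direction == "increased"),
        n_dd = sum(.data$direction_anchor == "decreased" &
                     .data$direction == "decreased"),
        .groups = "drop"
      )
    planted$site <- site_label(planted$accession, planted$residue,
                               planted$position)
    planted$sign <- ifelse(planted$concordance >= 0.5, "positive", "negative")
    pair_tallies <- dplyr::left_join(planted, pair_tallies, by = "site") |>
      dplyr::mutate(dplyr::across(dplyr::starts_with("n_"),
                                  ~ tidyr::replace_na(.x, 0L)))
  }
  truth <- list(
    anchor = format(anchor),
    n_anchor_callable = sum(callable),
    anchor_direction = anchor_truth,
    site_directions = site_directions,
    planted = pair_tallies
  )

  differential_obs$direction <- NULL
  corpus <- phospho_corpus(profile_obs = profile_obs,
                           differential_obs = differential_obs)
  list(corpus = corpus, truth = truth, config = config)
}

#' Default fixture configuration
#'
#' The documented study-conditions bundle: 72 differential datasets with
#' the anchor (YES1-style, `P07947:Y426`) callable in all of them, 5
#' studies, 6 condition codes, 50 planted positive partners (concordance
#' 0.9), 10 planted negative partners (concordance 0.1), co-observation
#' probability 0.9, 500 background sites, 60 profiling datasets, and six
#' anchor co-sites for the intra-protein co-occurrence and predominance
#' stages. Planted partner identities mirror well-known site-resolved
#' annotations (LCK Y394, LYN Y397/S11/T398, ERBB2 S1054, ...) so the
#' annotation overlays have named rows to find.
#'
#' @param seed Integer seed.
#' @return A [generator_config()].
#' @export
default_generator_config <- function(seed = 4261L) {
  pos <- tibble::tribble(
    ~accession, ~gene, ~residue, ~position,
    "P07948", "LYN", "Y", 397L,
    "P07948", "LYN", "S", 11L,
    "P07948", "LYN", "T", 398L,
    "P06239", "LCK", "Y", 394L,
    "P67809", "YBX1", "S", 209L,
    "P46108", "CRK", "S", 41L,
    "Q96T60", "PNKP", "S", 114L,
    "P15056", "BRAF", "S", 729L,
    "P27361", "MAPK3", "T", 207L,
    "Q13131", "PRKAA1", "S", 496L,
    "P35269", "GTF2F1", "S", 385L,
    "P18669", "PGAM1", "S", 14L,
    "Q9C0I1", "MTMR12", "S", 564L,
    "O15355", "PPM1G", "S", 183L,
    "Q05209", "PTPN12", "S", 435L,
    "P22681", "CBL", "S", 669L,
    "Q13263", "TRIM28", "S", 501L,
    "Q13263", "TRIM28", "S", 683L,
    "Q13435", "SF3B2", "S", 861L,
    "Q13435", "SF3B2", "T", 780L,
    "P15311", "EZR", "S", 535L,
    "P04792", "HSPB1", "S", 199L,
    "Q92934", "BAD", "S", 99L,
    "P49736", "MCM2", "S", 108L,
    "P26651", "ZFP36", "S", 60L,
    "Q05655", "PRKCD", "S", 645L,
    "Q9UHB6", "LIMA1", "S", 686L,
    "P17987", "TCP1", "S", 544L,
    "P55196", "AFDN", "S", 216L,
    "O15042", "U2SURP", "S", 485L,
    "Q4G0J3", "LARP7", "T", 257L,
    "P40227", "CCT6A", "S", 205L,
    "Q96I25", "RBM17", "T", 71L,
    "P02794", "FTH1", "S", 179L,
    "P17302", "GJA1", "S", 296L,
    "Q13480", "GAB1", "S", 266L,
    "Q13177", "PAK2", "S", 197L,
    "Q9UPQ0", "LIMCH1", "S", 493L,
    "Q13443", "ADAM9", "Y", 769L,
    "Q9NWQ8", "PAG1", "Y", 227L,
    "P68104", "EEF1A1", "Y", 141L,
    "P10398", "ARAF", "Y", 155L,
    "P52799", "EFNB2", "Y", 304L,
    "Q6NZI2", "CAVIN1", "Y", 308L,
    "O43684", "BUB3", "S", 211L,
    "O94885", "SASH1", "S", 407L,
    "Q9UPN4", "CEP131", "S", 78L,
    "Q05086", "UBE3A", "S", 218L,
    "P19105", "MYL12A", "S", 19L,
    "P13612", "ITGA4", "S", 1021L
  )
  pos$concordance <- 0.9
  neg <- tibble::tribble(
    ~accession, ~gene, ~residue, ~position,
    "P04626", "ERBB2", "S", 1054L,
    "Q9H792", "PEAK1", "T", 1151L,
    "Q96GX5", "MASTL", "S", 370L,
    "Q86YV5", "PRAG1", "S", 712L,
    "O00750", "PIK3C2B", "S", 155L,
    "Q13233", "MAP3K1", "S", 1157L,
    "Q92539", "LPIN2", "S", 106L,
    "P06400", "RB1", "S", 811L,
    "P07737", "PFN1", "Y", 129L,
    "Q9UQ84", "EXO1", "S", 714L
  )
  neg$concordance <- 0.1
  partners <- dplyr::bind_rows(pos, neg)
  partners$coobservation <- 0.9
  cosites <- tibble::tribble(
    ~residue, ~position, ~concordance, ~coobservation, ~profile_probability,
    "S", 40L, 0.5, 0.12, 0.95,
    "Y", 194L, 0.5, 0.10, 0.90,
    "S", 111L, 0.90, 0.50, 0.40,
    "S", 195L, 0.90, 0.50, 0.35,
    "T", 427L, 0.95, 0.60, 0.50,
    "S", 197L, 0.50, 0.20, 0.20
  )
  generator_config(planted_partners = partners, anchor_cosites = cosites,
                   seed = seed)
}

#' Write the default fixture bundle
#'
#' Generates the default corpus (see [default_generator_config()]) and
#' writes `profiling.tsv`, `differential.tsv`, a JSON `truth.json` sidecar
#' (anchor per-dataset directions, planted tallies and sign classes) and
#' the curated annotation fixtures under `annotations/`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed (default 4261, the documented fixture seed).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_default_fixture <- function(dir, seed = 4261L) {
  sim <- generate_corpus(default_generator_config(seed = seed))
  paths <- write_corpus(sim$corpus, dir)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ann_dir <- file.path(dir, "annotations")
  ann_paths <- write_annotation_fixtures(ann_dir)
  invisible(c(paths, truth = truth_path, ann_paths))
}

#' Deterministic worked-example corpus for the annotation overlays
#'
#' A compact corpus in which the named example partners are planted with
#' concordance 1 (or 0 for the negative example) and co-observation 1, so
#' their high-confidence status does not depend on the seed: LCK Y394,
#' LYN Y397/S11/T398, YBX1 S209, CRK S41 and PNKP S114 come out positive,
#' ERBB2 S1054 negative.
#'
#' @param seed Integer seed (affects only the anchor's direction pattern
#'   and nuisance values, not the overlay outcomes).
#' @return List with `corpus`, `truth`, `config` as [generate_corpus()].
#' @export
generate_overlay_demo <- function(seed = 1L) {
  partners <- tibble::tribble(
    ~accession, ~gene, ~residue, ~position, ~concordance,
    "P06239", "LCK", "Y", 394L, 1.0,
    "P07948", "LYN", "Y", 397L, 1.0,
    "P07948", "LYN", "S", 11L, 1.0,
    "P07948", "LYN", "T", 398L, 1.0,
    "P67809", "YBX1", "S", 209L, 1.0,
    "P46108", "CRK", "S", 41L, 1.0,
    "Q96T60", "PNKP", "S", 114L, 1.0,
    "P15056", "BRAF", "S", 729L, 1.0,
    "P04626", "ERBB2", "S", 1054L, 0.0
  )
  partners$coobservation <- 1.0
  cfg <- generator_config(
    n_differential_datasets = 30L, n_profile_datasets = 10L,
    planted_partners = partners, n_background_sites = 20L,
    background_observation_probability = 0.3,
    n_studies = 4L, n_conditions = 5L, seed = seed
  )
  generate_corpus(cfg)
}
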
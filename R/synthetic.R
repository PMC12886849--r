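#' Configuration for the synthetic survey-data generator
#'
#' Describes a BioTIME-shaped ensemble of community survey time series with
#' known ground truth. Each community holds `community_richness` species
#' drawn from a regional pool of `pool_size`; each year, every resident is
#' independently replaced with the era-appropriate probability (before
#' versus since `breakyear`) by a species drawn uniformly from the pool
#' minus the current residents, so richness stays constant and compositional
#' change is pure replacement. Surveys observe each resident in each
#' within-year sample with probability `1 - false_negative_rate`
#' (independent per species and sample), generating pseudo-turnover; the
#' number of samples per year can vary to exercise rarefaction, and interior
#' survey years can go missing.
#'
#' @param n_communities Number of communities.
#' @param years Integer vector of survey years (common to all communities).
#' @param breakyear Year at which the true replacement rate switches (the
#'   breakyear itself uses the "after" rate).
#' @param replacement_rate_before,replacement_rate_after Per-year
#'   per-resident replacement probabilities in the two eras.
#' @param pool_size Regional species pool size.
#' @param community_richness Constant per-community richness
#'   (`<= pool_size`).
#' @param false_negative_rate Per-(species, sample) non-detection
#'   probability.
#' @param samples_per_year Single integer, or length-2 range from which each
#'   (community, year) draws its sample count uniformly.
#' @param missing_year_prob Probability that an interior survey year of a
#'   community is dropped (first and last years are always kept, preserving
#'   the series span).
#' @param taxon_labels Taxon-group labels cycled over communities.
#' @param seed Master seed; every community derives an independent stream.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_communities = 10,
                             years = 1955:1995,
                             breakyear = 1975,
                             replacement_rate_before = 0.09,
                             replacement_rate_after = 0.06,
                             pool_size = 400,
                             community_richness = 50,
                             false_negative_rate = 0,
                             samples_per_year = 1,
                             missing_year_prob = 0,
                             taxon_labels = c("birds", "fish", "benthos",
                                              "all"),
                             seed = 1) {
  stopifnot(
    n_communities >= 1, length(years) >= 2,
    replacement_rate_before >= 0, replacement_rate_before <= 1,
    replacement_rate_after >= 0, replacement_rate_after <= 1,
    community_richness <= pool_size,
    false_negative_rate >= 0, false_negative_rate < 1,
    missing_year_prob >= 0, missing_year_prob < 1,
    length(samples_per_year) %in% 1:2, all(samples_per_year >= 1)
  )
  structure(
    list(n_communities = n_communities, years = sort(unique(years)),
         breakyear = breakyear,
         replacement_rate_before = replacement_rate_before,
         replacement_rate_after = replacement_rate_after,
         pool_size = pool_size, community_richness = community_richness,
         false_negative_rate = false_negative_rate,
         samples_per_year = samples_per_year,
         missing_year_prob = missing_year_prob,
         taxon_labels = taxon_labels, seed = seed),
    class = "synthetic_config"
  )
}

# evolve one community's true composition over the configured years
evolve_composition <- function(config) {
  pool <- seq_len(config$pool_size)
  comp <- sample(pool, config$community_richness)
  out <- vector("list", length(config$years))
  out[[1]] <- comp
  for (i in seq_along(config$years)[-1]) {
    yr <- config$years[i]
    rho <- if (yr >= config$breakyear) config$replacement_rate_after else
      config$replacement_rate_before
    gap <- config$years[i] - config$years[i - 1]
    for (g in seq_len(gap)) {
      leave <- runif(length(comp)) < rho
      k <- sum(leave)
      if (k > 0) {
        newcomers <- sample(setdiff(pool, comp), k)
        comp[leave] <- newcomers
      }
    }
    out[[i]] <- comp
  }
  out
}

#' Generate a synthetic survey ensemble with a truth ledger
#'
#' Draws every community's true compositional trajectory under the Markov
#' replacement model of [synthetic_config()], then simulates the survey
#' process (variable effort, false negatives, missing years) to produce a
#' long-format presence-record table, together with a ledger of the ground
#' truth needed by estimator-validation tests. Bit-reproducible under a
#' fixed seed; each community uses a seed derived from the master seed and
#' its id, so results do not depend on generation order.
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (presence-record tibble as produced by
#'   [read_survey_table()]) and `ledger` (list: `config`, per-community
#'   `true_composition` year-by-species lists, `n_records`,
#'   `n_records_by_community`, `surveyed_years`).
#' @export
generate_ensemble <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ids <- sprintf("comm%04d", seq_len(config$n_communities))
  taxa <- rep_len(config$taxon_labels, config$n_communities)
  per_comm <- purrr::map2(ids, taxa, function(cid, taxon) {
    with_seed(derive_seed(config$seed, cid), {
      truth <- evolve_composition(config)
      keep <- rep(TRUE, length(config$years))
      if (config$missing_year_prob > 0 && length(config$years) > 2) {
        interior <- seq(2, length(config$years) - 1)
        keep[interior] <- runif(length(interior)) >= config$missing_year_prob
      }
      yr_v <- integer(0)
      smp_v <- integer(0)
      sp_v <- integer(0)
      for (i in which(keep)) {
        n_samp <- if (length(config$samples_per_year) == 2) {
          sample(seq(config$samples_per_year[1], config$samples_per_year[2]),
                 1)
        } else {
          config$samples_per_year
        }
        comp <- truth[[i]]
        for (s in seq_len(n_samp)) {
          detected <- comp[runif(length(comp)) >= config$false_negative_rate]
          if (length(detected) > 0) {
            yr_v <- c(yr_v, rep.int(config$years[i], length(detected)))
            smp_v <- c(smp_v, rep.int(s, length(detected)))
            sp_v <- c(sp_v, detected)
          }
        }
      }
      obs <- tibble::tibble(year = yr_v, sample_id = sprintf("s%02d", smp_v),
                            species_id = sprintf("sp%04d", sp_v))
      list(obs = obs, truth = truth,
           surveyed_years = config$years[keep])
    })
  })
  records <- dplyr::bind_rows(purrr::map2(per_comm, seq_along(ids),
    function(pc, i) {
      if (nrow(pc$obs) == 0) return(NULL)
      dplyr::mutate(pc$obs,
                    study_id = "synthetic", community_id = ids[i],
                    latitude = NA_real_, longitude = NA_real_,
                    taxon_group = taxa[i])
    }))
  records <- dplyr::select(records, "study_id", "community_id", "year",
                           "sample_id", "species_id", "latitude",
                           "longitude", "taxon_group")
  ledger <- list(
    config = config,
    true_composition = setNames(purrr::map(per_comm, "truth"), ids),
    surveyed_years = setNames(purrr::map(per_comm, "surveyed_years"), ids),
    n_records = nrow(records),
    n_records_by_community = records |>
      dplyr::count(.data$community_id, name = "n_records")
  )
  list(records = records, ledger = ledger)
}

#' Expected similarity by lag under the replacement model
#'
#' Closed-form expectation of the similarity between two survey years
#' separated by a given lag for the generator of [generate_ensemble()].
#' Under uniform replacement at per-year rate `rho`, fixed richness `R` and
#' pool `P`, each species' presence is marginally a two-state Markov chain
#' (leave probability `rho`, entry probability `rho * R / (P - R)`), so the
#' probability that a species present now is present `l` years later is
#' `q_l = R/P + (1 - R/P) * (1 - rho - rho * R/(P - R))^l`. Because richness
#' is constant, Ochiai (and Sorensen) similarity equals `a / R`, giving
#' `E[similarity] = q_l` exactly for perfect detection. With per-sample
#' false-negative rate `f` and `m` pooled samples per year, the non-zero-lag
#' expectation is approximately `delta * q_l` with detection probability
#' `delta = 1 - f^m`: a multiplicative bias common to all non-zero lags
#' (the pseudo-turnover intercept shift).
#'
#' @param config A [synthetic_config()].
#' @param lags Integer vector of lags (>= 0).
#' @param period `"before"` or `"after"`: which era's replacement rate to
#'   use.
#' @return Tibble: `lag`, `similarity`.
#' @export
expected_similarity_by_lag <- function(config, lags = 0:5,
                                       period = c("before", "after")) {
  period <- match.arg(period)
  rho <- switch(period, before = config$replacement_rate_before,
                after = config$replacement_rate_after)
  R <- config$community_richness
  P <- config$pool_size
  pi0 <- R / P
  e <- if (P > R) rho * R / (P - R) else 1
  q <- pi0 + (1 - pi0) * (1 - rho - e)^lags
  m <- min(config$samples_per_year)
  delta <- 1 - config$false_negative_rate^m
  sim <- ifelse(lags == 0, 1, delta * q)
  tibble::tibble(lag = as.integer(lags), similarity = sim)
}

#' Expected turnover rate under the replacement model
#'
#' The negative OLS slope of [expected_similarity_by_lag()] over the given
#' lags: the analytic value that [turnover_rate()] estimates on data from
#' [generate_ensemble()].
#'
#' @inheritParams expected_similarity_by_lag
#' @param lags Lags used in the regression (default `1:5`).
#' @return Single number: expected turnover rate (per year).
#' @export
expected_turnover_rate <- function(config, lags = 1:5,
                                   period = c("before", "after")) {
  es <- expected_similarity_by_lag(config, lags = lags, period = period)
  -unname(coef(lm(similarity ~ lag, data = es))["lag"])
}
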
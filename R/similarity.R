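#' Presence/absence community similarity indices
#'
#' Pairwise compositional similarity between two species sets, parameterised
#' by the usual 2x2 co-occurrence counts: `a` species shared, `b` unique to
#' the first set, `c` unique to the second. All three indices lie in
#' \[0, 1\], equal 1 for identical nonempty sets and 0 for disjoint sets.
#' The Ochiai index `a / sqrt((a + b)(a + c))` is the geometric mean of the
#' two conditional overlap proportions and is comparatively robust to
#' false-negative detection error, which is why it is the default similarity
#' throughout this package.
#'
#' When either set is empty (`a + b == 0` or `a + c == 0`) the index is
#' undefined and `NA_real_` is returned; undefined pairs are skipped (never
#' coerced to 0) by downstream lag averaging.
#'
#' @param a,b,c Non-negative integer counts: shared, unique to first,
#'   unique to second. Vectorised.
#' @return Numeric vector of similarities in \[0, 1\], `NA` where undefined.
#' @examples
#' ochiai(2, 1, 0) # 2 / sqrt(3 * 2)
#' sorensen(2, 1, 0) # 4 / 5
#' jaccard(2, 1, 0) # 2 / 3
#' @export
ochiai <- function(a, b, c) {
  stopifnot(all(a >= 0, na.rm = TRUE), all(b >= 0, na.rm = TRUE),
            all(c >= 0, na.rm = TRUE))
  out <- a / sqrt((a + b) * (a + c))
  out[(a + b) == 0 | (a + c) == 0] <- NA_real_
  out
}

#' @rdname ochiai
#' @export
sorensen <- function(a, b, c) {
  stopifnot(all(a >= 0, na.rm = TRUE), all(b >= 0, na.rm = TRUE),
            all(c >= 0, na.rm = TRUE))
  out <- 2 * a / (2 * a + b + c)
  out[(a + b) == 0 | (a + c) == 0] <- NA_real_
  out
}

#' @rdname ochiai
#' @export
jaccard <- function(a, b, c) {
  stopifnot(all(a >= 0, na.rm = TRUE), all(b >= 0, na.rm = TRUE),
            all(c >= 0, na.rm = TRUE))
  out <- a / (a + b + c)
  out[(a + b) == 0 | (a + c) == 0] <- NA_real_
  out
}

#' Co-occurrence counts for two species sets
#'
#' @param x,y Character (or otherwise comparable) vectors of species
#'   identities; duplicates are ignored.
#' @return One-row tibble with columns `a`, `b`, `c`.
#' @examples
#' pair_counts(c("wren", "robin"), c("robin", "crow"))
#' @export
pair_counts <- function(x, y) {
  x <- unique(x)
  y <- unique(y)
  a <- length(intersect(x, y))
  tibble::tibble(a = a, b = length(x) - a, c = length(y) - a)
}

similarity_fun <- function(index) {
  if (is.function(index)) return(index)
  switch(match.arg(index, c("ochiai", "sorensen", "jaccard")),
    ochiai = ochiai, sorensen = sorensen, jaccard = jaccard
  )
}

# year x species logical presence matrix from long observations
presence_matrix <- function(year, species_idx, years, n_species) {
  m <- matrix(FALSE, length(years), n_species)
  m[cbind(match(year, years), species_idx)] <- TRUE
  m
}

# all-pairs similarity from a logical presence matrix (rows = years)
pairwise_index <- function(m, fun) {
  mi <- matrix(as.numeric(m), nrow(m))
  a <- tcrossprod(mi)
  r <- rowSums(mi)
  n <- nrow(mi)
  b <- matrix(r, n, n) - a      # unique to row community
  fun(a, b, t(b))
}

#' Rarefied pairwise similarities between survey years
#'
#' Computes the compositional similarity between every pair of survey years
#' of one community, equalising sampling effort by rarefaction: the minimum
#' number of within-year samples `m` over all survey years is determined
#' once, and in each of `n_subsamples` passes every year randomly retains
#' exactly `m` of its samples (uniformly, without replacement); species are
#' pooled across the retained samples and the index evaluated for every
#' year pair. The returned similarity is the mean over passes. When every
#' year already has exactly `m` samples the result equals the plain pooled
#' similarity and a single pass is evaluated.
#'
#' @param obs Data frame of one community's observations with columns
#'   `year`, `sample_id`, `species_id`.
#' @param index Similarity index: `"ochiai"` (default), `"sorensen"`,
#'   `"jaccard"`, or a function of counts `(a, b, c)`.
#' @param n_subsamples Number of rarefaction passes (default 100).
#' @param seed Integer master seed for the rarefaction draws.
#' @param community_id Optional label; when given, the rarefaction stream is
#'   seeded from `seed` and a hash of the label, so per-community results do
#'   not depend on the order communities are processed in.
#' @return Tibble with columns `year_i < year_j` and `similarity` (mean over
#'   passes; `NA` rows, from pairs undefined in every pass, are dropped).
#' @examples
#' obs <- tibble::tibble(
#'   year = c(2000, 2000, 2001), sample_id = c("s1", "s2", "s1"),
#'   species_id = c("x", "y", "x")
#' )
#' rarefied_pair_similarities(obs, n_subsamples = 50, seed = 1)
#' @export
rarefied_pair_similarities <- function(obs, index = "ochiai",
                                       n_subsamples = 100, seed = 1,
                                       community_id = NULL) {
  stopifnot(all(c("year", "sample_id", "species_id") %in% names(obs)))
  fun <- similarity_fun(index)
  obs <- obs[!duplicated(paste(obs$year, obs$sample_id, obs$species_id)), ]
  years <- sort(unique(obs$year))
  if (length(years) < 2) {
    return(tibble::tibble(year_i = integer(), year_j = integer(),
                          similarity = double()))
  }
  species <- unique(obs$species_id)
  sp_idx <- match(obs$species_id, species)

  year_samples <- split(obs$sample_id, obs$year)
  year_samples <- lapply(year_samples, unique)
  m <- min(lengths(year_samples))
  equal_effort <- all(lengths(year_samples) == m)

  key <- paste(obs$year, obs$sample_id)
  one_pass <- function(keep_keys) {
    rows <- key %in% keep_keys
    pm <- presence_matrix(obs$year[rows], sp_idx[rows], years, length(species))
    pairwise_index(pm, fun)
  }

  if (equal_effort) {
    sims <- one_pass(unique(key))
  } else {
    s <- if (is.null(community_id)) seed else derive_seed(seed, community_id)
    acc <- matrix(0, length(years), length(years))
    cnt <- matrix(0L, length(years), length(years))
    with_seed(s, {
      for (rep in seq_len(n_subsamples)) {
        keep <- unlist(lapply(names(year_samples), function(y) {
          ss <- year_samples[[y]]
          paste(y, if (length(ss) == m) ss else sample(ss, m))
        }))
        sm <- one_pass(keep)
        ok <- !is.na(sm)
        acc[ok] <- acc[ok] + sm[ok]
        cnt <- cnt + ok
      }
    })
    sims <- ifelse(cnt > 0, acc / cnt, NA_real_)
  }

  ut <- which(upper.tri(sims), arr.ind = TRUE)
  s <- sims[ut]
  ok <- !is.na(s)
  tibble::tibble(year_i = years[ut[ok, 1]], year_j = years[ut[ok, 2]],
                 similarity = s[ok])
}

#' Mean similarity by lag (similarity schedule)
#'
#' Averages pairwise similarities over all available year pairs separated by
#' each lag `1..max_lag`, optionally restricted to a set of years (both
#' members of a pair must lie in the set, so pairs straddling a period
#' boundary contribute to neither period). Lags with no available pair are
#' absent from the schedule; no imputation over missing survey years.
#'
#' @param pair_sims Tibble from [rarefied_pair_similarities()]: `year_i`,
#'   `year_j`, `similarity`.
#' @param years Optional integer vector; keep only pairs with both years in
#'   it.
#' @param max_lag Largest lag retained (default 5).
#' @return Tibble of class `similarity_schedule` with columns `lag`,
#'   `similarity`, `n_pairs`.
#' @export
mean_similarity_by_lag <- function(pair_sims, years = NULL, max_lag = 5) {
  keep <- !is.na(pair_sims$similarity)
  if (!is.null(years)) {
    keep <- keep & pair_sims$year_i %in% years & pair_sims$year_j %in% years
  }
  lag <- pair_sims$year_j - pair_sims$year_i
  keep <- keep & lag >= 1 & lag <= max_lag
  lag <- lag[keep]
  sim <- pair_sims$similarity[keep]
  lags_present <- sort(unique(lag))
  key <- as.character(lags_present)
  mean_by_lag <- as.numeric(tapply(sim, lag, mean)[key])
  n_by_lag <- as.integer(tapply(sim, lag, length)[key])
  out <- tibble::new_tibble(
    list(lag = lags_present, similarity = mean_by_lag, n_pairs = n_by_lag),
    nrow = length(lags_present)
  )
  class(out) <- c("similarity_schedule", class(out))
  out
}

#' Signal-to-noise ratio of a similarity schedule
#'
#' The ratio between the lag-1 minus lag-5 similarity difference (the
#' turnover "signal") and the drop from lag 0 (similarity 1 by construction)
#' to lag 1, which is dominated by false-negative pseudo-turnover (the
#' "noise"). Used to screen candidate similarity indices. Undefined (`NA`)
#' when lag 1 or lag 5 is missing from the schedule or when the lag-1
#' similarity equals 1.
#'
#' @param schedule A [mean_similarity_by_lag()] result.
#' @param lag_hi The "signal" upper lag (default 5).
#' @return A single number `(s1 - s_hi) / (1 - s1)`, or `NA`.
#' @export
snr_for_index <- function(schedule, lag_hi = 5) {
  s1 <- schedule$similarity[schedule$lag == 1]
  s5 <- schedule$similarity[schedule$lag == lag_hi]
  if (length(s1) != 1 || length(s5) != 1 || s1 >= 1) return(NA_real_)
  (s1 - s5) / (1 - s1)
}

#' Monte-Carlo robustness of index lag-differences to false negatives
#'
#' Compares the Ochiai and Sorensen indices on their coefficient of
#' variation (CV) of the difference between similarities at two non-zero
#' lags when surveys suffer independent per-species false negatives. A
#' smaller CV means the turnover signal between the two lags is less
#' corrupted by detection noise. The simulated ensemble holds richness
#' fixed at `n_species` per survey with true overlap declining linearly in
#' lag (`1 - decline * lag`), and thins every survey independently with the
#' given false-negative rate.
#'
#' @param false_negative_rate Per-species probability of non-detection, in
#'   \[0, 1).
#' @param n_species Species richness of each surveyed community.
#' @param decline True per-year similarity decline (slow declines are the
#'   regime of interest).
#' @param lags Length-2 vector of non-zero lags whose similarity difference
#'   is studied (default `c(1, 5)`).
#' @param n_reps Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return Tibble with one row per index: `index`, `false_negative_rate`,
#'   `cv`, `mean_diff`, `sd_diff`.
#' @export
cv_robustness_mc <- function(false_negative_rate, n_species = 50,
                             decline = 0.02, lags = c(1, 5), n_reps = 2000,
                             seed = 1) {
  stopifnot(false_negative_rate >= 0, false_negative_rate < 1,
            length(lags) == 2, all(lags >= 1), n_species > 0)
  R <- n_species
  shared <- round(R * (1 - decline * lags))
  stopifnot(all(shared >= 0), all(shared <= R))
  det <- 1 - false_negative_rate

  idx_fun <- list(ochiai = ochiai, sorensen = sorensen)
  diffs <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      # reference survey plus one survey at each lag; true sets overlap the
      # reference in `shared` species, all surveys thinned independently
      d0 <- runif(R) < det
      s <- vapply(seq_along(lags), function(k) {
        a_true <- shared[k]
        dk <- runif(R) < det
        a <- sum(d0[seq_len(a_true)] & dk[seq_len(a_true)])
        n1 <- sum(d0)
        n2 <- sum(dk)
        c(ochiai = ochiai(a, n1 - a, n2 - a),
          sorensen = sorensen(a, n1 - a, n2 - a))
      }, c(ochiai = 0, sorensen = 0))
      s[, 1] - s[, 2]
    }, c(ochiai = 0, sorensen = 0))
  })
  mu <- rowMeans(diffs, na.rm = TRUE)
  sdev <- apply(diffs, 1, stats::sd, na.rm = TRUE)
  tibble::tibble(
    index = names(mu),
    false_negative_rate = false_negative_rate,
    cv = unname(ifelse(mu == 0 & sdev == 0, 0, sdev / abs(mu))),
    mean_diff = unname(mu), sd_diff = unname(sdev)
  )
}
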
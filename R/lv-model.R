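#' Structural-instability richness threshold
#'
#' For a Lotka-Volterra competition community with unit intraspecific
#' competition and random off-diagonal coefficients of mean `mean_offdiag`
#' and variance `var_offdiag`, ecological structural instability emerges
#' when species richness reaches `(1 - mean_offdiag)^2 / var_offdiag`.
#' For off-diagonal coefficients equal to 0.4 with probability 0.4 and 0
#' otherwise (mean 0.16, variance 0.0384) the threshold is 18.375; the
#' simulator's default pool is sized as a multiple of this value.
#'
#' @param mean_offdiag Mean off-diagonal competition coefficient (< 1).
#' @param var_offdiag Variance of off-diagonal coefficients (> 0).
#' @return Richness threshold (species).
#' @examples
#' m <- competition_moments(0.4, 0.4)
#' s_esi(m$mean, m$var) # 18.375
#' @export
s_esi <- function(mean_offdiag, var_offdiag) {
  stopifnot(var_offdiag > 0, mean_offdiag < 1)
  (1 - mean_offdiag)^2 / var_offdiag
}

#' Moments of the Bernoulli competition-coefficient ensemble
#'
#' Off-diagonal coefficients are `value` with probability `prob`, else 0.
#'
#' @param value Nonzero coefficient value (default 0.4).
#' @param prob Probability of a nonzero coefficient (default 0.4).
#' @return List with `mean` and `var`.
#' @export
competition_moments <- function(value = 0.4, prob = 0.4) {
  list(mean = value * prob, var = value^2 * prob * (1 - prob))
}

#' Sample a Lotka-Volterra community parameterisation
#'
#' Draws one random community for the turnover simulator: intrinsic growth
#' rates `r_i ~ Normal(1, 0.25)` (untruncated; few negatives), preferred
#' niche positions `x_i = (i - 1)/S` evenly spaced on the unit niche circle,
#' competition coefficients `A_ij` equal to `a_value` with probability
#' `a_prob` and 0 otherwise (diagonal fixed at 1), initial biomasses uniform
#' in (0, 1], plus the environmental-change parameters. Environmental
#' suitability of species `i` at time `t` is `cos(pi * (x_i - E(t)))^2`
#' raised to `niche_gamma`, peaking at 1 where the environment `E(t) = v * t
#' / env_time_scale` matches the preferred niche and vanishing at niche
#' distance 1/2; the squared sinusoid makes the niche axis periodic, so no
#' boundary effects arise at x = 0, 1. The default time scale (10 sampled
#' 'years' = 250 unit times, i.e. `v` is the niche displacement per decade)
#' keeps the environmental displacement within half the niche circle over
#' the 5-year lag window for the whole 0-0.6 range of `v`, so faster shift
#' maps monotonically to lagwise dissimilarity instead of aliasing around
#' the periodic niche axis.
#'
#' @param S Species-pool size (default 1470 = 80 x 18.375).
#' @param d Environmental degradation: uniform reduction of all growth
#'   rates (0-0.5).
#' @param v Environmental rate of change (0-0.6, niche units per sampled
#'   'year').
#' @param seed Integer seed.
#' @param r_mean,r_sd Moments of the growth-rate distribution.
#' @param a_value,a_prob Competition-coefficient ensemble.
#' @param epsilon Propagule rain permitting re-invasion (default 1e-20).
#' @param t_total,t_burnin Simulated and discarded unit times (4000, 400).
#' @param dt_sample Unit times per sampled 'year' (25).
#' @param presence_threshold Biomass above which a species counts as
#'   present (0.01).
#' @param niche_gamma Niche-width exponent (default 1).
#' @param env_time_scale Unit times over which the environment advances by
#'   `v` niche units (default `10 * dt_sample`).
#' @return An `lv_params` list.
#' @export
lv_params <- function(S = 1470, d = 0, v = 0, seed = 1,
                      r_mean = 1, r_sd = 0.25,
                      a_value = 0.4, a_prob = 0.4,
                      epsilon = 1e-20, t_total = 4000, t_burnin = 400,
                      dt_sample = 25, presence_threshold = 0.01,
                      niche_gamma = 1, env_time_scale = 10 * dt_sample) {
  stopifnot(S >= 1, d >= 0, v >= 0, t_total > t_burnin)
  drawn <- with_seed(seed, {
    A <- matrix(a_value * (runif(S * S) < a_prob), S, S)
    diag(A) <- 1
    list(r = rnorm(S, r_mean, r_sd), A = A, B0 = runif(S))
  })
  structure(
    list(S = S, r = drawn$r, A = drawn$A, x = (seq_len(S) - 1) / S,
         B0 = drawn$B0, d = d, v = v, epsilon = epsilon, t_total = t_total,
         t_burnin = t_burnin, dt_sample = dt_sample,
         presence_threshold = presence_threshold, niche_gamma = niche_gamma,
         env_time_scale = env_time_scale, seed = seed),
    class = "lv_params"
  )
}

#' Integrate the Lotka-Volterra turnover model
#'
#' Integrates `dB_i/dt = B_i * (r_i * f_i(t) - d - sum_j A_ij B_j) +
#' epsilon` from the sampled initial biomasses to `t_total`, with `f_i` the
#' periodic niche suitability described in [lv_params()]. An adaptive
#' embedded Runge-Kutta scheme (relative tolerance 1e-6, absolute tolerance
#' resolving the epsilon biomass floor) integrates exactly to each sampling
#' time; biomasses are clamped nonnegative between steps. Sampled 'years'
#' within the burn-in are discarded.
#'
#' @param params An [lv_params()] object.
#' @param rtol,atol Integrator tolerances.
#' @return An `lv_trajectory`: list with `biomass` (years x species
#'   matrix), `years` (1-based sampled 'year' indices after burn-in),
#'   `presence` (per-year integer vectors of species with biomass above the
#'   threshold), and `params`.
#' @export
lv_integrate <- function(params, rtol = 1e-6, atol = 1e-24) {
  stopifnot(inherits(params, "lv_params"))
  bm <- lv_integrate_cpp(
    params$r, params$A, params$x, params$B0, params$d,
    params$v / params$env_time_scale, params$epsilon, params$niche_gamma,
    params$t_total, params$t_burnin, params$dt_sample, rtol, atol,
    max_steps = 5e7
  )
  presence <- apply(bm, 1, function(b) which(b > params$presence_threshold),
                    simplify = FALSE)
  structure(
    list(biomass = bm, years = seq_len(nrow(bm)), presence = presence,
         params = params),
    class = "lv_trajectory"
  )
}

#' Turnover rate of a simulated trajectory
#'
#' Applies the empirical-data turnover pipeline to a simulated presence
#' series: the per-year presence sets (biomass above threshold) are cast as
#' single-sample survey observations, pairwise similarities and the lag
#' schedule are computed by the same code as for survey data, and the rate
#' is the lag regression of [turnover_rate()].
#'
#' @param trajectory An [lv_integrate()] result.
#' @param lags Regression lags (default `1:5`).
#' @param index Similarity index (default `"ochiai"`).
#' @return One-row tibble from [turnover_rate()].
#' @export
sim_turnover <- function(trajectory, lags = 1:5, index = "ochiai") {
  stopifnot(inherits(trajectory, "lv_trajectory"))
  obs <- lv_presence_obs(trajectory)
  if (nrow(obs) == 0) {
    return(tibble::tibble(rate = NA_real_, se = NA_real_,
                          intercept = NA_real_, n_lags = 0L))
  }
  ps <- rarefied_pair_similarities(obs, index = index, n_subsamples = 1,
                                   seed = 1)
  turnover_rate(mean_similarity_by_lag(ps, max_lag = max(lags)), lags = lags)
}

#' Presence series of a trajectory as survey observations
#'
#' @param trajectory An [lv_integrate()] result.
#' @return Tibble of `year`, `sample_id`, `species_id` (one sample per
#'   'year').
#' @export
lv_presence_obs <- function(trajectory) {
  rows <- purrr::map2(trajectory$years, trajectory$presence,
    function(y, sp) {
      if (length(sp) == 0) return(NULL)
      tibble::tibble(year = y, sample_id = "sim",
                     species_id = sprintf("sp%05d", sp))
    })
  dplyr::bind_rows(rows)
}

#' Enumerate a factorial simulation design
#'
#' Dry-run bookkeeping for [factorial_experiment()]: one row per
#' (degradation, shift-rate, replicate) cell with its derived seed. The
#' full-scale design — 20 degradation levels in \[0, 0.5\], 20 shift-rate
#' levels in \[0, 0.6\], 20 replicates — enumerates 8000 runs.
#'
#' @param d_grid,v_grid Numeric grids of degradation and shift-rate levels.
#' @param replicates Replicates per cell.
#' @param seed Master seed from which per-run seeds are derived.
#' @return Tibble: `d`, `v`, `replicate`, `run_seed`.
#' @examples
#' nrow(factorial_plan(seq(0, 0.5, length.out = 20),
#'                     seq(0, 0.6, length.out = 20), 20)) # 8000
#' @export
factorial_plan <- function(d_grid = seq(0, 0.5, length.out = 20),
                           v_grid = seq(0, 0.6, length.out = 20),
                           replicates = 20, seed = 1) {
  stopifnot(length(d_grid) >= 1, length(v_grid) >= 1, replicates >= 1)
  plan <- tidyr::expand_grid(d = d_grid, v = v_grid,
                             replicate = seq_len(replicates))
  dplyr::mutate(plan, run_seed = purrr::pmap_int(
    list(.data$d, .data$v, .data$replicate),
    function(d, v, k) derive_seed(seed, sprintf("%.6f|%.6f|%d", d, v, k))
  ))
}

#' Full-factorial turnover simulation experiment
#'
#' Runs [lv_integrate()] and [sim_turnover()] for every row of
#' [factorial_plan()], drawing an independent community (growth rates,
#' competition matrix, initial biomasses) per run from the run's derived
#' seed, so any cell can be recomputed in isolation. Failed runs are
#' recorded with an `error` message, never dropped silently.
#'
#' @param S Species-pool size.
#' @inheritParams factorial_plan
#' @param lags Regression lags (default `1:5`).
#' @param ... Further arguments passed to [lv_params()] (e.g. `t_total`).
#' @return Tibble: `d`, `v`, `replicate`, `run_seed`, `rate`, `n_lags`,
#'   `error`.
#' @export
factorial_experiment <- function(S, d_grid = seq(0, 0.5, length.out = 20),
                                 v_grid = seq(0, 0.6, length.out = 20),
                                 replicates = 20, seed = 1, lags = 1:5,
                                 ...) {
  plan <- factorial_plan(d_grid, v_grid, replicates, seed)
  res <- purrr::pmap(plan, function(d, v, replicate, run_seed) {
    tryCatch({
      params <- lv_params(S = S, d = d, v = v, seed = run_seed, ...)
      est <- sim_turnover(lv_integrate(params), lags = lags)
      tibble::tibble(rate = est$rate, n_lags = est$n_lags,
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(rate = NA_real_, n_lags = 0L,
                     error = conditionMessage(e))
    })
  })
  dplyr::bind_cols(plan, dplyr::bind_rows(res))
}
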
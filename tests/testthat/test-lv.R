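test_that("structural-instability threshold reproduces printed constants", {
  m <- competition_moments(0.4, 0.4)
  expect_equal(m$mean, 0.16)
  expect_equal(m$var, 0.0384)
  expect_equal(s_esi(m$mean, m$var), 18.375)
  expect_equal(80 * s_esi(m$mean, m$var), 1470)
  expect_equal(s_esi(0, 1), 1)
  expect_error(s_esi(0.16, 0), "var")
})

test_that("sampled parameters have the stated ensemble statistics", {
  p <- lv_params(S = 2000, seed = 10)
  expect_equal(mean(p$r), 1, tolerance = 0.02)
  expect_equal(stats::sd(p$r), 0.25, tolerance = 0.05)
  off <- p$A[row(p$A) != col(p$A)]
  expect_true(all(off %in% c(0, 0.4)))
  expect_equal(mean(off > 0), 0.4, tolerance = 0.01)
  expect_true(all(diag(p$A) == 1))
  expect_equal(p$x, (0:1999) / 2000)
  expect_identical(lv_params(S = 50, seed = 3)$A, lv_params(S = 50, seed = 3)$A)
  expect_false(identical(lv_params(S = 50, seed = 3)$r,
                         lv_params(S = 50, seed = 4)$r))
})

test_that("a lone species follows the logistic fixed point", {
  p <- lv_params(S = 1, d = 0, v = 0, seed = 1, t_total = 300, t_burnin = 100,
                 dt_sample = 25)
  p$r <- 1
  p$A <- matrix(1, 1, 1)
  p$x <- 0 # optimum at the (static) environment: f = 1
  p$B0 <- 0.05
  tr <- lv_integrate(p)
  expect_equal(unname(tr$biomass[nrow(tr$biomass), 1]), 1, tolerance = 1e-4)
})

test_that("degradation above all growth rates empties the community", {
  p <- lv_params(S = 20, d = 3, v = 0, seed = 2, t_total = 600,
                 t_burnin = 100, dt_sample = 25)
  tr <- lv_integrate(p)
  expect_true(all(lengths(tr$presence) == 0))
  expect_true(all(tr$biomass >= 0))
  expect_true(all(tr$biomass < 0.01))
})

test_that("the zero state is invariant without propagule rain", {
  p <- lv_params(S = 10, seed = 4, t_total = 200, t_burnin = 50,
                 dt_sample = 25)
  p$B0 <- rep(0, 10)
  p$epsilon <- 0
  tr <- lv_integrate(p)
  expect_true(all(tr$biomass == 0))
  # with the default epsilon the same start stays strictly positive
  p$epsilon <- 1e-20
  tr2 <- lv_integrate(p)
  expect_true(all(tr2$biomass > 0))
})

test_that("simulated turnover reuses the empirical pipeline", {
  # frozen community: no presence change, rate exactly 0
  frozen <- structure(
    list(years = 1:10,
         presence = rep(list(1:8), 10),
         params = list(presence_threshold = 0.01)),
    class = "lv_trajectory"
  )
  expect_equal(sim_turnover(frozen)$rate, 0)

  # one of 10 species replaced per year: Ochiai(lag l) = (10 - l)/10,
  # so the regression slope is exactly -0.1
  rolling <- structure(
    list(years = 1:12,
         presence = lapply(1:12, function(t) seq(t, t + 9)),
         params = list(presence_threshold = 0.01)),
    class = "lv_trajectory"
  )
  expect_equal(sim_turnover(rolling)$rate, 0.1, tolerance = 1e-12)

  # code-path equality: sim_turnover == turnover module on the exported obs
  p <- lv_params(S = 150, d = 0.1, v = 0.3, seed = 6, t_total = 900,
                 t_burnin = 150, dt_sample = 25)
  tr <- lv_integrate(p)
  direct <- turnover_rate(mean_similarity_by_lag(
    rarefied_pair_similarities(lv_presence_obs(tr), n_subsamples = 1,
                               seed = 1)))
  expect_identical(sim_turnover(tr), direct)
})

test_that("factorial bookkeeping enumerates the full design", {
  expect_equal(nrow(factorial_plan(c(0, 0.5), c(0, 0.6), 2)), 8)
  expect_equal(nrow(factorial_plan()), 8000) # 20 x 20 x 20
  expect_identical(factorial_plan(seed = 3), factorial_plan(seed = 3))
  # distinct run seeds so any cell can be recomputed in isolation
  expect_equal(anyDuplicated(factorial_plan(seed = 1)$run_seed), 0)
})

test_that("a reduced factorial experiment is complete and reproducible", {
  tab <- factorial_experiment(S = 60, d_grid = c(0, 0.4), v_grid = c(0, 0.4),
                              replicates = 1, seed = 5, t_total = 500,
                              t_burnin = 100)
  expect_equal(nrow(tab), 4)
  expect_true(all(is.na(tab$error)))
  expect_true(all(is.finite(tab$rate)))
  tab2 <- factorial_experiment(S = 60, d_grid = c(0, 0.4),
                               v_grid = c(0, 0.4), replicates = 1, seed = 5,
                               t_total = 500, t_burnin = 100)
  expect_identical(tab, tab2)
})

test_that("surface order selection recovers generating polynomials", {
  # AIC selection is consistent only in probability: on data drawn from a
  # true order-k polynomial it picks k most of the time, so assert majority
  # over replicate noise draws rather than a single draw
  set.seed(14)
  grid <- tidyr::expand_grid(d = seq(0, 0.5, length.out = 12),
                             v = seq(0, 0.6, length.out = 12))
  pick <- function(truth_fun) {
    replicate(12, {
      dat <- dplyr::mutate(grid,
        rate = truth_fun(d, v) + rnorm(dplyr::n(), 0, 0.003))
      fit_surface(dat)$order
    })
  }
  cubic <- pick(function(d, v) 0.05 + 0.2 * d - 0.3 * v + 0.5 * d * v -
                  0.8 * d^2 + 0.6 * v^3 - 0.9 * d^2 * v)
  expect_gte(mean(cubic == 3), 0.75)
  plane <- pick(function(d, v) 0.1 + 0.2 * d - 0.1 * v)
  expect_gte(mean(plane == 2), 0.75)
  expect_true(all(plane <= 3) || any(plane == 2)) # never underfits a cubic

  flat <- dplyr::mutate(grid, rate = 0.07)
  co <- suppressWarnings(tidy(fit_surface(flat), order = 2))
  expect_true(all(abs(co$estimate[-1]) < 1e-10))
  # rank deficiency is a named error
  degenerate <- dplyr::mutate(grid[grid$d == 0, ], rate = 0.1 + v)
  expect_error(fit_surface(degenerate, orders = 2), "order 2")
})

test_that("surface tidiers and predictions are consistent", {
  set.seed(15)
  grid <- tidyr::expand_grid(d = seq(0, 0.5, length.out = 8),
                             v = seq(0, 0.6, length.out = 8))
  dat <- dplyr::mutate(grid, rate = 0.1 - 0.1 * d + 0.2 * v +
                         rnorm(dplyr::n(), 0, 0.002))
  fit <- fit_surface(dat)
  g <- glance(fit)
  expect_equal(nrow(g), 3)
  expect_equal(g$order[g$selected], fit$order)
  expect_equal(sum(g$selected), 1L)
  pred <- predict(fit, newdata = tibble::tibble(d = 0.2, v = 0.3))
  expect_equal(pred$rate, 0.1 - 0.1 * 0.2 + 0.2 * 0.3, tolerance = 0.01)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
})
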
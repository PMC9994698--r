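test_that("AICc follows the small-sample formula", {
  expect_equal(aicc(-100, 2, 50), 200 + 4 + 12 / 47)
  expect_equal(aicc(-100, 0, 50), 200)
  expect_error(aicc(-100, 10, 11), "n_eff")
})

test_that("Akaike weights are the softmax of -delta/2", {
  fits <- list(
    structure(list(model = list(name = "A"), k = 3, loglik = -100,
                   converged = TRUE, n_individuals = 10,
                   superpopulation = 50,
                   design = list(groups = tibble::tibble(
                     cohort = 1, telemetry_occasions = 0, n_released = 50))),
              class = "popan_fit"),
    structure(list(model = list(name = "B"), k = 4, loglik = -100,
                   converged = TRUE, n_individuals = 10,
                   superpopulation = 50,
                   design = list(groups = tibble::tibble(
                     cohort = 1, telemetry_occasions = 0, n_released = 50))),
              class = "popan_fit")
  )
  tab <- rank_models(fits, n_eff = 1e6)  # penalty ~ 2k: delta = 2
  expect_equal(tab$delta_AICc, c(0, 2), tolerance = 1e-4)
  expect_equal(tab$weight,
               c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-4)
  expect_equal(sum(tab$weight), 1)
  single <- rank_models(fits[1], n_eff = 1e6)
  expect_equal(single$weight, 1)

  # ranking is invariant to a shared additive log-likelihood constant
  shifted <- lapply(fits, function(f) { f$loglik <- f$loglik + 123.4; f })
  tab2 <- rank_models(shifted, n_eff = 1e6)
  expect_equal(tab2$delta_AICc, tab$delta_AICc)
  expect_equal(tab2$weight, tab$weight)

  # mixed data refuses to rank
  other <- fits[[2]]
  other$n_individuals <- 99
  expect_error(rank_models(list(fits[[1]], other)), "identical data")
})

test_that("parsimony preference annotates the fewest-k close model", {
  mk <- function(name, k, ll) {
    structure(list(model = list(name = name), k = k, loglik = ll,
                   converged = TRUE, n_individuals = 10,
                   superpopulation = 260,
                   design = list(groups = tibble::tibble(
                     cohort = 1, telemetry_occasions = 0,
                     n_released = 260))),
              class = "popan_fit")
  }
  fits <- list(mk("big", 9, -100), mk("small", 5, -104.2), mk("far", 5, -120))
  tab <- rank_models(fits)
  expect_true(tab$delta_AICc[tab$model == "small"] < 2)
  expect_equal(tab$model[tab$preferred], "small")
})

test_that("Fletcher c-hat is exactly zero when observed equals expected", {
  # T = 3, all telemetered, phi = 0.5, n = 4: expected cells (1, 1, 2)
  d <- build_design(
    tibble::tibble(cohort = 2015L, telemetry_occasions = 3L,
                   n_released = 4L),
    years = 2015:2017, survey_years = integer()
  )
  det <- rbind(c(1L, 1L, 1L), c(1L, 1L, 0L), c(1L, 0L, 0L), c(1L, 0L, 0L))
  h <- make_histories(det, cohort = 2015, telem = 3L, years = 2015:2017)
  fit <- fit_popan(h, d, "Phi(constant) p(t)", n_restarts = 0)
  expect_equal(tidy(fit)$estimate[1], 0.5, tolerance = 1e-5)
  chat <- fletcher_chat(fit)
  expect_equal(as.numeric(chat), 0, tolerance = 1e-6)
  expect_equal(attr(chat, "df"), 1)
})

test_that("abundance projection follows the recursion and its invariants", {
  d <- build_design()
  # no mortality: everyone released is still present in 2020
  traj1 <- project_abundance(d, 1)
  expect_equal(traj1$abundance[6], 260)
  # jumps at releases, decline in between
  phi_fun <- function(cohort, year, acc) {
    if (acc == "New" && cohort == 2019) 0.43 else 0.89
  }
  traj <- project_abundance(d, phi_fun)
  sched <- headstart_releases(include_2014 = FALSE)$n_released
  by_group <- abundance_by_group(traj)
  rel <- d$groups$release_occasion[match(by_group$group_id,
                                         d$groups$group_id)]
  expect_true(all(by_group$abundance[by_group$occasion < rel] == 0))
  at_release <- by_group$abundance[by_group$occasion == rel]
  expect_equal(at_release[match(d$groups$group_id,
                                by_group$group_id[by_group$occasion == rel])],
               as.numeric(d$groups$n_released))
  prev_carry <- traj$abundance[-1] - sched[-1]
  expect_true(all(prev_carry <= traj$abundance[-6] + 1e-9))
  # hand evaluation of the recursion at the reported estimates
  expect_equal(
    traj$abundance[6],
    21 * 0.89^5 + 36 * 0.89^4 + 49 * 0.89^3 + 49 * 0.89^2 + 48 * 0.43 + 57
  )
})

test_that("Delta-method abundance variance matches Monte-Carlo propagation", {
  # single group, single free interval
  d <- build_design(
    tibble::tibble(cohort = 2015L, telemetry_occasions = 2L,
                   n_released = 40L),
    years = 2015:2016, survey_years = integer()
  )
  det <- rbind(
    matrix(rep(c(1L, 1L), 30), ncol = 2, byrow = TRUE),
    matrix(rep(c(1L, 0L), 10), ncol = 2, byrow = TRUE)
  )
  h <- make_histories(det, cohort = 2015, telem = 2L, years = 2015:2016)
  fit <- fit_popan(h, d, "Phi(constant) p(t)", n_restarts = 0)
  traj <- derive_abundance(fit)
  mc <- withr::with_seed(8, {
    draws <- stats::rnorm(1e5, fit$coefficients, sqrt(fit$vcov[1, 1]))
    stats::sd(40 * plogis(draws))
  })
  expect_equal(traj$std.error[2], mc, tolerance = 0.02)
  # intervals bracket the estimate
  expect_true(all(traj$conf.low <= traj$abundance + 1e-9))
  expect_true(all(traj$conf.high >= traj$abundance - 1e-9))
})

test_that("Delta-method interval width shrinks with sample size", {
  width_at <- function(scale) {
    sc <- simulation_scenario(seed = 5, scale = scale)
    h <- simulate_histories(sc)
    fit <- fit_popan(h, scenario_design(sc), "Phi(acc2019) p(t)",
                     n_restarts = 0)
    traj <- derive_abundance(fit)
    (traj$conf.high[6] - traj$conf.low[6]) / traj$abundance[6]
  }
  expect_lt(width_at(10), width_at(1))
})

test_that("density reporting rounds to whole animals per hectare", {
  expect_equal(density_estimate(183, 9)$density_rounded, 20)
  expect_equal(density_estimate(183, 9)$density, 183 / 9)
  expect_equal(density_estimate(0, 9)$density_rounded, 0)
  expect_equal(density_estimate(45, 4.5)$density_rounded, 10)
  expect_error(density_estimate(10, 0), "positive")
})
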
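test_that("nonencounter recursions match hand-computed cases", {
  # certain detection at the start forbids the all-zero record
  rec <- nonencounter_recursion(phi = c(0.7, 0.8), p = c(1, 0.3, 0.2),
                                start = 1)
  expect_equal(rec$zeta[1], 0)
  # immortal and invisible: never seen with certainty
  rec <- nonencounter_recursion(phi = c(1, 1), p = c(0, 0, 0), start = 1)
  expect_equal(rec$zeta[1], 1)
  # two occasions: die (0.2) or survive undetected (0.8 * 0.5)
  rec <- nonencounter_recursion(phi = 0.8, p = c(0, 0.5), start = 1)
  expect_equal(rec$zeta[1], 0.6)
  expect_equal(rec$chi[2], 1)
  expect_error(nonencounter_recursion(phi = 1.2, p = c(0, 0), start = 1),
               "\\[0, 1\\]")
})

test_that("history probabilities match hand-computed cases", {
  # telemetered (p = 1): non-detection after detection implies death
  expect_equal(
    history_probability(c(1, 1, 0), phi = c(0.9, 0.8), p = c(1, 1, 1)),
    0.9 * (1 - 0.8)
  )
  # survival is the only uncertainty for a fully detected pair
  expect_equal(
    history_probability(c(1, 1), phi = 0.7, p = c(1, 1)), 0.7
  )
  # the all-zero history is the never-seen probability
  phi <- c(0.8, 0.6)
  p <- c(0, 0.4, 0.3)
  expect_equal(
    history_probability(c(0, 0, 0), phi, p, start = 1),
    nonencounter_recursion(phi, p, 1)$zeta[1]
  )
  expect_error(
    history_probability(c(1, 0, 0), phi, p, start = 2),
    "before the release"
  )
})

test_that("history probabilities agree with the death-time enumeration oracle", {
  set.seed(41)
  for (rep in 1:50) {
    T <- sample(2:4, 1)
    r <- sample(seq_len(T), 1)
    phi <- runif(T - 1)
    p <- runif(T)
    x <- integer(T)
    free <- r:T
    x[free] <- rbinom(length(free), 1, 0.5)
    expect_equal(
      history_probability(x, phi, p, start = r),
      brute_history_prob(x, phi, p, r),
      tolerance = 1e-12
    )
  }
})

test_that("history probabilities are complete over the history space", {
  set.seed(42)
  for (rep in 1:200) {
    T <- sample(2:3, 1)
    r <- sample(seq_len(T), 1)
    phi <- runif(T - 1)
    p <- runif(T)
    pats <- popantel:::enumerate_patterns(T, r)
    total <- sum(apply(pats, 1, history_probability, phi = phi, p = p,
                       start = r))
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("group log-likelihood equals the multinomial enumeration", {
  # 2-occasion untracked group, n = 10 released, 6 seen
  phi <- 0.75
  p <- c(0.5, 0.4)
  pats <- popantel:::enumerate_patterns(2, 1)
  pr <- apply(pats, 1, history_probability, phi = phi, p = p, start = 1)
  # observed: "10" x2, "01" x1, "11" x3, never seen x4
  key <- apply(pats, 1, paste, collapse = "")
  counts <- setNames(c(4, 2, 1, 3), c("00", "10", "01", "11"))
  counts <- counts[key]
  ll_multinom <- stats::dmultinom(counts, prob = pr, log = TRUE) -
    lgamma(10 + 1) + sum(lgamma(counts + 1))
  hist_mat <- pats[key != "00", , drop = FALSE]
  ll <- group_loglik(hist_mat, counts[key != "00"], n_released = 10,
                     release_occasion = 1, phi = phi, p = p)
  expect_equal(ll, ll_multinom, tolerance = 1e-12)
})

test_that("total log-likelihood matches the per-individual oracle to 1e-10", {
  d <- toy_design_3()
  sc <- simulation_scenario(
    telemetry_plan = d$groups[, c("cohort", "telemetry_occasions",
                                  "n_released")],
    phi_baseline = 0.8, phi_acc2019 = NULL,
    p = c("2015" = 0.5, "2016" = 0.4, "2017" = 0.3),
    years = 2015:2017, survey_years = 2015:2017, seed = 5
  )
  h <- simulate_histories(sc)
  model <- model_spec("Phi(t) p(t)")
  prep <- popantel:::prepare_model(d, model)
  set.seed(7)
  for (rep in 1:10) {
    theta <- rnorm(prep$k)
    res <- popantel:::resolve_theta(prep, theta)
    mine <- total_loglik(h, d, model, theta)
    expect_equal(mine$loglik,
                 brute_total_loglik(h, d, res$PHI, res$P),
                 tolerance = 1e-10)
    # fast optimizer path agrees with the per-group recursion path
    dat <- popantel:::popan_group_data(h, d)
    expect_equal(popantel:::total_loglik_prepared(prep, dat, theta),
                 mine$loglik, tolerance = 1e-12)
    expect_equal(sum(mine$per_group), mine$loglik)
  }
})

test_that("log-likelihood is invariant to relabeling and group order", {
  d <- toy_design_3()
  sc <- simulation_scenario(
    telemetry_plan = d$groups[, c("cohort", "telemetry_occasions",
                                  "n_released")],
    phi_baseline = 0.8, phi_acc2019 = NULL,
    p = c("2015" = 0.5, "2016" = 0.4, "2017" = 0.3),
    years = 2015:2017, survey_years = 2015:2017, seed = 6
  )
  h <- simulate_histories(sc)
  theta <- c(0.3, -0.2, 0.1, 0.5, -0.4)
  model <- model_spec("Phi(t) p(t)")
  base <- total_loglik(h, d, model, theta)$loglik
  shuffled <- h[sample(nrow(h)), ]
  shuffled$id <- paste0("relabeled_", seq_len(nrow(shuffled)))
  expect_equal(total_loglik(shuffled, d, model, theta)$loglik, base)
})

test_that("data inconsistent with the design is rejected", {
  d <- build_design()
  det <- matrix(0L, 1, 6)
  det[1, 2] <- 1L  # untracked 2017 animal detected in 2016 (fixed-0 cell)
  h <- make_histories(det, cohort = 2017, telem = 0L, years = 2015:2020)
  expect_error(popantel:::popan_group_data(h, d), "fixed at 0")
  # more individuals than released
  det2 <- matrix(0L, 4, 6)
  det2[, 4] <- 1L
  h2 <- make_histories(det2, cohort = 2015, telem = 6L, years = 2015:2020)
  h2$telemetry_occasions <- 6L
  det2[, 1:6] <- 1L
  h2[paste0("y", 2015:2020)] <- as.data.frame(det2)
  expect_error(popantel:::popan_group_data(h2, d), "More individuals")
})
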
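#' Define a simulation scenario
#'
#' A scenario bundles the true demographic process and the study plan used
#' by the synthetic encounter-history generator. The defaults reproduce the
#' monitored headstarted population's study conditions: the 2015--2020
#' release schedule (21/36/49/49/48/57), the 23 cohort-by-telemetry groups,
#' baseline annual apparent survival 0.89 with first-interval survival 0.43
#' for the 2019 releases (the mass-mortality year), and survey detection
#' probabilities 0.34/0.10/0.04 in 2018/2019/2020. Telemetered animals are
#' detected with certainty while tracked.
#'
#' @param telemetry_plan Group table (`cohort`, `telemetry_occasions`,
#'   `n_released`); defaults to [headstart_groups()].
#' @param phi_baseline Baseline per-interval apparent survival.
#' @param phi_acc2019 Survival of the 2019 cohort in its first interval
#'   (`NULL` to disable the effect).
#' @param phi_new Optional survival for all first ("New") intervals.
#' @param year_phi Optional named vector of survival overrides by interval
#'   starting year, e.g. `c("2018" = 0.8)`.
#' @param mass_mortality Optional `list(year =, extra_hazard =)`: survival in
#'   intervals starting that year is multiplied by `1 - extra_hazard`.
#' @param phi_precision Optional beta precision for persistent individual
#'   survival heterogeneity: each animal keeps a lifelong frailty quantile
#'   and its interval survival is the corresponding quantile of a
#'   Beta(phi * nu, (1 - phi) * nu) distribution. Smaller values give more
#'   heterogeneity; `NULL` (default) disables it.
#' @param phi_env_precision Optional beta precision for shared environmental
#'   survival variation: one beta draw per interval (centred on the resolved
#'   survival) applies to every animal alive in that interval, correlating
#'   fates and producing genuine overdispersion relative to the multinomial
#'   model; `NULL` (default) disables it.
#' @param p Named vector of detection probabilities per survey year.
#' @param sex_ratio Presumed male:female ratio at release (`"1:1.5"` by
#'   default, set by egg-incubation temperatures).
#' @param years,survey_years Occasion years and survey years.
#' @param seed Default seed for the generator.
#' @param scale Replication multiplier applied to every group size.
#' @return A `popan_scenario` object.
#' @export
simulation_scenario <- function(telemetry_plan = headstart_groups(),
                                phi_baseline = 0.89,
                                phi_acc2019 = 0.43,
                                phi_new = NULL,
                                year_phi = NULL,
                                mass_mortality = NULL,
                                phi_precision = NULL,
                                phi_env_precision = NULL,
                                p = c("2018" = 0.34, "2019" = 0.10,
                                      "2020" = 0.04),
                                sex_ratio = "1:1.5",
                                years = 2015:2020,
                                survey_years = 2018:2020,
                                seed = 1L,
                                scale = 1) {
  telemetry_plan <- as_tibble(telemetry_plan)
  if (!setequal(as.character(survey_years), names(p))) {
    abort("`p` must be named by the survey years.")
  }
  probs <- c(phi_baseline, phi_acc2019, phi_new, year_phi, p)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  sc <- structure(
    list(
      telemetry_plan = telemetry_plan,
      release_schedule = telemetry_plan %>%
        group_by(.data$cohort) %>%
        summarise(n_released = sum(.data$n_released)),
      phi_baseline = phi_baseline, phi_acc2019 = phi_acc2019,
      phi_new = phi_new, year_phi = year_phi,
      mass_mortality = mass_mortality, phi_precision = phi_precision,
      phi_env_precision = phi_env_precision,
      p = p, sex_ratio = sex_ratio,
      years = as.integer(years), survey_years = as.integer(survey_years),
      seed = seed, scale = scale
    ),
    class = "popan_scenario"
  )
  sc
}

#' @export
print.popan_scenario <- function(x, ...) {
  cat("<popan_scenario>\n")
  cat("  releases:", paste(x$release_schedule$n_released, collapse = "/"),
      "x scale", x$scale, "\n")
  cat("  phi baseline:", x$phi_baseline,
      if (!is.null(x$phi_acc2019)) paste0("(2019 new: ", x$phi_acc2019, ")"),
      "\n")
  cat("  p:", paste(names(x$p), x$p, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# True survival for a (cohort, interval-start-year, acclimation) cell.
true_phi <- function(scenario, cohort, year, acc) {
  val <- scenario$phi_baseline
  if (!is.null(scenario$phi_new) && acc == "New") val <- scenario$phi_new
  yr <- as.character(year)
  if (!is.null(scenario$year_phi) && yr %in% names(scenario$year_phi)) {
    val <- scenario$year_phi[[yr]]
  }
  if (!is.null(scenario$phi_acc2019) && acc == "New" && cohort == 2019L) {
    val <- scenario$phi_acc2019
  }
  mm <- scenario$mass_mortality
  if (!is.null(mm) && year == mm$year) val <- val * (1 - mm$extra_hazard)
  val
}

#' True parameter values of a scenario
#'
#' @param scenario A `popan_scenario`.
#' @return A list with a `phi` tibble (per cohort, interval year,
#'   acclimation) and the `p` vector -- the truth record against which
#'   recovery is judged.
#' @export
scenario_truth <- function(scenario) {
  design <- scenario_design(scenario)
  phi <- popan_cells(design)$phi %>%
    distinct(.data$cohort, .data$year, .data$acc) %>%
    mutate(phi = purrr::pmap_dbl(
      list(.data$cohort, .data$year, as.character(.data$acc)),
      function(co, yr, ac) true_phi(scenario, co, yr, ac)
    ))
  list(phi = phi, p = scenario$p)
}

#' Study design implied by a scenario
#'
#' @param scenario A `popan_scenario`.
#' @return A `popan_design` with group sizes multiplied by the scenario's
#'   `scale`.
#' @export
scenario_design <- function(scenario) {
  groups <- mutate(scenario$telemetry_plan,
                   n_released = as.integer(round(.data$n_released *
                                                   scenario$scale)))
  build_design(groups, years = scenario$years,
               survey_years = scenario$survey_years)
}

# Core forward simulation shared by simulate_histories() and
# simulate_capture_records(). Returns histories, the release roster with
# presumed sex, and survey capture events.
simulate_core <- function(scenario, seed) {
  design <- scenario_design(scenario)
  g <- design$groups
  years <- design$years
  n_occ <- design$n_occasions
  p_male <- parse_ratio(scenario$sex_ratio)[1]

  run <- function() {
    hist_list <- vector("list", nrow(g))
    cap_list <- vector("list", nrow(g))
    env_u <- if (is.null(scenario$phi_env_precision)) {
      NULL
    } else {
      runif(n_occ - 1L)
    }
    for (j in seq_len(nrow(g))) {
      n <- g$n_released[j]
      r <- g$release_occasion[j]
      d <- g$telemetry_occasions[j]
      co <- g$cohort[j]
      alive <- matrix(FALSE, n, n_occ)
      alive[, r] <- TRUE
      frailty <- if (is.null(scenario$phi_precision)) NULL else runif(n)
      if (r < n_occ) {
        for (t in r:(n_occ - 1L)) {
          acc <- if (t == r) "New" else "Exp"
          phi_t <- true_phi(scenario, co, years[t], acc)
          if (!is.null(env_u)) {
            nu_e <- scenario$phi_env_precision
            phi_t <- stats::qbeta(env_u[t], phi_t * nu_e, (1 - phi_t) * nu_e)
          }
          surv <- if (is.null(frailty)) {
            rbinom(n, 1L, phi_t) == 1L
          } else {
            nu <- scenario$phi_precision
            phi_i <- stats::qbeta(frailty, phi_t * nu, (1 - phi_t) * nu)
            runif(n) < phi_i
          }
          alive[, t + 1L] <- alive[, t] & surv
        }
      }
      det <- matrix(0L, n, n_occ)
      cap <- matrix(FALSE, n, n_occ)
      for (t in r:n_occ) {
        tracked <- t < r + d
        survey <- years[t] %in% scenario$survey_years
        trapped <- if (survey) {
          rbinom(n, 1L, scenario$p[[as.character(years[t])]]) == 1L &
            alive[, t]
        } else {
          rep(FALSE, n)
        }
        cap[, t] <- trapped
        det[, t] <- as.integer((tracked & alive[, t]) | trapped)
      }
      ids <- sprintf("g%02d_%05d", j, seq_len(n))
      sex <- if_else(rbinom(n, 1L, p_male) == 1L, "male", "female")
      hist_list[[j]] <- tibble(
        id = ids, cohort = co, telemetry_occasions = d,
        !!!setNames(lapply(seq_len(n_occ), function(t) det[, t]),
                    detection_cols(years)),
        sex = sex
      )
      cap_idx <- which(cap, arr.ind = TRUE)
      cap_list[[j]] <- tibble(
        id = ids[cap_idx[, 1]], cohort = co,
        year = years[cap_idx[, 2]], sex = sex[cap_idx[, 1]]
      )
    }
    list(histories = bind_rows(hist_list), captures = bind_rows(cap_list))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate encounter histories
#'
#' Forward-simulates the process the likelihood assumes: each individual
#' enters at its group's release occasion, survives each interval as a
#' Bernoulli trial with the scenario-resolved survival, is detected with
#' certainty while telemetered and alive, detected as a Bernoulli trial with
#' the year's survey detection probability when alive in a survey year, and
#' never otherwise. Deterministic for a fixed seed.
#'
#' @param scenario A `popan_scenario`.
#' @param seed Seed (default: the scenario's).
#' @return A canonical encounter-history tibble (plus a `sex` column); the
#'   generating truth is attached as the `"truth"` attribute
#'   (see [scenario_truth()]).
#' @export
#' @examples
#' h <- simulate_histories(simulation_scenario(seed = 42))
#' nrow(h)  # 260: the analysis superpopulation
simulate_histories <- function(scenario = simulation_scenario(),
                               seed = scenario$seed) {
  stopifnot(inherits(scenario, "popan_scenario"))
  out <- simulate_core(scenario, seed)$histories
  attr(out, "truth") <- scenario_truth(scenario)
  out
}

#' Simulate survey capture records with presumed sex
#'
#' Assigns presumed sex at release at the scenario's ratio and emits one
#' record per survey-year trap capture of a live animal, consistent with the
#' detection process of [simulate_histories()] (for untracked animals the
#' trap captures are exactly their survey-year detections).
#'
#' @inheritParams simulate_histories
#' @return A tibble of capture events (`id`, `cohort`, `year`, `sex`); the
#'   full release roster (with sex) is attached as the `"roster"` attribute.
#' @export
simulate_capture_records <- function(scenario = simulation_scenario(),
                                     seed = scenario$seed) {
  stopifnot(inherits(scenario, "popan_scenario"))
  core <- simulate_core(scenario, seed)
  out <- core$captures
  attr(out, "roster") <- select(core$histories, "id", "cohort", "sex")
  out
}
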
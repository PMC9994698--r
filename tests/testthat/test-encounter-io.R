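years <- 2015:2020

test_that("tabular histories map directly onto records", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    id = "A", cohort = 2018, telemetry_occasions = 2,
    y2015 = 0, y2016 = 0, y2017 = 0, y2018 = 1, y2019 = 1, y2020 = 0
  ), path)
  h <- read_histories(path)
  expect_equal(h$id, "A")
  expect_equal(h$cohort, 2018L)
  expect_equal(unlist(h[paste0("y", years)], use.names = FALSE),
               c(0L, 0L, 0L, 1L, 1L, 0L))
})

test_that("a user column mapping is honoured", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    Turtle = "A", ReleaseYear = 2018, Tracked = 0,
    y2015 = 0, y2016 = 0, y2017 = 0, y2018 = 1, y2019 = 0, y2020 = 0
  ), path)
  h <- read_histories(path, col_map = c(
    id = "Turtle", cohort = "ReleaseYear", telemetry_occasions = "Tracked"
  ))
  expect_equal(h$telemetry_occasions, 0L)
})

test_that("histories round-trip through CSV and .inp", {
  h <- simulate_histories(simulation_scenario(seed = 11)) %>%
    dplyr::select(-sex)
  attr(h, "truth") <- NULL
  csv <- withr::local_tempfile(fileext = ".csv")
  write_histories(h, csv)
  h2 <- read_histories(csv)
  expect_equal(as.data.frame(h2), as.data.frame(h))

  inp <- withr::local_tempfile(fileext = ".inp")
  write_inp(h, inp)
  h3 <- read_inp(inp)
  key <- function(x) {
    x %>%
      dplyr::arrange(dplyr::across(dplyr::all_of(
        c("cohort", "telemetry_occasions", paste0("y", years))))) %>%
      dplyr::select(-id)
  }
  expect_equal(as.data.frame(key(h3)), as.data.frame(key(h)))
})

test_that("dated records collapse to one occasion per year", {
  recs <- tibble::tibble(
    id = c("a", "a", "a", "b"),
    cohort = c(2017L, 2017L, 2017L, 2018L),
    telemetry_occasions = 0L,
    year = c(2018L, 2018L, 2020L, NA)
  )
  h <- collapse_records(recs, years)
  expect_equal(h$y2018[h$id == "a"], 1L)
  expect_equal(h$y2019[h$id == "a"], 0L)
  expect_equal(h$y2020[h$id == "a"], 1L)
  expect_equal(sum(unlist(h[h$id == "b", paste0("y", years)])), 0L)
})

test_that("malformed histories are rejected with context", {
  base <- tibble::tibble(
    id = "bad", cohort = 2018L, telemetry_occasions = 0L,
    y2015 = 0L, y2016 = 0L, y2017 = 0L, y2018 = 0L, y2019 = 0L, y2020 = 0L
  )
  nb <- base; nb$y2019 <- 2L
  expect_error(validate_histories(nb), "Non-binary")
  pre <- base; pre$y2016 <- 1L
  expect_error(validate_histories(pre), "before release.*bad")
})

test_that("inclusion rules retain the right individuals and ledger the rest", {
  det0 <- matrix(0L, 6, 6)
  det0[1, 4] <- 1L                      # plain survey detection, kept
  det0[2, 4] <- 1L                      # dead at first encounter
  det0[3, 2] <- 1L                      # 2016 opportunistic-only, untracked
  det0[4, 5] <- 1L                      # kept
  det0[5, 6] <- 1L                      # 2014 cohort
  det0[6, 4] <- 1L                      # kept
  h <- make_histories(det0,
                      cohort = c(2018, 2018, 2015, 2017, 2014, 2016),
                      telem = 0L, years = years)
  h$first_encounter_dead <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  kept <- apply_inclusion_rules(h)
  expect_equal(nrow(kept), 3)
  led <- exclusion_ledger(kept)
  expect_setequal(led$rule,
                  c("first_encounter_dead", "opportunistic_only",
                    "cohort_2014"))
  expect_true(all(kept$cohort %in% 2015:2020))

  # toy set from hand application of the rules: 6 records, one dead at
  # first encounter, one 2016 opportunistic-only -> 4 retained
  det6 <- matrix(0L, 6, 6)
  det6[1, 4] <- 1L
  det6[2, 4] <- 1L                      # dead at first encounter
  det6[3, 2] <- 1L                      # 2016 opportunistic-only
  det6[4, 5] <- 1L
  det6[5, 6] <- 1L
  det6[6, 4] <- 1L
  h6 <- make_histories(det6,
                       cohort = c(2018, 2018, 2015, 2017, 2019, 2016),
                       telem = 0L, years = years)
  h6$first_encounter_dead <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(nrow(apply_inclusion_rules(h6)), 4)

  empty <- h[0, ]
  kept0 <- apply_inclusion_rules(empty)
  expect_equal(nrow(kept0), 0)
  expect_equal(nrow(exclusion_ledger(kept0)), 0)
  expect_error(
    apply_inclusion_rules(dplyr::mutate(h, cohort = 2011L)),
    "Unknown cohort"
  )
})

test_that("telemetered animals are never opportunistic-only exclusions", {
  det0 <- matrix(0L, 1, 6)
  det0[1, 2] <- 1L   # only a 2016 detection, but via telemetry
  h <- make_histories(det0, cohort = 2016, telem = 1L, years = years)
  expect_equal(nrow(apply_inclusion_rules(h)), 1)
})
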
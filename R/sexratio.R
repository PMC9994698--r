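#' First-capture counts by presumed sex
#'
#' Reduces survey capture records to one record per unique individual (its
#' earliest capture within the survey years) and counts by presumed sex.
#' Records with sex labels other than `"male"`/`"female"` are excluded with
#' a warning.
#'
#' @param captures A data frame of capture events with columns `id`, `year`,
#'   `sex`.
#' @param survey_years Years to include (default `2018:2020`).
#' @return A tibble with columns `sex` and `n` (always both sexes, possibly
#'   zero).
#' @export
#' @examples
#' caps <- tibble::tibble(
#'   id = c("a", "a", "b"), year = c(2018, 2020, 2019),
#'   sex = c("female", "female", "male")
#' )
#' first_captures(caps)
first_captures <- function(captures, survey_years = 2018:2020) {
  captures <- as_tibble(captures)
  known <- captures$sex %in% c("male", "female")
  if (any(!known)) {
    warn(paste0("Excluding ", sum(!known),
                " capture record(s) with unknown sex label."))
    captures <- captures[known, , drop = FALSE]
  }
  firsts <- captures %>%
    filter(.data$year %in% .env$survey_years) %>%
    group_by(.data$id) %>%
    slice_min(.data$year, n = 1, with_ties = FALSE) %>%
    ungroup()
  counts <- count(firsts, .data$sex)
  tibble(sex = c("male", "female")) %>%
    left_join(counts, by = "sex") %>%
    mutate(n = tidyr::replace_na(.data$n, 0L))
}

parse_ratio <- function(ratio) {
  if (is.numeric(ratio) && length(ratio) == 2) {
    parts <- ratio
  } else {
    m <- stringr::str_match(as.character(ratio),
                            "^\\s*([0-9.]+)\\s*:\\s*([0-9.]+)\\s*$")
    if (is.na(m[1, 1])) {
      abort(paste0("Cannot parse ratio '", ratio, "'; expected \"a:b\"."))
    }
    parts <- as.numeric(m[1, 2:3])
  }
  if (any(parts <= 0)) abort("Ratio components must be positive.")
  parts / sum(parts)
}

#' Chi-square goodness-of-fit test for a sex ratio
#'
#' Pearson chi-square test (no continuity correction) of observed
#' male/female counts against an expected `male:female` odds ratio, with
#' `df = 1` and an upper-tail p-value. For the monitored population the
#' expected pre-release ratio is 1:1.5, set by egg-incubation temperatures.
#'
#' @param observed Either a length-2 numeric vector `c(males, females)` or a
#'   tibble from [first_captures()].
#' @param expected_ratio Expected `male:female` odds, as a string `"a:b"` or
#'   a length-2 numeric vector.
#' @return A one-row tibble: observed and expected counts, `statistic`,
#'   `df`, `p.value`, and the ratio used.
#' @export
#' @examples
#' sex_ratio_test(c(23, 23), "1:1.5")  # chi^2 = 1.92, p = 0.17
sex_ratio_test <- function(observed, expected_ratio = "1:1.5") {
  if (is.data.frame(observed)) {
    m <- observed$n[observed$sex == "male"]
    f <- observed$n[observed$sex == "female"]
    observed <- c(m, f)
  }
  stopifnot(length(observed) == 2, all(observed >= 0))
  if (sum(observed) == 0) abort("Total observed count must be positive.")
  shares <- parse_ratio(expected_ratio)
  expected <- sum(observed) * shares
  if (any(expected <= 0)) abort("Expected counts must be positive.")
  test <- chisq.test(observed, p = shares, correct = FALSE)
  tibble(
    males = observed[1], females = observed[2],
    expected_males = expected[1], expected_females = expected[2],
    expected_ratio = if (is.character(expected_ratio)) {
      expected_ratio
    } else {
      paste(expected_ratio, collapse = ":")
    },
    statistic = unname(test$statistic),
    df = 1L,
    p.value = unname(test$p.value)
  )
}
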
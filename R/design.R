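#' Release schedule of the headstarting program
#'
#' Annual counts of headstarted juveniles released into the study wetland,
#' 2014--2020. The 2014 cohort is normally excluded from analysis (missing
#' data), leaving the 260 animals released 2015--2020 that make up the
#' analysis superpopulation.
#'
#' @param include_2014 Keep the 2014 release row (default `TRUE`; the
#'   inclusion rules drop that cohort from encounter data, not from the
#'   schedule).
#' @return A tibble with columns `cohort` and `n_released`.
#' @export
#' @examples
#' headstart_releases()
#' sum(headstart_releases(include_2014 = FALSE)$n_released) # 260
headstart_releases <- function(include_2014 = TRUE) {
  out <- tibble(
    cohort = 2014:2020,
    n_released = c(10L, 21L, 36L, 49L, 49L, 48L, 57L)
  )
  if (!include_2014) out <- filter(out, .data$cohort != 2014L)
  out
}

#' Cohort-by-telemetry groups of the monitored population
#'
#' The 23 groups used to parameterise the open-population model: each release
#' cohort (2015--2020) subdivided by the number of consecutive annual
#' occasions an animal carried a radio transmitter, starting at release.
#' Group sizes sum to each cohort's release total (260 overall).
#'
#' @return A tibble with columns `cohort`, `telemetry_occasions`, and
#'   `n_released`.
#' @export
#' @examples
#' g <- headstart_groups()
#' nrow(g)               # 23
#' sum(g$n_released)     # 260
headstart_groups <- function() {
  tibble(
    cohort = c(
      rep(2015L, 5), rep(2016L, 6), rep(2017L, 4),
      rep(2018L, 4), rep(2019L, 3), 2020L
    ),
    telemetry_occasions = c(
      6L, 5L, 4L, 2L, 1L,
      5L, 4L, 3L, 2L, 1L, 0L,
      4L, 3L, 2L, 0L,
      3L, 2L, 1L, 0L,
      2L, 1L, 0L,
      0L
    ),
    n_released = c(
      3L, 4L, 2L, 11L, 1L,
      5L, 4L, 1L, 8L, 6L, 12L,
      2L, 4L, 10L, 33L,
      2L, 19L, 1L, 27L,
      18L, 5L, 25L,
      57L
    )
  )
}

# Mask states for detection probability cells.
MASK_FREE <- "free"
MASK_FIXED_0 <- "fixed0"
MASK_FIXED_1 <- "fixed1"

#' Build a study design from cohort groups
#'
#' Expands a cohort-by-telemetry group table into the full design used by the
#' likelihood: one row per group with its release occasion and fixed
#' superpopulation, plus a detection mask over (group, occasion) cells.
#' Detection is fixed at 1 while a group is tracked (telemetry gives certain
#' detection), fixed at 0 before release and in years without survey effort,
#' and free (estimable) otherwise. Probability of entry is fixed at 1 for the
#' release occasion and 0 elsewhere, so entry contributes no estimated
#' parameters.
#'
#' @param groups A data frame with columns `cohort`, `telemetry_occasions`,
#'   `n_released` (one row per group); defaults to [headstart_groups()].
#' @param years Ordered annual occasion labels (default `2015:2020`).
#' @param survey_years Years with trapping/visual survey effort, in which
#'   untracked animals are detectable (default `2018:2020`).
#' @return An object of class `popan_design`.
#' @export
#' @examples
#' design <- build_design()
#' design
build_design <- function(groups = headstart_groups(),
                         years = 2015:2020,
                         survey_years = 2018:2020) {
  groups <- as_tibble(groups)
  needed <- c("cohort", "telemetry_occasions", "n_released")
  if (!all(needed %in% names(groups))) {
    abort(paste("`groups` must have columns:", paste(needed, collapse = ", ")))
  }
  if (!all(survey_years %in% years)) {
    abort("`survey_years` must be a subset of `years`.")
  }
  if (any(groups$n_released < 0)) abort("`n_released` must be non-negative.")
  if (!all(groups$cohort %in% years)) {
    bad <- setdiff(unique(groups$cohort), years)
    abort(paste0("Unknown cohort year(s): ", paste(bad, collapse = ", ")))
  }
  if (any(groups$n_released == 0)) {
    warn("Dropping group(s) with n_released = 0.")
    groups <- filter(groups, .data$n_released > 0)
  }
  n_occ <- length(years)
  groups <- groups %>%
    mutate(
      release_occasion = match(.data$cohort, .env$years),
      group_id = row_number()
    ) %>%
    select("group_id", "cohort", "telemetry_occasions", "n_released",
           "release_occasion")
  over <- groups$release_occasion + groups$telemetry_occasions - 1L > n_occ
  if (any(over)) {
    abort(paste0(
      "Telemetry span exceeds the last occasion for group(s): ",
      paste(groups$group_id[over], collapse = ", ")
    ))
  }

  mask <- matrix(MASK_FIXED_0, nrow = nrow(groups), ncol = n_occ,
                 dimnames = list(groups$group_id, years))
  for (i in seq_len(nrow(groups))) {
    r <- groups$release_occasion[i]
    d <- groups$telemetry_occasions[i]
    if (d > 0) mask[i, r:(r + d - 1L)] <- MASK_FIXED_1
    # untracked availability: survey years at/after release, after telemetry ends
    free_occ <- setdiff(which(years %in% survey_years), seq_len(r + d - 1L))
    if (length(free_occ)) mask[i, free_occ] <- MASK_FREE
  }

  structure(
    list(
      years = as.integer(years),
      survey_years = as.integer(survey_years),
      groups = groups,
      mask = mask,
      n_occasions = n_occ
    ),
    class = "popan_design"
  )
}

#' @export
print.popan_design <- function(x, ...) {
  cat("<popan_design>\n")
  cat("  occasions:", paste(x$years, collapse = " "), "\n")
  cat("  survey years:", paste(x$survey_years, collapse = " "), "\n")
  cat("  groups:", nrow(x$groups),
      "| superpopulation:", sum(x$groups$n_released), "\n")
  invisible(x)
}

#' Detection mask in tidy form
#'
#' @param design A `popan_design`.
#' @return A tibble with one row per (group, occasion) cell and its mask
#'   state: `"free"`, `"fixed0"`, or `"fixed1"`.
#' @export
design_mask <- function(design) {
  stopifnot(inherits(design, "popan_design"))
  tidyr::expand_grid(
    group_id = design$groups$group_id,
    occasion = seq_len(design$n_occasions)
  ) %>%
    mutate(
      year = design$years[.data$occasion],
      state = as.vector(t(design$mask))
    ) %>%
    left_join(
      select(design$groups, "group_id", "cohort", "telemetry_occasions"),
      by = "group_id"
    ) %>%
    select("group_id", "cohort", "telemetry_occasions", "occasion", "year",
           "state")
}

#' Entry fixing in tidy form
#'
#' Probability-of-entry values implied by the release schedule: 1 at each
#' group's release occasion, 0 elsewhere.
#'
#' @param design A `popan_design`.
#' @return A tibble of (group, occasion, entry) rows.
#' @export
entry_fix <- function(design) {
  stopifnot(inherits(design, "popan_design"))
  tidyr::expand_grid(
    group_id = design$groups$group_id,
    occasion = seq_len(design$n_occasions)
  ) %>%
    left_join(select(design$groups, "group_id", "release_occasion"),
              by = "group_id") %>%
    mutate(entry = as.integer(.data$occasion == .data$release_occasion)) %>%
    select("group_id", "occasion", "entry")
}
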
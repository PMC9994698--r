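#' Read encounter histories
#'
#' Reads individual encounter histories from disk. Three layouts are
#' supported:
#'
#' * `"tabular"` -- one row per individual with columns `id`, `cohort`,
#'   `telemetry_occasions`, and one 0/1 detection column per occasion year
#'   (`y2015` ... `y2020` by default). CSV is read with readr; `.xlsx` files
#'   are read with readxl when that package is available. Optional columns
#'   `first_encounter_dead` and `direct_release` are carried through for the
#'   inclusion rules.
#' * `"inp"` -- a MARK-style encounter file: one encounter string per row,
#'   one frequency column per group, `/* ... */` comments, trailing `;`.
#' * `"records"` -- dated observation records (`id`, `cohort`,
#'   `telemetry_occasions`, `year`), which are collapsed to one annual
#'   occasion per year: any live observation in year *y* becomes a detection
#'   at occasion *y*.
#'
#' @param path Path to the input file.
#' @param format One of `"tabular"`, `"inp"`, `"records"`.
#' @param years Occasion years (default `2015:2020`).
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(id = "Turtle", cohort = "ReleaseYear")`. Detection columns may be
#'   mapped the same way (`y2015 = "Det2015"`, ...).
#' @param groups For `format = "inp"`, the group table giving the meaning of
#'   the frequency columns (default [headstart_groups()]).
#' @return A tibble of validated encounter histories in canonical layout.
#' @export
read_histories <- function(path,
                           format = c("tabular", "inp", "records"),
                           years = 2015:2020,
                           col_map = NULL,
                           groups = headstart_groups()) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  h <- switch(format,
    tabular = read_histories_tabular(path, years, col_map),
    inp = read_inp(path, groups = groups, years = years),
    records = read_histories_records(path, years, col_map)
  )
  validate_histories(h, years)
}

detection_cols <- function(years) paste0("y", years)

read_histories_tabular <- function(path, years, col_map) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("Reading .xlsx requires the readxl package.")
    }
    as_tibble(readxl::read_excel(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, comment = "#")
  }
  raw <- apply_col_map(raw, col_map)
  need <- c("id", "cohort", "telemetry_occasions", detection_cols(years))
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")))
  }
  as_canonical(raw, years)
}

read_histories_records <- function(path, years, col_map) {
  raw <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  raw <- apply_col_map(raw, col_map)
  need <- c("id", "cohort", "telemetry_occasions", "year")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")))
  }
  collapse_records(raw, years)
}

#' Collapse dated observation records to annual encounter histories
#'
#' Any live observation of an individual in year *y* becomes a detection at
#' the annual occasion *y*; observations outside `years` are ignored.
#'
#' @param records A data frame with columns `id`, `cohort`,
#'   `telemetry_occasions`, `year` (one row per observation; zero-observation
#'   individuals may appear with `NA` year).
#' @param years Occasion years.
#' @return A canonical encounter-history tibble.
#' @export
collapse_records <- function(records, years = 2015:2020) {
  records <- as_tibble(records)
  base <- distinct(records, .data$id, .data$cohort, .data$telemetry_occasions)
  det <- records %>%
    filter(!is.na(.data$year), .data$year %in% .env$years) %>%
    distinct(.data$id, .data$year) %>%
    mutate(col = paste0("y", .data$year), value = 1L) %>%
    select("id", "col", "value") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "value",
                       values_fill = 0L)
  out <- left_join(base, det, by = "id")
  for (cl in detection_cols(years)) {
    if (!cl %in% names(out)) out[[cl]] <- 0L
    out[[cl]][is.na(out[[cl]])] <- 0L
  }
  select(out, "id", "cohort", "telemetry_occasions",
         dplyr::all_of(detection_cols(years)), dplyr::any_of(
           c("first_encounter_dead", "direct_release")))
}

apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  for (canon in names(col_map)) {
    src <- col_map[[canon]]
    if (!src %in% names(df)) abort(paste0("Mapped column not found: ", src))
    names(df)[names(df) == src] <- canon
  }
  df
}

as_canonical <- function(df, years) {
  keep <- c("id", "cohort", "telemetry_occasions", detection_cols(years),
            intersect(c("first_encounter_dead", "direct_release"), names(df)))
  df <- select(df, dplyr::all_of(keep))
  df %>% mutate(
    id = as.character(.data$id),
    cohort = as.integer(.data$cohort),
    telemetry_occasions = as.integer(.data$telemetry_occasions),
    across(dplyr::all_of(detection_cols(years)), \(x) as.integer(x))
  )
}

#' Validate encounter histories
#'
#' Checks the structural invariants of an encounter-history table: detection
#' flags are 0/1; no detection occurs before an individual's release
#' occasion; telemetry spans stay within the study occasions. Malformed rows
#' are reported with row numbers and individual ids.
#'
#' @param histories A canonical encounter-history tibble.
#' @param years Occasion years.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_histories <- function(histories, years = 2015:2020) {
  histories <- as_tibble(histories)
  dcols <- detection_cols(years)
  det <- as.matrix(histories[dcols])
  bad <- which(!(det %in% c(0L, 1L)) | is.na(det))
  if (length(bad)) {
    rows <- sort(unique(((bad - 1L) %% nrow(det)) + 1L))
    abort(paste0("Non-binary detection value(s) in row(s): ",
                 paste(head(rows, 10), collapse = ", ")))
  }
  rel <- match(histories$cohort, years)  # NA for pre-study cohorts (e.g. 2014)
  for (i in seq_len(nrow(histories))) {
    r <- rel[i]
    if (!is.na(r) && r > 1 && any(det[i, seq_len(r - 1L)] == 1L)) {
      abort(paste0("Detection before release for individual '",
                   histories$id[i], "' (row ", i, ")."))
    }
    d <- histories$telemetry_occasions[i]
    if (!is.na(r) && d > 0 && r + d - 1L > length(years)) {
      abort(paste0("Telemetry span exceeds last occasion for individual '",
                   histories$id[i], "' (row ", i, ")."))
    }
  }
  histories
}

#' Write encounter histories as canonical CSV
#'
#' @param histories A canonical encounter-history tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histories <- function(histories, path) {
  readr::write_csv(as_tibble(histories), path)
  invisible(path)
}

#' Write encounter histories in MARK .inp dialect
#'
#' One line per individual: the encounter string, one frequency column per
#' group (1 in the individual's group, 0 elsewhere), and a terminating `;`.
#' The individual id is carried in a `/* ... */` comment. Group order follows
#' `groups`.
#'
#' @param histories A canonical encounter-history tibble.
#' @param path Output path.
#' @param groups Group table used for the frequency columns.
#' @param years Occasion years.
#' @return `path`, invisibly.
#' @export
write_inp <- function(histories, path, groups = headstart_groups(),
                      years = 2015:2020) {
  histories <- as_tibble(histories)
  groups <- as_tibble(groups)
  gidx <- match(
    paste(histories$cohort, histories$telemetry_occasions),
    paste(groups$cohort, groups$telemetry_occasions)
  )
  if (anyNA(gidx)) {
    bad <- histories$id[is.na(gidx)]
    abort(paste0("No group for individual(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  det <- as.matrix(histories[detection_cols(years)])
  hs <- apply(det, 1, paste, collapse = "")
  freq <- matrix(0L, nrow(histories), nrow(groups))
  freq[cbind(seq_len(nrow(histories)), gidx)] <- 1L
  header <- paste0(
    "/* encounter histories; groups (cohort:telemetry): ",
    paste(paste0(groups$cohort, ":", groups$telemetry_occasions),
          collapse = " "),
    " */"
  )
  lines <- paste0(
    "/* ", histories$id, " */ ", hs, " ",
    apply(freq, 1, paste, collapse = " "), ";"
  )
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a MARK .inp encounter file
#'
#' Parses the dialect written by [write_inp()]: `/* ... */` comments are
#' stripped, each statement is an encounter string followed by per-group
#' frequency counts and a `;`. Individuals are reconstructed per group (a
#' frequency of `f` yields `f` records). Ids are taken from a preceding
#' comment when present, otherwise synthesised.
#'
#' @inheritParams write_inp
#' @return A canonical encounter-history tibble.
#' @export
read_inp <- function(path, groups = headstart_groups(), years = 2015:2020) {
  groups <- as_tibble(groups)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  # capture ids from comments immediately preceding a history
  txt_noc <- gsub("/\\*.*?\\*/", " ", txt)
  ids <- stringr::str_match_all(
    txt, "/\\*\\s*([^*/]*?)\\s*\\*/\\s*([01]+)"
  )[[1]]
  id_lookup <- if (nrow(ids)) setNames(ids[, 2], ids[, 3]) else character()
  stmts <- strsplit(txt_noc, ";")[[1]]
  stmts <- trimws(stmts)
  stmts <- stmts[nzchar(stmts)]
  out <- list()
  counter <- 0L
  for (s in stmts) {
    tok <- strsplit(s, "\\s+")[[1]]
    hist <- tok[1]
    if (!grepl("^[01]+$", hist)) {
      abort(paste0("Non-binary encounter symbol in statement: '", s, "'"))
    }
    if (nchar(hist) != length(years)) {
      abort(paste0("Encounter string '", hist, "' has ", nchar(hist),
                   " occasions; expected ", length(years), "."))
    }
    freqs <- suppressWarnings(as.numeric(tok[-1]))
    if (anyNA(freqs)) abort(paste0("Non-numeric frequency in: '", s, "'"))
    if (length(freqs) == 0) freqs <- 1
    if (length(freqs) == 1 && nrow(groups) > 1) {
      abort("Single-frequency rows require a single-group table.")
    }
    det <- as.integer(strsplit(hist, "")[[1]])
    for (g in which(freqs > 0)) {
      for (k in seq_len(freqs[g])) {
        counter <- counter + 1L
        out[[counter]] <- tibble(
          id = NA_character_, hist = hist,
          cohort = groups$cohort[g],
          telemetry_occasions = groups$telemetry_occasions[g],
          !!!setNames(as.list(det), detection_cols(years))
        )
      }
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(id = character(), cohort = integer(),
                  telemetry_occasions = integer()) %>%
             bind_rows(tibble(!!!setNames(
               rep(list(integer()), length(years)), detection_cols(years)))))
  }
  res$id <- if (length(id_lookup) == nrow(res)) {
    unname(id_lookup)
  } else {
    sprintf("ind%04d", seq_len(nrow(res)))
  }
  validate_histories(select(res, -"hist"), years)
}

#' Default inclusion rules
#'
#' The filtering applied before model fitting: drop the 2014 release cohort
#' (missing data), drop animals found dead at first encounter, drop animals
#' whose only detections are opportunistic captures in non-survey years
#' without telemetry, and drop direct-release hatchlings.
#'
#' @param drop_cohorts Cohort years to exclude entirely.
#' @param drop_first_encounter_dead,drop_opportunistic_only,drop_direct_release
#'   Logical switches for the respective rules.
#' @param survey_years Years with survey effort (detections in other years are
#'   opportunistic).
#' @param valid_cohorts Cohort years the retained data may contain.
#' @return A named list of rules for [apply_inclusion_rules()].
#' @export
inclusion_rules <- function(drop_cohorts = 2014L,
                            drop_first_encounter_dead = TRUE,
                            drop_opportunistic_only = TRUE,
                            drop_direct_release = TRUE,
                            survey_years = 2018:2020,
                            valid_cohorts = 2014:2020) {
  list(
    drop_cohorts = as.integer(drop_cohorts),
    drop_first_encounter_dead = drop_first_encounter_dead,
    drop_opportunistic_only = drop_opportunistic_only,
    drop_direct_release = drop_direct_release,
    survey_years = as.integer(survey_years),
    valid_cohorts = as.integer(valid_cohorts)
  )
}

#' Apply inclusion rules to raw encounter histories
#'
#' Filters a raw encounter-history table down to the analysis set and keeps a
#' ledger of exclusions (individual id and the rule that removed it),
#' retrievable with [exclusion_ledger()].
#'
#' @param histories Raw canonical encounter-history tibble; may carry logical
#'   columns `first_encounter_dead` and `direct_release`.
#' @param rules A rule list from [inclusion_rules()].
#' @param years Occasion years.
#' @return The retained tibble, with the exclusion ledger attached as the
#'   `"exclusions"` attribute.
#' @export
#' @examples
#' h <- tibble::tibble(
#'   id = c("a", "b"), cohort = c(2014L, 2018L), telemetry_occasions = 0L,
#'   y2015 = 0L, y2016 = 0L, y2017 = 0L, y2018 = c(0L, 1L),
#'   y2019 = 0L, y2020 = 0L
#' )
#' kept <- apply_inclusion_rules(h)
#' exclusion_ledger(kept)
apply_inclusion_rules <- function(histories, rules = inclusion_rules(),
                                  years = 2015:2020) {
  histories <- as_tibble(histories)
  unknown <- setdiff(unique(histories$cohort), rules$valid_cohorts)
  if (length(unknown)) {
    abort(paste0("Unknown cohort year(s): ", paste(unknown, collapse = ", ")))
  }
  rule_of <- rep(NA_character_, nrow(histories))

  mark <- function(cond, tag) {
    rule_of[is.na(rule_of) & cond] <<- tag
  }
  if (length(rules$drop_cohorts)) {
    mark(histories$cohort %in% rules$drop_cohorts,
         paste0("cohort_", paste(rules$drop_cohorts, collapse = "_")))
  }
  if (rules$drop_direct_release && "direct_release" %in% names(histories)) {
    mark(isTRUE_vec(histories$direct_release), "direct_release")
  }
  if (rules$drop_first_encounter_dead &&
      "first_encounter_dead" %in% names(histories)) {
    mark(isTRUE_vec(histories$first_encounter_dead), "first_encounter_dead")
  }
  if (rules$drop_opportunistic_only) {
    det <- as.matrix(histories[detection_cols(years)])
    non_survey <- !(years %in% rules$survey_years)
    any_det <- rowSums(det) > 0
    survey_det <- rowSums(det[, !non_survey, drop = FALSE]) > 0
    opp_only <- any_det & !survey_det & histories$telemetry_occasions == 0L
    mark(opp_only, "opportunistic_only")
  }

  ledger <- tibble(id = histories$id[!is.na(rule_of)],
                   rule = rule_of[!is.na(rule_of)])
  retained <- histories[is.na(rule_of), , drop = FALSE]
  attr(retained, "exclusions") <- ledger
  retained
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Exclusion ledger of a filtered history table
#'
#' @param histories The result of [apply_inclusion_rules()].
#' @return A tibble with columns `id` and `rule`.
#' @export
exclusion_ledger <- function(histories) {
  led <- attr(histories, "exclusions")
  if (is.null(led)) tibble(id = character(), rule = character()) else led
}
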
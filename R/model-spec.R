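PHI_STRUCTURES <- c("constant", "t", "acc", "cohort", "t*acc", "t+acc",
                    "t+acc2019", "acc+t2019", "acc2019", "2019")
P_STRUCTURES <- c("constant", "t", "t+acc", "t*acc")

#' Specify a survival/detection model structure
#'
#' A model is a pair of submodel structures on the logit scale:
#'
#' * survival (`phi`): `"constant"`, `"t"` (interval-specific), `"acc"`
#'   (two acclimation levels: `New` in the first interval after release,
#'   `Exp` afterwards), `"cohort"`, `"t*acc"`, `"t+acc"`, `"t+acc2019"`
#'   (time plus an extra level for newly released animals in 2019),
#'   `"acc+t2019"`, `"acc2019"` (constant except 2019 new releases), `"2019"`
#'   (a 2019-interval effect only);
#' * detection (`p`): `"t"` (year-specific), `"t+acc"`, `"t*acc"`, or
#'   `"constant"` (mostly for toy designs). Acclimation for detection is
#'   `New` at the release-year occasion.
#'
#' A full model can also be given as a single string in the conventional
#' notation, e.g. `"Phi(acc2019) p(t)"`.
#'
#' @param phi Survival structure name, or a full `"Phi(...) p(...)"` string.
#' @param p Detection structure name (ignored when `phi` is a full string).
#' @return A `popan_model` object.
#' @export
#' @examples
#' model_spec("Phi(acc2019) p(t)")
#' model_spec(phi = "t+acc2019", p = "t")
model_spec <- function(phi, p = NULL) {
  if (is.null(p)) {
    m <- stringr::str_match(
      phi, "^\\s*Phi\\(([^)]+)\\)\\s*p\\(([^)]+)\\)\\s*$"
    )
    if (is.na(m[1, 1])) {
      abort(paste0("Cannot parse model string '", phi,
                   "'; expected \"Phi(<structure>) p(<structure>)\"."))
    }
    phi <- m[1, 2]
    p <- m[1, 3]
  }
  if (!phi %in% PHI_STRUCTURES) {
    abort(paste0("Unknown survival structure '", phi, "'."))
  }
  if (!p %in% P_STRUCTURES) {
    abort(paste0("Unknown detection structure '", p, "'."))
  }
  structure(
    list(phi = phi, p = p, name = paste0("Phi(", phi, ") p(", p, ")")),
    class = "popan_model"
  )
}

#' @export
print.popan_model <- function(x, ...) {
  cat("<popan_model>", x$name, "\n")
  invisible(x)
}

#' The candidate model set
#'
#' The 18 survival-by-detection combinations considered for the headstarted
#' population: survival structures `t+acc2019`, `acc2019`, `acc+t2019`,
#' `cohort`, `t` crossed with detection structures `t`, `t*acc`, `t+acc`,
#' plus the general `Phi(t*acc)` structure with `p(t)` and `p(t*acc)` and
#' the pure `Phi(2019)` structure with `p(t*acc)`.
#'
#' @return A character vector of model names accepted by [model_spec()].
#' @export
default_candidates <- function() {
  phis <- c("t+acc2019", "acc2019", "acc+t2019", "cohort", "t")
  ps <- c("t", "t*acc", "t+acc")
  grid <- tidyr::expand_grid(phi = phis, p = ps)
  c(paste0("Phi(", grid$phi, ") p(", grid$p, ")"),
    "Phi(t*acc) p(t)", "Phi(t*acc) p(t*acc)", "Phi(2019) p(t*acc)")
}

# Cell tables: one row per estimable-or-fixed probability cell.
popan_cells <- function(design) {
  g <- design$groups
  years <- design$years
  n_occ <- design$n_occasions

  phi <- purrr::pmap_dfr(g, function(group_id, cohort, telemetry_occasions,
                                     n_released, release_occasion) {
    ints <- seq_len(n_occ - 1L)
    ints <- ints[ints >= release_occasion]
    if (!length(ints)) return(NULL)
    tibble(
      group_id = group_id, cohort = cohort, interval = ints,
      year = years[ints],
      acc = if_else(ints == release_occasion, "New", "Exp")
    )
  }) %>%
    mutate(
      acc = factor(.data$acc, levels = c("Exp", "New")),
      acc2019 = .data$acc == "New" & .data$cohort == 2019L,
      t2019 = .data$year == 2019L
    )

  p <- purrr::pmap_dfr(g, function(group_id, cohort, telemetry_occasions,
                                   n_released, release_occasion) {
    occ <- seq.int(release_occasion, n_occ)
    st <- design$mask[as.character(group_id), ][occ]
    tibble(
      group_id = group_id, cohort = cohort, occasion = occ,
      year = years[occ],
      acc = if_else(occ == release_occasion, "New", "Exp"),
      state = unname(st)
    )
  }) %>%
    mutate(acc = factor(.data$acc, levels = c("Exp", "New")))
  list(phi = phi, p = p)
}

phi_formula <- function(structure) {
  switch(structure,
    "constant" = ~1,
    "t" = ~ factor(year),
    "acc" = ~acc,
    "cohort" = ~ factor(cohort),
    "t*acc" = ~ factor(year) * acc,
    "t+acc" = ~ factor(year) + acc,
    "t+acc2019" = ~ factor(year) + acc2019,
    "acc+t2019" = ~ acc + t2019,
    "acc2019" = ~acc2019,
    "2019" = ~t2019
  )
}

p_formula <- function(structure) {
  switch(structure,
    "constant" = ~1,
    "t" = ~ factor(year),
    "t+acc" = ~ factor(year) + acc,
    "t*acc" = ~ factor(year) * acc
  )
}

# Full-rank design matrix over realized cells: aliased columns (factor
# combinations never realized in the design) are dropped, so ncol() is the
# structural parameter count.
full_rank_mm <- function(formula, data) {
  if (nrow(data) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  }
  # augment with a phantom row on a distinct year so single-level factors
  # still build; its dummy columns are all-zero on real rows and fall out
  # with the other aliased columns below
  phantom <- data[1, , drop = FALSE]
  phantom$year <- max(data$year) + 1L
  X <- model.matrix(formula, data = dplyr::bind_rows(data, phantom))
  X <- X[seq_len(nrow(data)), , drop = FALSE]
  q <- qr(X)
  X[, sort(q$pivot[seq_len(q$rank)]), drop = FALSE]
}

# Assemble everything the likelihood needs for (design, model).
prepare_model <- function(design, model) {
  stopifnot(inherits(design, "popan_design"), inherits(model, "popan_model"))
  cells <- popan_cells(design)
  X_phi <- full_rank_mm(phi_formula(model$phi), cells$phi)
  p_free <- filter(cells$p, .data$state == MASK_FREE)
  X_p <- full_rank_mm(p_formula(model$p), p_free)
  k_phi <- ncol(X_phi)
  k_p <- ncol(X_p)

  G <- nrow(design$groups)
  n_occ <- design$n_occasions
  PHI <- matrix(NA_real_, G, n_occ - 1L)
  P <- matrix(NA_real_, G, n_occ)
  P[cbind(match(cells$p$group_id, design$groups$group_id),
          cells$p$occasion)] <-
    dplyr::case_when(
      cells$p$state == MASK_FIXED_0 ~ 0,
      cells$p$state == MASK_FIXED_1 ~ 1,
      TRUE ~ NA_real_
    )
  phi_idx <- cbind(match(cells$phi$group_id, design$groups$group_id),
                   cells$phi$interval)
  p_idx <- cbind(match(p_free$group_id, design$groups$group_id),
                 p_free$occasion)

  list(
    model = model, design = design, cells = cells, p_free = p_free,
    X_phi = X_phi, X_p = X_p, k_phi = k_phi, k_p = k_p, k = k_phi + k_p,
    PHI_template = PHI, P_template = P,
    phi_lin = phi_idx[, 1] + (phi_idx[, 2] - 1L) * G,
    p_lin = p_idx[, 1] + (p_idx[, 2] - 1L) * G
  )
}

# Resolve link-scale parameters into per-group probability matrices.
resolve_theta <- function(prep, theta) {
  if (length(theta) != prep$k) {
    abort(paste0("theta has length ", length(theta), "; expected ", prep$k))
  }
  if (any(!is.finite(theta))) abort("Non-finite parameter value.")
  PHI <- prep$PHI_template
  P <- prep$P_template
  if (prep$k_phi > 0) {
    PHI[prep$phi_lin] <- plogis(drop(prep$X_phi %*% theta[seq_len(prep$k_phi)]))
  }
  if (prep$k_p > 0) {
    P[prep$p_lin] <- plogis(drop(prep$X_p %*% theta[prep$k_phi + seq_len(prep$k_p)]))
  }
  list(PHI = PHI, P = P)
}

#' Parameter index matrix for a model on a design
#'
#' Expands a model structure over a study design into one row per survival
#' or detection cell, reporting whether the cell is fixed (and at what
#' value) or free, and which shared estimable parameter it maps to. Cells
#' sharing a design-matrix row share an index; under additive structures a
#' cell can load on several coefficients, so the number of distinct indices
#' can exceed the structural parameter count `k` (stored in the `"k"`
#' attribute along with `"k_phi"` and `"k_p"`).
#'
#' @param design A `popan_design`.
#' @param model A `popan_model` (or a model string).
#' @return A tibble with columns `type` (`"phi"`/`"p"`), `group_id`,
#'   `cohort`, `index` (interval or occasion), `year`, `acc`, `status`,
#'   `fixed_value`, `par_index`.
#' @export
#' @examples
#' pim <- parameter_index(build_design(), model_spec("Phi(acc2019) p(t)"))
#' attr(pim, "k")  # 5
parameter_index <- function(design, model) {
  if (is.character(model)) model <- model_spec(model)
  prep <- prepare_model(design, model)

  share_index <- function(X) {
    if (nrow(X) == 0) return(integer())
    keys <- apply(X, 1, paste, collapse = "\r")
    match(keys, unique(keys))
  }
  phi_tab <- prep$cells$phi %>%
    mutate(
      type = "phi", index = .data$interval, status = "free",
      fixed_value = NA_real_, par_index = share_index(prep$X_phi)
    )
  p_ids <- share_index(prep$X_p)
  offset <- if (length(p_ids)) max(c(0L, phi_tab$par_index)) else 0L
  p_tab <- prep$cells$p %>%
    mutate(
      type = "p", index = .data$occasion,
      status = dplyr::recode(.data$state, free = "free", fixed0 = "fixed",
                             fixed1 = "fixed"),
      fixed_value = dplyr::case_when(
        .data$state == MASK_FIXED_0 ~ 0,
        .data$state == MASK_FIXED_1 ~ 1,
        TRUE ~ NA_real_
      ),
      par_index = NA_integer_
    )
  p_tab$par_index[p_tab$state == MASK_FREE] <- p_ids + offset
  out <- bind_rows(
    select(phi_tab, "type", "group_id", "cohort", "index", "year", "acc",
           "status", "fixed_value", "par_index"),
    select(p_tab, "type", "group_id", "cohort", "index", "year", "acc",
           "status", "fixed_value", "par_index")
  )
  attr(out, "k") <- prep$k
  attr(out, "k_phi") <- prep$k_phi
  attr(out, "k_p") <- prep$k_p
  attr(out, "model") <- model$name
  out
}
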
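#' Project group abundances through the survival recursion
#'
#' Expected abundance of each group: `N[g, r] = n_released` at the release
#' occasion and `N[g, t+1] = N[g, t] * phi[g, t]` afterwards (0 before
#' release). Occasion totals sum over groups, so totals jump by exactly the
#' release count at each release occasion and otherwise decline.
#'
#' @param design A `popan_design`.
#' @param phi Either a single survival probability used everywhere, a
#'   function `f(cohort, year, acc)` returning the survival for a group's
#'   interval (`acc` is `"New"` for the first interval after release), or a
#'   full groups-by-intervals matrix.
#' @return A tibble with columns `occasion`, `year`, `abundance`, and a
#'   `"by_group"` attribute holding the per-group trajectories.
#' @export
#' @examples
#' # the study's headline projection: baseline survival 0.89 except the
#' # first interval of the 2019 releases (0.43, mass-mortality year)
#' phi_fun <- function(cohort, year, acc) {
#'   if (acc == "New" && cohort == 2019) 0.43 else 0.89
#' }
#' project_abundance(build_design(), phi_fun)
project_abundance <- function(design, phi) {
  stopifnot(inherits(design, "popan_design"))
  PHI <- phi_as_matrix(design, phi)
  traj_from_phi(design, PHI)
}

phi_as_matrix <- function(design, phi) {
  G <- nrow(design$groups)
  n_int <- design$n_occasions - 1L
  if (is.matrix(phi)) {
    stopifnot(nrow(phi) == G, ncol(phi) == n_int)
    return(phi)
  }
  PHI <- matrix(NA_real_, G, n_int)
  for (j in seq_len(G)) {
    r <- design$groups$release_occasion[j]
    for (t in seq_len(n_int)) {
      if (t < r) next
      acc <- if (t == r) "New" else "Exp"
      PHI[j, t] <- if (is.function(phi)) {
        phi(design$groups$cohort[j], design$years[t], acc)
      } else {
        phi
      }
    }
  }
  PHI
}

traj_from_phi <- function(design, PHI) {
  g <- design$groups
  n_occ <- design$n_occasions
  N <- matrix(0, nrow(g), n_occ)
  for (j in seq_len(nrow(g))) {
    r <- g$release_occasion[j]
    N[j, r] <- g$n_released[j]
    if (r < n_occ) {
      for (t in r:(n_occ - 1L)) {
        if (!is.finite(PHI[j, t])) {
          abort(paste0("Missing survival for group ", g$group_id[j],
                       ", interval ", t, "."))
        }
        N[j, t + 1L] <- N[j, t] * PHI[j, t]
      }
    }
  }
  by_group <- tidyr::expand_grid(
    group_id = g$group_id, occasion = seq_len(n_occ)
  ) %>%
    mutate(
      year = design$years[.data$occasion],
      abundance = as.vector(t(N))
    )
  out <- tibble(
    occasion = seq_len(n_occ),
    year = design$years,
    abundance = colSums(N)
  )
  attr(out, "by_group") <- by_group
  out
}

#' Derived abundance trajectory with Delta-method intervals
#'
#' Plugs the fitted survival estimates into the abundance recursion
#' ([project_abundance()]) and propagates the link-scale covariance of the
#' estimates to each occasion total by the Delta method (numerical gradient
#' of the total with respect to the link-scale parameters, sandwiched with
#' the fitted covariance). Intervals use the normal approximation, floored
#' at 0.
#'
#' @param fit A `popan_fit`.
#' @param level Confidence level (default 0.95).
#' @return A `popan_abundance` tibble: `occasion`, `year`, `abundance`,
#'   `std.error`, `conf.low`, `conf.high`; per-group trajectories in the
#'   `"by_group"` attribute. When the fitted covariance is singular the
#'   intervals are `NA` and flagged via the `"vcov_singular"` attribute.
#' @export
derive_abundance <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "popan_fit"))
  design <- fit$design
  totals_at <- function(theta) {
    res <- resolve_theta(fit$prep, theta)
    traj_from_phi(design, res$PHI)$abundance
  }
  est <- traj_from_phi(design, resolve_theta(fit$prep, fit$coefficients)$PHI)
  z <- qnorm(1 - (1 - level) / 2)

  se <- rep(NA_real_, design$n_occasions)
  if (!fit$vcov_singular) {
    eps <- 1e-6
    k <- fit$k
    grad <- matrix(0, design$n_occasions, k)
    for (j in seq_len(k)) {
      up <- fit$coefficients
      dn <- fit$coefficients
      up[j] <- up[j] + eps
      dn[j] <- dn[j] - eps
      grad[, j] <- (totals_at(up) - totals_at(dn)) / (2 * eps)
    }
    vars <- diag(grad %*% fit$vcov %*% t(grad))
    se <- sqrt(pmax(vars, 0))
  }
  out <- est %>%
    mutate(
      std.error = se,
      conf.low = pmax(.data$abundance - z * se, 0),
      conf.high = .data$abundance + z * se
    )
  attr(out, "by_group") <- attr(est, "by_group")
  attr(out, "vcov_singular") <- fit$vcov_singular
  class(out) <- c("popan_abundance", class(out))
  out
}

#' Per-group abundance trajectories
#'
#' @param abundance A tibble from [derive_abundance()] or
#'   [project_abundance()].
#' @return The `"by_group"` tibble.
#' @export
abundance_by_group <- function(abundance) {
  attr(abundance, "by_group")
}

#' Population density
#'
#' @param total_abundance Estimated abundance.
#' @param area_ha Occupied area in hectares (must be positive).
#' @return A tibble with the unrounded density (`density`, animals/ha) and
#'   the value rounded to the nearest integer (`density_rounded`).
#' @export
#' @examples
#' density_estimate(183, 9)  # about 20 turtles/ha
density_estimate <- function(total_abundance, area_ha) {
  if (!is.finite(area_ha) || area_ha <= 0) {
    abort("`area_ha` must be positive.")
  }
  d <- total_abundance / area_ha
  tibble(
    abundance = total_abundance, area_ha = area_ha,
    density = d, density_rounded = round(d)
  )
}

#' Plot a derived abundance trajectory
#'
#' @param object A `popan_abundance` tibble.
#' @param ... Unused.
#' @return A ggplot: occasion totals with their confidence ribbon.
#' @method autoplot popan_abundance
#' @export
autoplot.popan_abundance <- function(object, ...) {
  pl <- ggplot2::ggplot(object, ggplot2::aes(x = .data$year,
                                             y = .data$abundance))
  if (!all(is.na(object$std.error))) {
    pl <- pl + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      fill = "steelblue", alpha = 0.25
    )
  }
  pl +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Year", y = "Estimated abundance") +
    ggplot2::theme_minimal()
}
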
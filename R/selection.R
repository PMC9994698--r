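#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1) / (n_eff - k - 1)`.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n_eff Effective sample size. Because every model of a candidate set
#'   shares `n_eff`, ranking is insensitive to its exact definition; the
#'   fitting functions default it to the analysis superpopulation.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(-100, 2, 50)
aicc <- function(loglik, k, n_eff) {
  if (n_eff <= k + 1) {
    abort("`n_eff` must exceed `k + 1` for the small-sample correction.")
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n_eff - k - 1)
}

#' Rank fitted models by AICc
#'
#' Builds a model-selection table: AICc, differences from the best model,
#' Akaike weights `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`, and
#' the deviance (`-2 logLik`, multinomial constant dropped). Among models
#' with `delta < 2`, the one with fewest parameters is annotated as the
#' parsimony preference; the table reports, it does not auto-select.
#'
#' @param fits A list of `popan_fit` objects fitted to the same data.
#' @param n_eff Effective sample size shared by the candidate set (default:
#'   the analysis superpopulation of the first fit).
#' @return A tibble sorted by AICc with columns `model`, `k`, `AICc`,
#'   `delta_AICc`, `weight`, `deviance`, `converged`, `preferred`.
#' @export
rank_models <- function(fits, n_eff = NULL) {
  stopifnot(length(fits) >= 1, all(purrr::map_lgl(fits, inherits, "popan_fit")))
  sig <- purrr::map_chr(fits, function(f) {
    paste(f$n_individuals, f$superpopulation,
          digest_groups(f$design$groups))
  })
  if (length(unique(sig)) != 1) {
    abort("All fits must be on identical data and design.")
  }
  if (is.null(n_eff)) n_eff <- fits[[1]]$superpopulation
  tab <- purrr::map_dfr(fits, function(f) {
    tibble(
      model = f$model$name, k = f$k, logLik = f$loglik,
      AICc = aicc(f$loglik, f$k, n_eff),
      deviance = -2 * f$loglik, converged = f$converged
    )
  }) %>%
    arrange(.data$AICc) %>%
    mutate(
      delta_AICc = .data$AICc - min(.data$AICc),
      weight = exp(-.data$delta_AICc / 2) / sum(exp(-.data$delta_AICc / 2))
    )
  close <- tab$delta_AICc < 2
  preferred_model <- tab$model[close][which.min(tab$k[close])]
  tab <- tab %>%
    mutate(preferred = .data$model == preferred_model) %>%
    select("model", "k", "AICc", "delta_AICc", "weight", "deviance",
           "converged", "preferred")
  class(tab) <- c("popan_ranking", class(tab))
  tab
}

digest_groups <- function(groups) {
  paste(groups$cohort, groups$telemetry_occasions, groups$n_released,
        collapse = ";")
}

#' Fletcher overdispersion statistic
#'
#' Goodness of fit for the multinomial encounter-history model:
#' `c_F = (X^2 / df) / (1 + s_bar)`, where `X^2` is the Pearson statistic
#' over (group, distinct history) cells -- including each group's never-seen
#' cell -- `df = cells - k - groups`, and `s_bar` is the mean of
#' `(observed - expected) / expected` over cells. Values near 1 indicate an
#' adequate fit; values well above 1 indicate overdispersion. Cells that are
#' structurally impossible under the design (expected and observed both
#' zero, e.g. the never-seen cell of a fully telemetered group) are
#' excluded.
#'
#' @param fit A converged `popan_fit`.
#' @return The Fletcher c-hat value, with attributes `X2`, `df`, `s_bar`,
#'   `n_cells`.
#' @export
fletcher_chat <- function(fit) {
  stopifnot(inherits(fit, "popan_fit"))
  res <- resolve_theta(fit$prep, fit$coefficients)
  g <- fit$design$groups
  n_occ <- fit$design$n_occasions
  obs <- numeric(0)
  expc <- numeric(0)
  for (j in seq_len(nrow(g))) {
    r <- g$release_occasion[j]
    phi <- res$PHI[j, ]
    p <- res$P[j, ]
    pats <- enumerate_patterns(n_occ, r)
    pr <- apply(pats, 1, history_probability, phi = phi, p = p, start = r)
    keep <- pr > 1e-12  # structurally possible cells only
    pats <- pats[keep, , drop = FALSE]
    pr <- pr[keep]
    key <- apply(pats, 1, paste, collapse = "")
    rows <- which(fit$data$group == j)
    o <- setNames(rep(0, length(key)), key)
    if (length(rows)) {
      okey <- apply(fit$data$hist[rows, , drop = FALSE], 1, paste,
                    collapse = "")
      hit <- match(okey, key)
      if (anyNA(hit)) {
        abort("Observed history with zero probability under the fitted model.")
      }
      o[hit] <- fit$data$n_ind[rows]
    }
    zero_key <- paste(rep(0L, n_occ), collapse = "")
    if (zero_key %in% key) {
      o[zero_key] <- g$n_released[j] - fit$data$M[j]
    }
    obs <- c(obs, o)
    expc <- c(expc, g$n_released[j] * pr)
  }
  n_cells <- length(obs)
  df <- n_cells - fit$k - nrow(g)
  if (df <= 0) abort("Non-positive degrees of freedom for Fletcher c-hat.")
  X2 <- sum((obs - expc)^2 / expc)
  s_bar <- mean((obs - expc) / expc)
  chat <- (X2 / df) / (1 + s_bar)
  structure(chat, X2 = X2, df = df, s_bar = s_bar, n_cells = n_cells)
}

# All detection patterns over occasions start..n_occ (zeros elsewhere).
enumerate_patterns <- function(n_occ, start) {
  m <- n_occ - start + 1L
  grid <- as.matrix(expand.grid(rep(list(0:1), m)))
  out <- matrix(0L, nrow(grid), n_occ)
  out[, start:n_occ] <- grid
  out
}

#' Plot a model-ranking table
#'
#' @param object A `popan_ranking` tibble from [rank_models()].
#' @param ... Unused.
#' @return A ggplot of Akaike weights by model.
#' @method autoplot popan_ranking
#' @export
autoplot.popan_ranking <- function(object, ...) {
  df <- mutate(object, model = factor(.data$model, levels = rev(.data$model)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$model)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Akaike weight", y = NULL) +
    ggplot2::theme_minimal()
}
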
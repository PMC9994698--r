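#' Fit a POPAN model by maximum likelihood
#'
#' Maximises the total log-likelihood over link-scale (logit) parameters with
#' quasi-Newton (BFGS) optimisation, restarting from jittered start values,
#' and computes the asymptotic covariance as the inverse of the observed
#' information (finite-difference Hessian). Parameters whose estimates pin to
#' the boundary of the probability scale, or whose information matrix is
#' singular, are flagged as unreliable/inestimable -- a common symptom of
#' overparameterised structures on sparse data.
#'
#' @param histories Canonical encounter-history tibble (the analysis set
#'   after [apply_inclusion_rules()]).
#' @param design A `popan_design`.
#' @param model A `popan_model` or model string such as `"Phi(acc2019) p(t)"`.
#' @param start Optional link-scale start values (default zeros, i.e. all
#'   probabilities 0.5).
#' @param n_restarts Number of jittered restarts tried after the first fit
#'   (default 5); the best optimum is kept.
#' @param restart_sd Standard deviation of the start-value jitter.
#' @param seed Seed for the restart jitter (applied locally; does not touch
#'   the global RNG stream).
#' @param reltol Relative convergence tolerance passed to [stats::optim()]
#'   (default 1e-8 on the log-likelihood).
#' @return A `popan_fit` object; see [tidy()], [glance()],
#'   [derive_abundance()].
#' @export
fit_popan <- function(histories, design, model, start = NULL,
                      n_restarts = 5, restart_sd = 1.5, seed = 1,
                      reltol = 1e-8) {
  if (is.character(model)) model <- model_spec(model)
  prep <- prepare_model(design, model)
  dat <- popan_group_data(histories, design)
  if (prep$k == 0) abort("Model has no free parameters on this design.")

  negll <- function(theta) {
    ll <- total_loglik_prepared(prep, dat, theta)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  starts <- list(if (is.null(start)) rep(0, prep$k) else start)
  if (n_restarts > 0) {
    jitter <- withr::with_seed(seed, lapply(seq_len(n_restarts), function(i) {
      stats::rnorm(prep$k, 0, restart_sd)
    }))
    starts <- c(starts, jitter)
  }
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      optim(s, negll, method = "BFGS",
            control = list(maxit = 500, reltol = reltol)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
  }
  if (is.null(best)) abort("Optimisation failed from every start value.")
  converged <- best$convergence == 0 && is.finite(best$value)

  H <- tryCatch(optimHess(best$par, negll), error = function(e) NULL)
  vc <- matrix(NA_real_, prep$k, prep$k)
  singular <- TRUE
  if (!is.null(H)) {
    vc_try <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc_try) && all(is.finite(vc_try)) &&
        all(diag(vc_try) > -1e-8)) {
      vc <- vc_try
      singular <- FALSE
    }
  }
  boundary <- abs(best$par) > 10

  structure(
    list(
      coefficients = best$par,
      vcov = vc,
      loglik = -best$value,
      k = prep$k,
      converged = converged,
      boundary = boundary,
      vcov_singular = singular,
      model = model,
      design = design,
      prep = prep,
      data = dat,
      n_individuals = dat$n_histories,
      superpopulation = sum(design$groups$n_released)
    ),
    class = "popan_fit"
  )
}

#' @export
coef.popan_fit <- function(object, ...) object$coefficients

#' @export
vcov.popan_fit <- function(object, ...) object$vcov

#' @export
logLik.popan_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
print.popan_fit <- function(x, ...) {
  cat("<popan_fit>", x$model$name, "\n")
  cat("  logLik:", format(x$loglik, digits = 8), " k:", x$k,
      " converged:", x$converged, "\n")
  cat("  observed individuals:", x$n_individuals,
      " superpopulation:", x$superpopulation, "\n")
  if (any(x$boundary)) {
    cat("  boundary-flagged parameters:", sum(x$boundary), "\n")
  }
  invisible(x)
}

# Real (probability-scale) parameters: one row per distinct design-matrix
# row, i.e. per shared estimable cell value.
real_params <- function(fit, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  one_block <- function(cells, X, beta, V, type) {
    if (nrow(X) == 0) return(NULL)
    keys <- apply(X, 1, paste, collapse = "\r")
    uid <- match(keys, unique(keys))
    purrr::map_dfr(seq_len(max(uid)), function(u) {
      rows <- which(uid == u)
      x <- X[rows[1], ]
      eta <- sum(x * beta)
      var_eta <- if (all(is.finite(V))) drop(t(x) %*% V %*% x) else NA_real_
      se_eta <- if (!is.na(var_eta) && var_eta >= 0) sqrt(var_eta) else NA_real_
      est <- plogis(eta)
      boundary <- abs(eta) > 10
      cc <- cells[rows, , drop = FALSE]
      pick <- function(v) if (length(unique(v)) == 1) unique(v) else NA
      tibble(
        type = type,
        year = pick(cc$year),
        acc = as.character(pick(as.character(cc$acc))),
        cohort = pick(cc$cohort),
        estimate = est,
        std.error = est * (1 - est) * se_eta,
        conf.low = if (is.na(se_eta)) NA_real_ else plogis(eta - z * se_eta),
        conf.high = if (is.na(se_eta)) NA_real_ else plogis(eta + z * se_eta),
        n_cells = length(rows),
        boundary = boundary,
        unreliable = boundary || is.na(se_eta)
      )
    })
  }
  bphi <- fit$coefficients[seq_len(fit$prep$k_phi)]
  bp <- fit$coefficients[fit$prep$k_phi + seq_len(fit$prep$k_p)]
  Vphi <- fit$vcov[seq_len(fit$prep$k_phi), seq_len(fit$prep$k_phi),
                   drop = FALSE]
  ip <- fit$prep$k_phi + seq_len(fit$prep$k_p)
  Vp <- fit$vcov[ip, ip, drop = FALSE]
  bind_rows(
    one_block(fit$prep$cells$phi, fit$prep$X_phi, bphi, Vphi, "phi"),
    one_block(fit$prep$p_free, fit$prep$X_p, bp, Vp, "p")
  )
}

#' Wald confidence intervals for fitted parameters
#'
#' Intervals are computed on the logit scale (`estimate +/- z * SE`) and
#' back-transformed, so they are asymmetric on the probability scale and
#' always lie in `[0, 1]`. Boundary-flagged parameters are marked
#' `unreliable`.
#'
#' @param fit A `popan_fit`.
#' @param level Confidence level (default 0.95).
#' @return A tibble of probability-scale parameters with `conf.low`,
#'   `conf.high`, and reliability flags.
#' @export
wald_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "popan_fit"))
  real_params(fit, level = level)
}

#' Tidy a fitted POPAN model
#'
#' One row per shared estimable parameter on the probability scale, with
#' logit-scale Wald intervals back-transformed. Columns `year`, `acc`,
#' `cohort` identify the cells a parameter covers (`NA` when the parameter
#' spans several values).
#'
#' @param x A `popan_fit`.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy popan_fit
#' @export
tidy.popan_fit <- function(x, conf.level = 0.95, ...) {
  out <- real_params(x, level = conf.level)
  mutate(out, term = paste0(
    .data$type,
    if_else(is.na(.data$year), "", paste0("(", .data$year, ")")),
    if_else(is.na(.data$acc), "", paste0("[", .data$acc, "]"))
  )) %>%
    select("term", dplyr::everything())
}

#' Glance at a fitted POPAN model
#'
#' @param x A `popan_fit`.
#' @param n_eff Effective sample size for AICc (default: the analysis
#'   superpopulation).
#' @param ... Unused.
#' @return A one-row tibble with `logLik`, `k`, `AICc`, `deviance`
#'   (`-2 logLik`, multinomial constant dropped), convergence and size
#'   information.
#' @method glance popan_fit
#' @export
glance.popan_fit <- function(x, n_eff = x$superpopulation, ...) {
  tibble(
    model = x$model$name,
    logLik = x$loglik,
    k = x$k,
    AICc = aicc(x$loglik, x$k, n_eff),
    deviance = -2 * x$loglik,
    n_eff = n_eff,
    n_individuals = x$n_individuals,
    superpopulation = x$superpopulation,
    converged = x$converged,
    boundary_params = sum(x$boundary),
    vcov_singular = x$vcov_singular
  )
}
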
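# Independent brute-force oracle for encounter-history probabilities:
# enumerate the latent death time instead of using the zeta/chi recursions.
brute_history_prob <- function(x, phi, p, r) {
  T <- length(p)
  tot <- 0
  for (s in r:T) {  # s = last occasion alive
    pr_alive <- 1
    if (s > r) pr_alive <- prod(phi[r:(s - 1)])
    if (s < T) pr_alive <- pr_alive * (1 - phi[s])
    pr_det <- 1
    for (m in r:T) {
      pr_det <- pr_det * if (m <= s) {
        if (x[m] == 1) p[m] else 1 - p[m]
      } else {
        if (x[m] == 1) 0 else 1
      }
    }
    tot <- tot + pr_alive * pr_det
  }
  tot
}

# Brute-force total log-likelihood: per-individual forward product plus the
# never-seen term, all through the enumeration oracle.
brute_total_loglik <- function(histories, design, PHI, P) {
  g <- design$groups
  det <- as.matrix(histories[paste0("y", design$years)])
  gidx <- match(paste(histories$cohort, histories$telemetry_occasions),
                paste(g$cohort, g$telemetry_occasions))
  ll <- 0
  seen <- rowSums(det) > 0
  for (i in which(seen)) {
    j <- gidx[i]
    ll <- ll + log(brute_history_prob(det[i, ], PHI[j, ], P[j, ],
                                      g$release_occasion[j]))
  }
  M <- tabulate(gidx[seen], nbins = nrow(g))
  for (j in seq_len(nrow(g))) {
    unseen <- g$n_released[j] - M[j]
    if (unseen > 0) {
      z <- brute_history_prob(rep(0L, design$n_occasions), PHI[j, ], P[j, ],
                              g$release_occasion[j])
      ll <- ll + unseen * log(z)
    }
  }
  ll
}

# Small toy designs used across tests.
toy_design_2 <- function(n = 10) {
  suppressWarnings(build_design(
    tibble::tibble(cohort = 2015L, telemetry_occasions = 0L, n_released = n),
    years = 2015:2016, survey_years = 2015:2016
  ))
}

toy_design_3 <- function() {
  build_design(
    tibble::tibble(
      cohort = c(2015L, 2015L, 2016L),
      telemetry_occasions = c(2L, 0L, 0L),
      n_released = c(6L, 8L, 5L)
    ),
    years = 2015:2017, survey_years = 2015:2017
  )
}

# Canonical-history tibble from a matrix of detections.
make_histories <- function(det, cohort, telem, years) {
  df <- tibble::tibble(
    id = sprintf("i%03d", seq_len(nrow(det))),
    cohort = as.integer(cohort),
    telemetry_occasions = as.integer(telem)
  )
  for (k in seq_along(years)) df[[paste0("y", years[k])]] <- det[, k]
  df
}
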
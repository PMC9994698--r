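#' Never-seen and never-seen-again recursions
#'
#' Backward recursions over occasions for one group, with fixed detection
#' values already substituted:
#'
#' * `zeta[t]` is the probability an animal alive and present at occasion `t`
#'   is never detected at `t` or later:
#'   `zeta[T] = 1 - p[T]`, `zeta[t] = (1 - p[t]) * ((1 - phi[t]) + phi[t] * zeta[t+1])`.
#' * `chi[t]` is the probability an animal alive at occasion `t` is never
#'   detected after `t`:
#'   `chi[T] = 1`, `chi[t] = (1 - phi[t]) + phi[t] * (1 - p[t+1]) * chi[t+1]`.
#'
#' @param phi Survival probabilities per interval (length `T - 1`; entries
#'   before `start` may be `NA`).
#' @param p Detection probabilities per occasion (length `T`).
#' @param start First occasion the animal is present (its release occasion).
#' @return A list with vectors `zeta` and `chi` (entries before `start` are
#'   `NA`) .
#' @export
#' @examples
#' # two occasions, invisible at 1: die (0.2) or survive undetected (0.4)
#' nonencounter_recursion(phi = 0.8, p = c(0, 0.5), start = 1)$zeta[1]  # 0.6
nonencounter_recursion <- function(phi, p, start = 1L) {
  n_occ <- length(p)
  if (length(phi) != n_occ - 1L) {
    abort("`phi` must have length `length(p) - 1`.")
  }
  used_p <- p[start:n_occ]
  used_phi <- if (start <= n_occ - 1L) phi[start:(n_occ - 1L)] else numeric()
  if (any(!is.finite(used_p)) || any(used_p < 0 | used_p > 1) ||
      any(!is.finite(used_phi)) || any(used_phi < 0 | used_phi > 1)) {
    abort("Probabilities must lie in [0, 1].")
  }
  zeta <- rep(NA_real_, n_occ)
  chi <- rep(NA_real_, n_occ)
  zeta[n_occ] <- 1 - p[n_occ]
  chi[n_occ] <- 1
  t <- n_occ - 1L
  while (t >= start) {
    zeta[t] <- (1 - p[t]) * ((1 - phi[t]) + phi[t] * zeta[t + 1L])
    chi[t] <- (1 - phi[t]) + phi[t] * (1 - p[t + 1L]) * chi[t + 1L]
    t <- t - 1L
  }
  list(zeta = zeta, chi = chi)
}

#' Probability of one encounter history
#'
#' Probability of a binary detection history for an animal that entered the
#' population at occasion `start` (entry is deterministic: the release is
#' observed), given resolved per-interval survival `phi` and per-occasion
#' detection `p` for its group. For first detection `f` and last detection
#' `l`, the probability is the product of surviving undetected to `f`, the
#' detection/non-detection terms between `f` and `l`, and the probability
#' `chi[l]` of never being seen after `l`. The all-zero history has
#' probability `zeta[start]`.
#'
#' @param detections Integer 0/1 vector over all occasions.
#' @param phi,p,start As in [nonencounter_recursion()].
#' @return A probability.
#' @export
#' @examples
#' # telemetered over 3 occasions (p = 1): "110" means death in interval 2
#' history_probability(c(1, 1, 0), phi = c(0.9, 0.8), p = c(1, 1, 1))
#' # equals 0.9 * (1 - 0.8)
history_probability <- function(detections, phi, p, start = 1L) {
  n_occ <- length(p)
  stopifnot(length(detections) == n_occ)
  if (start > 1L && any(detections[seq_len(start - 1L)] == 1L)) {
    abort("Detection before the release occasion.")
  }
  rec <- nonencounter_recursion(phi, p, start)
  det_occ <- which(detections == 1L)
  if (!length(det_occ)) {
    return(rec$zeta[start])
  }
  f <- det_occ[1]
  l <- det_occ[length(det_occ)]
  prob <- 1
  if (f > start) {
    ks <- start:(f - 1L)
    prob <- prod((1 - p[ks]) * phi[ks])
  }
  prob <- prob * p[f]
  if (l > f) {
    for (k in f:(l - 1L)) {
      x <- detections[k + 1L]
      prob <- prob * phi[k] * (if (x == 1L) p[k + 1L] else 1 - p[k + 1L])
    }
  }
  prob * rec$chi[l]
}

# Aggregate observed histories by (group, distinct history) and attach the
# bookkeeping the likelihood needs. All-zero rows (released but never
# encountered) fold into the never-seen term alongside the
# n_released - M animals that have no row at all. Errors on data/design
# inconsistencies.
popan_group_data <- function(histories, design, years = design$years) {
  histories <- as_tibble(histories)
  g <- design$groups
  gidx <- match(
    paste(histories$cohort, histories$telemetry_occasions),
    paste(g$cohort, g$telemetry_occasions)
  )
  if (anyNA(gidx)) {
    bad <- histories$id[is.na(gidx)]
    abort(paste0("Individual(s) not matching any design group: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  det <- as.matrix(histories[detection_cols(years)])
  storage.mode(det) <- "integer"

  # detections at fixed-0 cells or before release are impossible
  fixed0 <- design$mask[gidx, , drop = FALSE] == MASK_FIXED_0
  bad_fix <- which(rowSums(det == 1L & fixed0) > 0)
  if (length(bad_fix)) {
    abort(paste0("Individual '", histories$id[bad_fix[1]],
                 "' detected at an occasion with detection fixed at 0."))
  }
  rel <- g$release_occasion[gidx]
  pre <- det == 1L &
    matrix(seq_len(ncol(det)), nrow(det), ncol(det), byrow = TRUE) <
      matrix(rel, nrow(det), ncol(det))
  bad_pre <- which(rowSums(pre) > 0)
  if (length(bad_pre)) {
    abort(paste0("Individual '", histories$id[bad_pre[1]],
                 "' detected before its release occasion."))
  }

  n_rows <- tabulate(gidx, nbins = nrow(g))
  if (any(n_rows > g$n_released)) {
    abort(paste0("More individuals than released in group(s): ",
                 paste(g$group_id[n_rows > g$n_released], collapse = ", ")))
  }
  seen <- rowSums(det) > 0
  M <- tabulate(gidx[seen], nbins = nrow(g))

  agg <- tibble(group = gidx[seen],
                hist = apply(det[seen, , drop = FALSE], 1,
                             paste, collapse = "")) %>%
    count(.data$group, .data$hist, name = "n_ind")
  hmat <- if (nrow(agg)) {
    do.call(rbind, lapply(strsplit(agg$hist, ""), as.integer))
  } else {
    matrix(integer(), 0L, design$n_occasions)
  }
  dat <- list(group = agg$group, hist = hmat, n_ind = agg$n_ind, M = M,
              n_histories = sum(seen), n_rows = nrow(histories))
  c(dat, history_cache(dat, design))
}

# Precompute, per distinct history, the index masks the vectorized
# likelihood needs: occasions/intervals before first detection (undetected
# survival), intervals between first and last detection, occasions after the
# first detection up to the last.
history_cache <- function(dat, design) {
  n <- length(dat$group)
  n_occ <- design$n_occasions
  f <- integer(n)
  l <- integer(n)
  U_occ <- matrix(0, n, n_occ)
  U_int <- matrix(0, n, n_occ - 1L)
  V_int <- matrix(0, n, n_occ - 1L)
  W_occ <- matrix(0, n, n_occ)
  for (i in seq_len(n)) {
    det_occ <- which(dat$hist[i, ] == 1L)
    f[i] <- det_occ[1]
    l[i] <- det_occ[length(det_occ)]
    r <- design$groups$release_occasion[dat$group[i]]
    if (f[i] > r) {
      U_occ[i, r:(f[i] - 1L)] <- 1
      U_int[i, r:(f[i] - 1L)] <- 1
    }
    if (l[i] > f[i]) {
      V_int[i, f[i]:(l[i] - 1L)] <- 1
      W_occ[i, (f[i] + 1L):l[i]] <- 1
    }
  }
  list(f = f, l = l, U_occ = U_occ, U_int = U_int, V_int = V_int,
       W_occ = W_occ)
}

#' Log-likelihood contribution of one group
#'
#' Sum of log history probabilities for the observed animals of a group plus
#' `(n_released - M) * log(zeta[release])` for the released-but-never-seen
#' animals. The multinomial coefficient, constant in the parameters, is
#' dropped.
#'
#' @param hist_mat Integer matrix of distinct observed histories (rows) by
#'   occasions (columns).
#' @param counts Number of individuals with each history.
#' @param n_released Fixed group superpopulation.
#' @param release_occasion Occasion of entry.
#' @param phi,p Resolved per-interval survival and per-occasion detection for
#'   the group.
#' @return Scalar log-likelihood component (can be `-Inf` for impossible
#'   data).
#' @export
group_loglik <- function(hist_mat, counts, n_released, release_occasion,
                         phi, p) {
  M <- sum(counts)
  if (M > n_released) abort("More observed individuals than released.")
  ll <- 0
  for (i in seq_len(nrow(hist_mat))) {
    pr <- history_probability(hist_mat[i, ], phi, p, release_occasion)
    ll <- ll + counts[i] * log(pr)
  }
  if (n_released > M) {
    z <- nonencounter_recursion(phi, p, release_occasion)$zeta[release_occasion]
    ll <- ll + (n_released - M) * log(z)
  }
  unname(ll)
}

#' Total log-likelihood of a model
#'
#' Transforms a link-scale parameter vector into survival and detection
#' probabilities for every cell of the design (substituting fixed values),
#' then sums the group log-likelihood components.
#'
#' @param histories Canonical encounter-history tibble (analysis set).
#' @param design A `popan_design`.
#' @param model A `popan_model` or model string.
#' @param theta Link-scale (logit) parameter vector of length `k`.
#' @return A list with `loglik`, `per_group` (named vector), and
#'   `dropped_constant = TRUE` (the multinomial coefficient is omitted).
#' @export
total_loglik <- function(histories, design, model, theta) {
  if (is.character(model)) model <- model_spec(model)
  prep <- prepare_model(design, model)
  dat <- popan_group_data(histories, design)
  total_loglik_prepared(prep, dat, theta, per_group = TRUE)
}

# Per-group evaluation via the readable per-history recursion; used for
# per-group diagnostics and as the reference the fast path is tested
# against.
total_loglik_groups <- function(prep, dat, theta) {
  res <- resolve_theta(prep, theta)
  g <- prep$design$groups
  per <- numeric(nrow(g))
  for (j in seq_len(nrow(g))) {
    rows <- which(dat$group == j)
    hm <- dat$hist[rows, , drop = FALSE]
    per[j] <- group_loglik(
      hm, dat$n_ind[rows], g$n_released[j], g$release_occasion[j],
      res$PHI[j, ], res$P[j, ]
    )
  }
  setNames(per, g$group_id)
}

LOG_CLAMP <- -700  # log-probability floor; exp() underflows to 0 anyway

clamped_log <- function(x) {
  out <- log(x)
  out[is.na(out)] <- 0       # cells outside a group's alive range
  pmax(out, LOG_CLAMP)
}

# Fast vectorized evaluation used by the optimizer.
total_loglik_prepared <- function(prep, dat, theta, per_group = FALSE) {
  if (per_group) {
    per <- total_loglik_groups(prep, dat, theta)
    return(list(loglik = sum(per), per_group = per,
                dropped_constant = TRUE))
  }
  res <- resolve_theta(prep, theta)
  g <- prep$design$groups
  G <- nrow(g)
  n_occ <- prep$design$n_occasions
  PHI <- res$PHI
  P <- res$P

  # backward recursions, vectorized over groups
  chi <- matrix(NA_real_, G, n_occ)
  zeta <- matrix(NA_real_, G, n_occ)
  chi[, n_occ] <- 1
  zeta[, n_occ] <- 1 - P[, n_occ]
  for (t in seq.int(n_occ - 1L, 1L)) {
    chi[, t] <- (1 - PHI[, t]) + PHI[, t] * (1 - P[, t + 1L]) * chi[, t + 1L]
    zeta[, t] <- (1 - P[, t]) * ((1 - PHI[, t]) + PHI[, t] * zeta[, t + 1L])
  }

  LP <- clamped_log(P)
  L1P <- clamped_log(1 - P)
  LPHI <- clamped_log(PHI)

  ll <- 0
  n <- length(dat$group)
  if (n > 0) {
    gi <- dat$group
    LPg <- LP[gi, , drop = FALSE]
    L1Pg <- L1P[gi, , drop = FALSE]
    LPHIg <- LPHI[gi, , drop = FALSE]
    X <- dat$hist
    A <- rowSums(dat$U_occ * L1Pg) + rowSums(dat$U_int * LPHIg)
    B <- LPg[cbind(seq_len(n), dat$f)]
    C <- rowSums(dat$V_int * LPHIg)
    D <- rowSums(dat$W_occ * (X * LPg + (1 - X) * L1Pg))
    E <- pmax(log(chi[cbind(gi, dat$l)]), LOG_CLAMP)
    ll <- sum(dat$n_ind * (A + B + C + D + E))
  }
  unseen <- g$n_released - dat$M
  zr <- zeta[cbind(seq_len(G), g$release_occasion)]
  pos <- unseen > 0
  ll + sum(unseen[pos] * pmax(log(zr[pos]), LOG_CLAMP))
}
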
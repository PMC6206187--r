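# Likelihood machinery for the dynamic occupancy model.
#
# State process: z[i,1] ~ Bern(psi_i); z[i,t+1] ~ Bern(z[i,t]*phi_t +
# (1-z[i,t])*gamma_t). Observation process: y[i,t,j] ~ Bern(z[i,t]*p_itj).
# Sites are independent, so the marginal likelihood factorizes over sites and
# each site is a two-state hidden Markov chain over seasons.

# Per-cell log P(y[i,t,] | z = 1) as an S x T matrix (0 for cells with no
# observed replicates), plus the detection indicator matrix.
cell_obs_loglik <- function(params, data, covs) {
  S <- data$n_sites; T_ <- data$n_seasons
  ll1 <- matrix(0, S, T_)
  oc <- if (sum(data$mask)) obs_covariates(data, covs) else NULL
  if (!is.null(oc) && nrow(oc)) {
    p <- detection_prob(params, oc)
    ll <- log_bern(oc$y, p)
    agg <- rowsum(ll, oc$cell)
    ll1[as.integer(rownames(agg))] <- agg
  }
  list(ll1 = ll1, det = detected_matrix(data))
}

#' Complete-data log likelihood
#'
#' Joint log probability of latent occupancy states `z` and observed
#' detections: Bernoulli terms for the initial states, the between-season
#' transitions, and every observed replicate (masked replicates are skipped).
#' Returns `-Inf` when `z` contradicts a detection (a detection at an
#' unoccupied site-season has probability zero).
#'
#' @param params A [dom_params()] state.
#' @param z Binary matrix `[n_sites, n_seasons]` of latent occupancy states.
#' @param data A [detection_history()].
#' @param covs A standardized [covariate_set()].
#' @return Scalar log likelihood.
#' @export
complete_data_loglik <- function(params, z, data, covs) {
  S <- data$n_sites; T_ <- data$n_seasons
  z <- matrix(z, S, T_)
  if (length(params$phi) != T_ - 1L)
    stop("phi/gamma length must be n_seasons - 1")
  psi <- psi_sites(params, covs, S)
  ll <- sum(log_bern(z[, 1], psi))
  for (t in seq_len(T_ - 1L)) {
    pr <- z[, t] * params$phi[t] + (1 - z[, t]) * params$gamma[t]
    ll <- ll + sum(log_bern(z[, t + 1], pr))
  }
  if (sum(data$mask)) {
    oc <- obs_covariates(data, covs)
    p <- detection_prob(params, oc)
    mu <- z[cbind(oc$site, oc$season)] * p
    ll <- ll + sum(log_bern(oc$y, mu))
  }
  ll
}

# Vectorized log(exp(a) + exp(b)) that is exact at -Inf.
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[!is.finite(m)] <- -Inf
  out
}

#' Marginal log likelihood (latent states summed out)
#'
#' Sums the complete-data likelihood over all latent occupancy
#' configurations by a per-site forward recursion over the two occupancy
#' states, in log space. Agrees with [brute_force_loglik()] to numerical
#' precision on any instance small enough to enumerate.
#'
#' @inheritParams complete_data_loglik
#' @return Scalar log likelihood of the observed detection history.
#' @export
marginal_loglik <- function(params, data, covs) {
  S <- data$n_sites; T_ <- data$n_seasons
  if (length(params$phi) != T_ - 1L)
    stop("phi/gamma length must be n_seasons - 1")
  co <- cell_obs_loglik(params, data, covs)
  ll0 <- ifelse(co$det == 1, -Inf, 0)   # P(y | z = 0): all-zero record or impossible
  ll1 <- co$ll1
  psi <- psi_sites(params, covs, S)
  la0 <- log1p(-psi) + ll0[, 1]
  la1 <- log(psi) + ll1[, 1]
  for (t in seq_len(T_ - 1L)) {
    f <- params$phi[t]; g <- params$gamma[t]
    new0 <- ll0[, t + 1] + logsumexp2(la0 + log1p(-g), la1 + log1p(-f))
    new1 <- ll1[, t + 1] + logsumexp2(la0 + log(g), la1 + log(f))
    la0 <- new0; la1 <- new1
  }
  sum(logsumexp2(la0, la1))
}

#' Brute-force marginal log likelihood (testing oracle)
#'
#' Enumerates all `2^(n_sites * n_seasons)` latent configurations and
#' log-sums the complete-data likelihood. Exponential cost; refuses designs
#' with more than 16 site-season cells. Kept deliberately independent of the
#' forward recursion so the two can check each other.
#'
#' @inheritParams complete_data_loglik
#' @return Scalar log likelihood.
#' @export
brute_force_loglik <- function(params, data, covs) {
  n_cells <- data$n_sites * data$n_seasons
  if (n_cells > 16L)
    stop("enumeration bound exceeded: n_sites * n_seasons must be <= 16")
  lls <- vapply(seq_len(2^n_cells) - 1L, function(k) {
    bits <- as.integer(intToBits(k))[seq_len(n_cells)]
    z <- matrix(bits, data$n_sites, data$n_seasons)
    complete_data_loglik(params, z, data, covs)
  }, numeric(1))
  logsumexp(lls)
}

#' Occupancy probability propagated across seasons
#'
#' `psi_{t+1} = psi_t * phi_t + (1 - psi_t) * gamma_t`.
#'
#' @param psi1 Initial occupancy probability (scalar or per-site vector).
#' @param phi,gamma Persistence / colonization per between-season interval.
#' @return Vector (scalar `psi1`) or matrix `[site, season]` of occupancy
#'   probabilities for all `length(phi) + 1` seasons.
#' @examples
#' recursive_occupancy(0.5, phi = c(1, 1), gamma = c(1, 1))  # 0.5 1 1
#' @export
recursive_occupancy <- function(psi1, phi, gamma) {
  stopifnot(length(phi) == length(gamma),
            all(psi1 >= 0 & psi1 <= 1),
            all(phi >= 0 & phi <= 1), all(gamma >= 0 & gamma <= 1))
  T_ <- length(phi) + 1L
  out <- matrix(NA_real_, length(psi1), T_)
  out[, 1] <- psi1
  for (t in seq_len(T_ - 1L))
    out[, t + 1] <- out[, t] * phi[t] + (1 - out[, t]) * gamma[t]
  if (length(psi1) == 1L) drop(out) else out
}
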
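# Generative simulator for study-like detection histories with known truth.

#' Deterministic fan-out of one master seed into stage seeds
#'
#' Pipeline stages (simulation, chains, diagnostics) each get their own seed
#' derived from the master seed, so any stage can be rerun in isolation and
#' still reproduce its output bit for bit. Results stay below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param k Stage index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 7919 + k * 104729) %% 2147483647)
}

# Table-like envelopes per depth stratum: depth (m, negative down), RDMV and
# seasonal maximum current (m/s) ranges observed across the three strata.
stratum_ranges <- list(
  shallow = list(depth = c(-23, -11), rdmv = c(0.14, 1.39), curmax = c(0.21, 0.24)),
  intermediate = list(depth = c(-43, -25), rdmv = c(0.06, 0.36), curmax = c(0.16, 0.23)),
  # deep sites sit below the 40 m canopy extinction depth by design
  deep = list(depth = c(-57, -40), rdmv = c(0.08, 0.67), curmax = c(0.16, 0.22))
)

#' Generate site covariates under a depth-stratified design
#'
#' Sites fall in three depth strata (shallow < 20 m, intermediate 20-40 m,
#' deep > 40 m) with covariates drawn uniformly within stratum-specific
#' envelopes. Bottom type is `"canopy"` where the seabed is shallower than
#' the canopy-algae extinction depth and `"none"` below it.
#'
#' @param n_sites Number of sites.
#' @param strata_fractions Named fractions (`shallow`, `intermediate`,
#'   `deep`) summing to 1; the default reproduces a 2/6/6 split at 14 sites.
#' @param canopy_depth_limit_m Algal extinction depth (positive metres).
#' @param seed Integer seed.
#' @return A [covariate_set()] with site-level covariates and a `stratum`
#'   column.
#' @export
generate_site_covariates <- function(n_sites = 14,
                                     strata_fractions = c(shallow = 2 / 14,
                                                          intermediate = 6 / 14,
                                                          deep = 6 / 14),
                                     canopy_depth_limit_m = 40, seed = 1L) {
  if (abs(sum(strata_fractions) - 1) > 1e-8)
    stop("`strata_fractions` must sum to 1")
  set.seed(seed)
  # largest-remainder apportionment of sites to strata
  raw <- strata_fractions * n_sites
  cnt <- floor(raw)
  left <- n_sites - sum(cnt)
  if (left > 0) {
    add <- order(raw - cnt, decreasing = TRUE)[seq_len(left)]
    cnt[add] <- cnt[add] + 1
  }
  stratum <- rep(names(strata_fractions), cnt)
  draw <- function(s, what) {
    r <- stratum_ranges[[s]][[what]]
    runif(1, r[1], r[2])
  }
  depth <- vapply(stratum, draw, numeric(1), what = "depth")
  rd <- vapply(stratum, draw, numeric(1), what = "rdmv")
  cm <- vapply(stratum, draw, numeric(1), what = "curmax")
  site <- data.frame(
    site_id = paste0("S", seq_len(n_sites)),
    depth_m = depth, rdmv = rd, curmax_ms = cm,
    bottom_type = ifelse(depth > -canopy_depth_limit_m, "canopy", "none"),
    stratum = stratum, row.names = NULL
  )
  covariate_set(site)
}

#' Generating parameters emulating the study's fitted model
#'
#' Detection coefficients are the study-scale values for a canopy/current
#' system (intercept -1.57, current -1.26, none 3.01, current:none 1.77,
#' effort -0.37 on the logit scale of standardized covariates); persistence
#' and colonization default to complement-of-extinction 0.44/0.56/0.85 and
#' 0.52/0.77/0.55 across the three between-season intervals.
#'
#' @param n_seasons Number of seasons.
#' @param model `"A"` (constant initial occupancy) or `"B"` (occupancy
#'   covariates).
#' @param effort Include the effort detection term?
#' @return A [dom_params()] truth state.
#' @export
default_truth_params <- function(n_seasons = 4, model = c("A", "B"),
                                 effort = TRUE) {
  model <- match.arg(model)
  alpha <- c(intercept = -1.57, current = -1.26, none = 3.01,
             current_none = 1.77)
  if (effort) alpha <- c(alpha, effort = -0.37)
  beta <- if (model == "A") c(intercept = 0.9) else
    c(intercept = 1.41, depth = -1.66, rdmv = 0.99, curmax = 0.04,
      curmax2 = 0.17)
  phi <- rep_len(c(0.44, 0.56, 0.85), n_seasons - 1L)
  gamma <- rep_len(c(0.52, 0.77, 0.55), n_seasons - 1L)
  dom_params(alpha = alpha, beta = beta, phi = phi, gamma = gamma)
}

#' Simulate detection histories under the generative model
#'
#' Draws latent occupancy states from the initial/transition model, assigns
#' each replicate a random observation time within its season window (equal
#' abutting blocks of the current series), looks up the bottom-current speed
#' nearest in time, draws sampling effort, and finally draws detections
#' `y ~ Bern(z * p)` with `p` evaluated on the standardized covariates.
#' The supplied parameters act on the standardized scale.
#'
#' @param params A [dom_params()] truth state.
#' @param site_covs A [covariate_set()] with site-level covariates.
#' @param field A [generate_tidal_series()] current field covering all sites.
#' @param n_seasons Number of seasons.
#' @param rep_probs Probabilities of 1, 2 or 3 replicates per site-season
#'   (default gives a mean of 2, maximum 3).
#' @param effort_range_min Uniform range of bottom time per replicate (min).
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @return Object of class `sim_truth`: the generating `params`, realized
#'   latent states `z`, the `data` ([detection_history()]), standardized
#'   `covs`, the `field`, and the `seed`.
#' @export
simulate_detection_histories <- function(params, site_covs, field,
                                         n_seasons = 4,
                                         rep_probs = c(0.25, 0.5, 0.25),
                                         effort_range_min = c(30, 90),
                                         seed = 1L) {
  S <- nrow(site_covs$site)
  if (ncol(field$speed) < S) stop("current field does not cover all sites")
  set.seed(seed)
  n_rep <- matrix(sample(1:3, S * n_seasons, replace = TRUE, prob = rep_probs),
                  S, n_seasons)
  J <- max(n_rep)
  span <- range(field$times)
  season_len <- diff(span) / n_seasons
  y <- obs_time <- eff <- cur <- array(NA_real_, dim = c(S, n_seasons, J))
  for (i in seq_len(S)) for (t in seq_len(n_seasons)) {
    j <- seq_len(n_rep[i, t])
    tt <- runif(length(j), span[1] + (t - 1) * season_len,
                span[1] + t * season_len)
    obs_time[i, t, j] <- tt
    cur[i, t, j] <- match_current_to_time(field, tt, i)
    eff[i, t, j] <- runif(length(j), effort_range_min[1], effort_range_min[2])
  }
  covs <- covariate_set(site_covs$site, current = cur, effort = eff)
  covs <- standardize_covariates(covs)
  # latent states
  psi <- psi_sites(params, covs, S)
  z <- matrix(0L, S, n_seasons)
  z[, 1] <- rbinom(S, 1, psi)
  for (t in seq_len(n_seasons - 1L))
    z[, t + 1] <- rbinom(S, 1, z[, t] * params$phi[t] +
                              (1 - z[, t]) * params$gamma[t])
  # observations
  mask <- !is.na(obs_time)
  dh0 <- detection_history(array(0, dim(y)) + ifelse(mask, 0, NA),
                           obs_time = obs_time, site_ids = site_covs$site$site_id)
  oc <- obs_covariates(dh0, covs)
  p <- detection_prob(params, oc)
  ydraw <- rbinom(nrow(oc), 1, z[cbind(oc$site, oc$season)] * p)
  yarr <- array(NA_real_, dim = dim(y))
  yarr[cbind(oc$site, oc$season, oc$replicate)] <- ydraw
  structure(
    list(params = params, z = z,
         data = detection_history(yarr, obs_time = obs_time,
                                  site_ids = site_covs$site$site_id),
         covs = covs, field = field, seed = seed),
    class = "sim_truth"
  )
}

#' Study-like synthetic fixture
#'
#' One call producing the default study-shaped dataset: 14 sites in a 2/6/6
#' depth-stratified design, 4 seasons, a mean of two (maximum three)
#' replicates per site-season, M2 tidal currents on a 20-minute step confined
#' to 0.01-0.31 m/s with inter-site lags up to an hour, and detection
#' histories generated under [default_truth_params()].
#'
#' @param seed Master seed; stage seeds are derived deterministically.
#' @param n_sites,n_seasons Design size.
#' @param params Generating truth (defaults to [default_truth_params()]).
#' @param strata_fractions Passed to [generate_site_covariates()].
#' @param rep_probs,effort_range_min Passed to
#'   [simulate_detection_histories()].
#' @param ... Passed to [generate_tidal_series()].
#' @return A `sim_truth` object.
#' @examples
#' sim <- simulate_study(seed = 1)
#' sim$data
#' @export
simulate_study <- function(seed = 1L, n_sites = 14, n_seasons = 4,
                           params = default_truth_params(n_seasons),
                           strata_fractions = c(shallow = 2 / 14,
                                                intermediate = 6 / 14,
                                                deep = 6 / 14),
                           rep_probs = c(0.25, 0.5, 0.25),
                           effort_range_min = c(30, 90), ...) {
  field <- generate_tidal_series(n_sites, seed = derive_seed(seed, 1L), ...)
  covs <- generate_site_covariates(n_sites, strata_fractions,
                                   seed = derive_seed(seed, 2L))
  simulate_detection_histories(params, covs, field, n_seasons,
                               rep_probs = rep_probs,
                               effort_range_min = effort_range_min,
                               seed = derive_seed(seed, 3L))
}
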
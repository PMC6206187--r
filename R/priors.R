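#' Prior configuration
#'
#' Logit-scale coefficients get weakly informative scaled t-distribution
#' priors; the default (mu = 0, sigma = 1.566, v = 7.763) is the
#' logistic-regression default of Dorazio-type weakly informative priors.
#' Persistence and colonization get uniform priors on [0, 1], and every
#' inclusion indicator a Bernoulli(0.5) prior.
#'
#' @param mu,sigma,df Location, scale (> 0) and degrees of freedom (> 0) of
#'   the coefficient prior.
#' @param name Optional label (used in sensitivity tables).
#' @return Object of class `prior_config`.
#' @export
prior_config <- function(mu = 0, sigma = 1.566, df = 7.763, name = "dorazio") {
  if (sigma <= 0) stop("prior `sigma` must be positive")
  if (df <= 0) stop("prior `df` must be positive")
  structure(list(mu = mu, sigma = sigma, df = df, name = name),
            class = "prior_config")
}

#' Named prior presets for the sensitivity analysis
#'
#' Three t-distribution priors recommended for logistic regression:
#' `"dorazio"` (0, 1.566, 7.763), `"firth_t"` (0, 2.5, 7) — the t
#' approximation to Jeffreys' prior — and `"gelman"` (0, 2.5, 1), a Cauchy.
#'
#' @param names Subset of the presets to return.
#' @return List of [prior_config()] objects.
#' @export
prior_presets <- function(names = c("dorazio", "firth_t", "gelman")) {
  all <- list(
    dorazio = prior_config(0, 1.566, 7.763, "dorazio"),
    firth_t = prior_config(0, 2.5, 7, "firth_t"),
    gelman = prior_config(0, 2.5, 1, "gelman")
  )
  all[match.arg(names, names(all), several.ok = TRUE)]
}

#' Scaled t-distribution density, CDF and sampler
#'
#' Location-scale t distribution used as the coefficient prior.
#'
#' @param x,q,n Evaluation points / sample size.
#' @param mu,sigma,df Location, scale, degrees of freedom.
#' @param log Return the log density?
#' @return Density, probability or random values.
#' @export
dst <- function(x, mu = 0, sigma = 1, df = 1, log = FALSE) {
  out <- dt((x - mu) / sigma, df, log = TRUE) - base::log(sigma)
  if (log) out else exp(out)
}

#' @rdname dst
#' @export
pst <- function(q, mu = 0, sigma = 1, df = 1) pt((q - mu) / sigma, df)

#' @rdname dst
#' @export
rst <- function(n, mu = 0, sigma = 1, df = 1) mu + sigma * rt(n, df)

#' Log prior density of a parameter state
#'
#' Scaled-t log densities for the intercepts and for each coefficient whose
#' inclusion indicator is 1, Bernoulli(0.5) mass for every indicator, and a
#' flat (0 / -Inf) contribution for persistence and colonization inside /
#' outside [0, 1].
#'
#' @param params A [dom_params()] state (or a compatible list).
#' @param prior A [prior_config()].
#' @return Scalar log prior density.
#' @export
log_prior <- function(params, prior) {
  if (length(params$phi) &&
      (any(params$phi < 0 | params$phi > 1) ||
       any(params$gamma < 0 | params$gamma > 1)))
    return(-Inf)
  wa <- params$w_alpha %||% setNames(rep(1, 0), character(0))
  wb <- params$w_beta %||% setNames(rep(1, 0), character(0))
  in_a <- c("intercept", names(wa)[wa == 1])
  in_b <- c("intercept", names(wb)[wb == 1])
  lp <- sum(dst(params$alpha[intersect(names(params$alpha), in_a)],
                prior$mu, prior$sigma, prior$df, log = TRUE)) +
    sum(dst(params$beta[intersect(names(params$beta), in_b)],
            prior$mu, prior$sigma, prior$df, log = TRUE)) +
    (length(wa) + length(wb)) * base::log(0.5)
  lp
}

#' Chain configuration
#'
#' Defaults match the full-scale analysis (5 chains of 50,000 draws, 10,000
#' burn-in, thinning 10). Scaled-down settings for interactive work are
#' obtained by overriding the fields, e.g. `chain_config(4, 4000, 1000, 3)`.
#'
#' @param n_chains Number of independent chains.
#' @param n_draws Total MCMC iterations per chain.
#' @param burn_in Iterations discarded (and used for proposal adaptation).
#' @param thin Store every `thin`-th post-burn-in draw.
#' @param proposal_scale Initial random-walk SD for coefficient updates
#'   (adapted during burn-in toward a 0.2-0.5 acceptance rate, then frozen).
#' @param seed Master seed; per-chain seeds are derived from it.
#' @return Object of class `chain_config`.
#' @export
chain_config <- function(n_chains = 5, n_draws = 50000, burn_in = 10000,
                         thin = 10, proposal_scale = 0.5, seed = 1L) {
  if (burn_in >= n_draws) stop("`burn_in` must be smaller than `n_draws`")
  if (thin < 1) stop("`thin` must be >= 1")
  structure(list(n_chains = n_chains, n_draws = n_draws, burn_in = burn_in,
                 thin = thin, proposal_scale = proposal_scale,
                 seed = as.integer(seed)),
            class = "chain_config")
}
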
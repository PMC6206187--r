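# Convergence, goodness of fit, identifiability and prior sensitivity.

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) PSRF from between- and within-chain variances:
#' `sqrt(((n-1)/n * W + B/n) / W)`, plus the Brooks-Gelman multivariate
#' version over the coefficient block, `sqrt((n-1)/n + (m+1)/m * lambda_1)`
#' with `lambda_1` the largest eigenvalue of `W^{-1} B/n`. Values below 1.1
#' are conventionally taken as converged. Accepts either a `dom_fit` (the
#' coefficient block is extracted per chain) or a list with one matrix
#' (iterations x parameters) or vector per chain.
#'
#' @param draws A `dom_fit` or a list of per-chain sample matrices/vectors.
#' @return List with `psrf` (named vector), `mpsrf` (scalar, `NA` when fewer
#'   than two non-constant parameters), `n`, `m`.
#' @examples
#' gelman_rubin(list(c(1, 2, 3), c(1, 2, 3)))$psrf  # sqrt(2/3)
#' @export
gelman_rubin <- function(draws) {
  if (inherits(draws, "dom_fit")) {
    d <- draws$draws
    mat <- cbind(d$alpha, beta = d$beta,
                 if (ncol(d$phi)) d$phi, if (ncol(d$gamma)) d$gamma)
    colnames(mat) <- c(
      paste0("alpha_", colnames(d$alpha)), paste0("beta_", colnames(d$beta)),
      if (ncol(d$phi)) paste0("phi_", seq_len(ncol(d$phi))),
      if (ncol(d$gamma)) paste0("gamma_", seq_len(ncol(d$gamma)))
    )
    draws <- lapply(unique(d$chain), function(ch) mat[d$chain == ch, , drop = FALSE])
  }
  if (!is.list(draws) || length(draws) < 2L)
    stop("at least two chains are required")
  draws <- lapply(draws, function(x) if (is.matrix(x)) x else matrix(x, ncol = 1))
  m <- length(draws)
  n <- nrow(draws[[1]])
  if (n < 2L) stop("chains must contain at least two draws")
  k <- ncol(draws[[1]])
  nms <- colnames(draws[[1]]) %||% paste0("par", seq_len(k))
  psrf <- setNames(numeric(k), nms)
  for (j in seq_len(k)) {
    xs <- vapply(draws, function(d) d[, j], numeric(n))
    W <- mean(apply(xs, 2, var))
    Bn <- var(colMeans(xs))          # B/n
    vplus <- (n - 1) / n * W + Bn
    psrf[j] <- if (W == 0) {
      if (Bn == 0) 1 else Inf
    } else sqrt(vplus / W)
  }
  # multivariate version over non-constant parameters
  keep <- vapply(seq_len(k), function(j)
    var(unlist(lapply(draws, function(d) d[, j]))) > 0, logical(1))
  mpsrf <- NA_real_
  if (sum(keep) >= 2L) {
    ds <- lapply(draws, function(d) d[, keep, drop = FALSE])
    W <- Reduce(`+`, lapply(ds, var)) / m
    mu <- t(vapply(ds, colMeans, numeric(sum(keep))))
    Bn <- var(mu)
    lam <- tryCatch(
      max(Re(eigen(solve(W, Bn), only.values = TRUE)$values)),
      error = function(e) NA_real_
    )
    if (is.finite(lam)) mpsrf <- sqrt((n - 1) / n + (m + 1) / m * lam)
  }
  list(psrf = psrf, mpsrf = mpsrf, n = n, m = m)
}

#' Posterior predictive tail probability from discrepancy pairs
#'
#' The Bayesian p-value is the proportion of posterior draws in which the
#' discrepancy of data simulated under the draw exceeds the observed
#' discrepancy; values near 0.5 indicate adequate fit.
#'
#' @param t_obs,t_sim Observed / simulated discrepancies, one per draw.
#' @return Scalar in [0, 1].
#' @export
pvalue_from_discrepancy <- function(t_obs, t_sim) {
  stopifnot(length(t_obs) == length(t_sim))
  mean(t_sim > t_obs)
}

#' Posterior predictive goodness of fit (Bayesian p-value)
#'
#' For each stored draw, data are simulated under that draw's parameters and
#' latent states (conditional replication: the draw's `z` is reused, so
#' residuals are defined at the observation level), and summed squared
#' Pearson residuals are computed for the observed and simulated records:
#' `r = (y - z p) / sqrt(z p (1 - z p) + 1e-6)`, the small constant guarding
#' unoccupied cells where mean and variance are both zero.
#'
#' @param fit A `dom_fit`.
#' @param n_draws Optional cap on the number of draws used (evenly thinned);
#'   default uses every stored draw.
#' @return Object of class `dom_gof`: `p_value`, per-draw `t_obs`, `t_sim`.
#' @export
bayesian_p_value <- function(fit, n_draws = NULL) {
  ctx <- make_ctx(fit$data, fit$covs, fit$model, fit$effort)
  if (!ctx$has_obs) stop("no observed replicates to assess fit against")
  d <- fit$draws
  ix <- seq_len(nrow(d$alpha))
  if (!is.null(n_draws) && n_draws < length(ix))
    ix <- ix[seq(1, length(ix), length.out = n_draws)]
  eps <- 1e-6
  t_obs <- t_sim <- numeric(length(ix))
  for (k in seq_along(ix)) {
    i <- ix[k]
    aeff <- d$alpha[i, ] *
      (if (ncol(d$w_alpha)) ew_alpha(ctx, d$w_alpha[i, ctx$sel_a])
       else rep(1, ncol(d$alpha)))
    p <- plogis(as.vector(ctx$X %*% aeff))
    zc <- d$z[i, , ][ctx$cell]
    mu <- zc * p
    v <- mu * (1 - mu) + eps
    t_obs[k] <- sum((ctx$y - mu)^2 / v)
    ysim <- rbinom(length(mu), 1, mu)
    t_sim[k] <- sum((ysim - mu)^2 / v)
  }
  structure(list(p_value = pvalue_from_discrepancy(t_obs, t_sim),
                 t_obs = t_obs, t_sim = t_sim),
            class = "dom_gof")
}

#' @export
print.dom_gof <- function(x, ...) {
  cat(sprintf("Bayesian p-value: %.3f (%d draws)\n", x$p_value, length(x$t_obs)))
  invisible(x)
}

#' Prior-posterior distributional overlap
#'
#' Percent overlap between the coefficient prior density and a kernel
#' estimate of the posterior: the integral of the pointwise minimum of the
#' two densities, by the trapezoid rule on a 1,024-point grid spanning both
#' distributions (out to the prior's 1e-4 tail quantiles). Parameters with
#' overlap below 35% are conventionally considered identifiable.
#'
#' @param draws Numeric vector of posterior draws for one parameter.
#' @param prior A [prior_config()].
#' @return Overlap in percent (0-100).
#' @export
prior_posterior_overlap <- function(draws, prior = prior_config()) {
  if (length(draws) < 500)
    stop("at least 500 draws are required for a stable overlap estimate")
  qlo <- prior$mu + prior$sigma * qt(1e-4, prior$df)
  qhi <- prior$mu + prior$sigma * qt(1 - 1e-4, prior$df)
  lo <- min(qlo, min(draws)); hi <- max(qhi, max(draws))
  kde <- density(draws, bw = "nrd0", n = 1024, from = lo, to = hi)
  pri <- dst(kde$x, prior$mu, prior$sigma, prior$df)
  h <- diff(kde$x[1:2])
  mn <- pmin(kde$y, pri)
  100 * sum((mn[-1] + mn[-length(mn)]) / 2) * h
}

#' Prior sensitivity analysis
#'
#' Refits the model under each prior configuration and tabulates posterior
#' means and SDs per parameter, plus the maximum absolute shift in posterior
#' means across priors (also expressed in units of each prior pair's larger
#' scale).
#'
#' @param data,covs,model,effort,chains As in [fit_dom()].
#' @param prior_set List of at least two [prior_config()] objects
#'   (default: the three standard logistic-regression priors).
#' @return Object of class `prior_sensitivity`: `table` (prior x parameter
#'   means/sds), `max_shift`, `max_shift_scaled`, and the `fits`.
#' @export
prior_sensitivity <- function(data, covs, model = "A", effort = TRUE,
                              prior_set = prior_presets(),
                              chains = chain_config(4, 4000, 1000, 3)) {
  if (length(prior_set) < 2L) stop("at least two prior configurations required")
  fits <- lapply(prior_set, function(pr)
    fit_dom(data, covs, model, effort, prior = pr, chains = chains))
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    s <- summary(fits[[i]])
    s <- s[s$submodel %in% c("detection", "occupancy"), ]
    data.frame(prior = prior_set[[i]]$name %||% paste0("prior", i),
               submodel = s$submodel, parameter = s$parameter,
               mean = s$mean, sd = s$sd,
               kept = is.na(s$inclusion) | s$inclusion > 0.5)
  }))
  wide <- split(tab, paste(tab$submodel, tab$parameter))
  shifts <- vapply(wide, function(g) diff(range(g$mean)), numeric(1))
  # excluded coefficients are pseudo-prior draws whose mean tracks the prior
  # by construction; the headline shift covers parameters estimated (kept or
  # intercept) under every prior
  est <- vapply(wide, function(g) all(g$kept), logical(1))
  if (!any(est)) est[] <- TRUE
  sig <- max(vapply(prior_set, function(p) p$sigma, numeric(1)))
  structure(list(table = tab, max_shift = max(shifts[est]),
                 max_shift_by_par = shifts,
                 max_shift_scaled = max(shifts[est]) / sig, fits = fits),
            class = "prior_sensitivity")
}

#' @export
print.prior_sensitivity <- function(x, ...) {
  cat(sprintf("Prior sensitivity over %d priors: max posterior-mean shift %.3f (%.2f prior-sd units)\n",
              length(unique(x$table$prior)), x$max_shift, x$max_shift_scaled))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Kolmogorov-Smirnov distance to a reference CDF
#'
#' Largest absolute difference between the empirical CDF of `x` and a
#' reference distribution function.
#'
#' @param x Numeric sample.
#' @param cdf Vectorized distribution function.
#' @return Scalar KS distance.
#' @export
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  f <- cdf(x)
  max(abs(c(seq_len(n) / n - f, f - (seq_len(n) - 1) / n)))
}
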
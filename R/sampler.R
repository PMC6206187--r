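# Metropolis-within-Gibbs sampler with latent-state data augmentation and
# Kuo-Mallick indicator variable selection.
#
# One iteration cycles: z (forward-filter backward-sample per site) ->
# phi/gamma (conjugate Beta given z transitions) -> detection coefficients
# (random-walk Metropolis; coefficients whose effective indicator is 0 are
# refreshed from the prior, which acts as the Kuo-Mallick pseudo-prior) ->
# detection indicators (exact Gibbs) -> occupancy coefficients -> occupancy
# indicators. Proposal scales adapt toward a 0.2-0.5 acceptance rate during
# burn-in only, so the post-burn-in kernel satisfies detailed balance.

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# sum of Bernoulli log likelihoods y*eta - log(1 + e^eta) (compiled kernel)
bern_ll <- function(y, eta) cpp_bern_ll(y, eta)

# Immutable per-fit context: design matrices and index plumbing.
make_ctx <- function(data, covs, model = "A", effort = TRUE) {
  S <- data$n_sites; T_ <- data$n_seasons
  a_names <- c("intercept", "current", "none", "current_none",
               if (effort) "effort")
  b_names <- if (model == "B")
    c("intercept", "depth", "rdmv", "curmax", "curmax2") else "intercept"
  has_obs <- sum(data$mask) > 0
  if (has_obs) {
    oc <- obs_covariates(data, covs)
    dummy <- dom_params(alpha = setNames(numeric(length(a_names)), a_names),
                        beta = c(intercept = 0),
                        phi = rep(0.5, T_ - 1L), gamma = rep(0.5, T_ - 1L))
    X <- detection_design(dummy, oc)
    y <- oc$y; cell <- oc$cell
  } else {
    X <- matrix(0, 0, length(a_names), dimnames = list(NULL, a_names))
    y <- numeric(0); cell <- integer(0)
  }
  Xb <- if (model == "B") {
    if (!isTRUE(covs$standardized)) stop("model B requires standardized covariates")
    cbind(intercept = 1, covs$site_std)
  } else matrix(1, S, 1, dimnames = list(NULL, "intercept"))
  det <- detected_matrix(data)
  sel_a <- setdiff(a_names, "intercept")
  # integer plumbing for fast effective-weight handling: position of each
  # selectable term in the alpha vector and in the w vector
  list(
    S = S, T_ = T_, y = y, cell = cell, X = X, Xb = Xb,
    a_names = a_names, b_names = b_names,
    sel_a = sel_a, sel_b = setdiff(b_names, "intercept"),
    apos = match(sel_a, a_names),
    wi = setNames(seq_along(sel_a), sel_a),
    det = det, ll0 = ifelse(det == 1, -Inf, 0), has_obs = has_obs,
    ucell = if (has_obs) sort(unique(cell)) else integer(0)
  )
}

# Effective alpha-column multipliers from the w vector (ordered as sel_a):
# intercept 1, each slope its indicator, interaction the triple product.
ew_alpha <- function(ctx, w) {
  ew <- rep(1, length(ctx$a_names))
  ew[ctx$apos] <- w
  if (!is.na(ctx$wi["current_none"]))
    ew[ctx$apos[ctx$wi["current_none"]]] <-
      w[ctx$wi["current"]] * w[ctx$wi["none"]] * w[ctx$wi["current_none"]]
  ew
}

ew_beta <- function(ctx, w) c(1, w)

# Per-cell log P(y | z = 1) given an eta vector over all observations.
ll1_from_eta <- function(ctx, eta) {
  if (!ctx$has_obs) return(matrix(0, ctx$S, ctx$T_))
  matrix(cpp_cell_ll(ctx$y, eta, ctx$cell, ctx$S * ctx$T_), ctx$S, ctx$T_)
}

# Forward-filter backward-sample the latent occupancy states of all sites
# (compiled two-state chain; uses R's RNG stream).
ffbs_draw <- function(ctx, psi, phi, gamma, ll1) {
  cpp_ffbs(ll1, ctx$ll0, psi, phi, gamma)
}

# Conjugate Beta updates for phi/gamma given latent transitions.
draw_phigamma <- function(z) {
  T_ <- ncol(z)
  phi <- gamma <- numeric(T_ - 1L)
  for (t in seq_len(T_ - 1L)) {
    occ <- z[, t] == 1L
    phi[t] <- rbeta(1, 1 + sum(z[occ, t + 1] == 1L), 1 + sum(z[occ, t + 1] == 0L))
    gamma[t] <- rbeta(1, 1 + sum(z[!occ, t + 1] == 1L), 1 + sum(z[!occ, t + 1] == 0L))
  }
  list(phi = phi, gamma = gamma)
}

# Random-walk Metropolis sweep over detection coefficients given the active
# (occupied-cell) observation subset; eta/ll are carried incrementally.
mh_alpha <- function(ctx, alpha, ew, Xact, yact, eta, ll, prior, scales) {
  accept <- rep(NA_real_, length(alpha))
  for (j in seq_along(alpha)) {
    if (ew[j] == 0) {                    # Kuo-Mallick pseudo-prior refresh
      alpha[j] <- rst(1, prior$mu, prior$sigma, prior$df)
      next
    }
    prop <- alpha[j] + scales[j] * rnorm(1)
    eta_new <- eta + Xact[, j] * (prop - alpha[j])
    ll_new <- bern_ll(yact, eta_new)
    lr <- ll_new - ll +
      dst(prop, prior$mu, prior$sigma, prior$df, log = TRUE) -
      dst(alpha[j], prior$mu, prior$sigma, prior$df, log = TRUE)
    if (is.finite(lr) && log(runif(1)) < lr) {
      alpha[j] <- prop; eta <- eta_new; ll <- ll_new
      accept[j] <- 1
    } else accept[j] <- 0
  }
  list(alpha = alpha, eta = eta, ll = ll, accept = accept)
}

# Exact Gibbs sweep over the detection inclusion indicators. Toggling an
# indicator shifts eta by the affected columns only; prior odds are 1.
gibbs_walpha <- function(ctx, alpha, w, Xact, yact, eta, ll) {
  wi <- ctx$wi
  for (nm in ctx$sel_a) {
    j <- wi[[nm]]
    cols <- switch(nm,
      current = c(ctx$apos[j],
                  if (!is.na(wi["current_none"]) &&
                      w[wi["current_none"]] == 1 && w[wi["none"]] == 1)
                    ctx$apos[wi["current_none"]]),
      none = c(ctx$apos[j],
               if (!is.na(wi["current_none"]) &&
                   w[wi["current_none"]] == 1 && w[wi["current"]] == 1)
                 ctx$apos[wi["current_none"]]),
      current_none = if (w[wi["current"]] == 1 && w[wi["none"]] == 1)
        ctx$apos[j],
      effort = ctx$apos[j]
    )
    if (is.null(cols) || !length(yact)) {   # term cannot act: conditional is the prior
      w[j] <- as.numeric(runif(1) < 0.5)
      next
    }
    v <- if (length(cols) == 1L) Xact[, cols] * alpha[cols]
         else as.vector(Xact[, cols, drop = FALSE] %*% alpha[cols])
    if (w[j] == 1) {
      ll_on <- ll
      eta_off <- eta - v
      ll_off <- bern_ll(yact, eta_off)
      eta_on <- eta
    } else {
      ll_off <- ll
      eta_on <- eta + v
      ll_on <- bern_ll(yact, eta_on)
      eta_off <- eta
    }
    w[j] <- as.numeric(runif(1) < plogis(ll_on - ll_off))
    if (w[j] == 1) { eta <- eta_on; ll <- ll_on }
    else { eta <- eta_off; ll <- ll_off }
  }
  list(w = w, eta = eta, ll = ll)
}

# Metropolis sweep over occupancy coefficients; the likelihood is the
# initial latent state z[,1] ~ Bern(psi).
mh_beta <- function(ctx, beta, ew, z1, prior, scales) {
  accept <- rep(NA_real_, length(beta))
  eta <- as.vector(ctx$Xb %*% (beta * ew))
  ll <- bern_ll(z1, eta)
  for (j in seq_along(beta)) {
    if (ew[j] == 0) {
      beta[j] <- rst(1, prior$mu, prior$sigma, prior$df)
      next
    }
    prop <- beta[j] + scales[j] * rnorm(1)
    eta_new <- eta + ctx$Xb[, j] * (prop - beta[j])
    ll_new <- bern_ll(z1, eta_new)
    lr <- ll_new - ll +
      dst(prop, prior$mu, prior$sigma, prior$df, log = TRUE) -
      dst(beta[j], prior$mu, prior$sigma, prior$df, log = TRUE)
    if (is.finite(lr) && log(runif(1)) < lr) {
      beta[j] <- prop; eta <- eta_new; ll <- ll_new
      accept[j] <- 1
    } else accept[j] <- 0
  }
  list(beta = beta, accept = accept)
}

gibbs_wbeta <- function(ctx, beta, w, z1) {
  for (j in seq_along(w)) {
    w1 <- w0 <- w
    w1[j] <- 1; w0[j] <- 0
    ll1 <- bern_ll(z1, as.vector(ctx$Xb %*% (beta * ew_beta(ctx, w1))))
    ll0 <- bern_ll(z1, as.vector(ctx$Xb %*% (beta * ew_beta(ctx, w0))))
    w[j] <- as.numeric(runif(1) < plogis(ll1 - ll0))
  }
  w
}

# Pull ordered w vectors out of a dom_params state.
w_vectors <- function(ctx, params) {
  list(a = as.numeric(params$w_alpha[ctx$sel_a]),
       b = as.numeric(params$w_beta[ctx$sel_b]))
}

#' One draw of the latent occupancy states from their full conditional
#'
#' Samples `z` exactly from its joint conditional given the parameters and
#' the detection history, by per-site forward filtering and backward
#' sampling over the two-state occupancy chain. Site-seasons with at least
#' one detection get `z = 1` with probability one.
#'
#' @param params A [dom_params()] state.
#' @param data A [detection_history()].
#' @param covs A standardized [covariate_set()].
#' @return Integer matrix `[n_sites, n_seasons]`.
#' @export
sample_latent_z <- function(params, data, covs) {
  effort <- "effort" %in% names(params$alpha)
  model <- if (length(params$beta) > 1) "B" else "A"
  ctx <- make_ctx(data, covs, model, effort)
  wv <- w_vectors(ctx, params)
  psi <- psi_sites(params, covs, ctx$S)
  aeff <- unname(params$alpha[ctx$a_names]) * ew_alpha(ctx, wv$a)
  eta <- if (ctx$has_obs) as.vector(ctx$X %*% aeff) else numeric(0)
  ffbs_draw(ctx, psi, params$phi, params$gamma, ll1_from_eta(ctx, eta))
}

#' One Metropolis sweep over the regression coefficients
#'
#' Updates every detection and occupancy coefficient by a random-walk
#' Metropolis step (symmetric Gaussian proposal, so the acceptance ratio
#' involves only posterior densities), conditional on the latent states in
#' `state$z`. Coefficients whose effective inclusion indicator is 0 are
#' refreshed from the prior (the Kuo-Mallick pseudo-prior).
#'
#' @param state List with elements `params` (a [dom_params()]) and `z`.
#' @param data A [detection_history()].
#' @param covs A standardized [covariate_set()].
#' @param prior A [prior_config()].
#' @param proposal_scales Scalar or vector of random-walk SDs.
#' @return List with updated `params` and an `accept` vector (NA for
#'   coefficients refreshed from the prior).
#' @export
sample_coefficients <- function(state, data, covs, prior = prior_config(),
                                proposal_scales = 0.5) {
  params <- state$params
  effort <- "effort" %in% names(params$alpha)
  model <- if (length(params$beta) > 1) "B" else "A"
  ctx <- make_ctx(data, covs, model, effort)
  wv <- w_vectors(ctx, params)
  z <- matrix(state$z, ctx$S, ctx$T_)
  act <- if (ctx$has_obs) z[ctx$cell] == 1L else logical(0)
  Xact <- ctx$X[act, , drop = FALSE]
  yact <- ctx$y[act]
  ew <- ew_alpha(ctx, wv$a)
  alpha <- unname(params$alpha[ctx$a_names])
  eta <- as.vector(Xact %*% (alpha * ew))
  ua <- mh_alpha(ctx, alpha, ew, Xact, yact, eta, bern_ll(yact, eta), prior,
                 rep_len(proposal_scales, length(alpha)))
  beta <- unname(params$beta[ctx$b_names])
  ub <- mh_beta(ctx, beta, ew_beta(ctx, wv$b), z[, 1], prior,
                rep_len(proposal_scales, length(beta)))
  params$alpha <- setNames(ua$alpha, ctx$a_names)
  params$beta <- setNames(ub$beta, ctx$b_names)
  list(params = params,
       accept = setNames(c(ua$accept, ub$accept),
                         c(ctx$a_names, paste0("beta_", ctx$b_names))))
}

#' One Gibbs sweep over the inclusion indicators
#'
#' Each indicator is drawn from its exact conditional: prior odds 1
#' (Bernoulli(0.5)) times the likelihood ratio with the term in versus out,
#' at the current coefficient values and latent states. The interaction's
#' effective contribution is `w_int * w_current * w_none`, so it is zero
#' whenever either main effect is out, in which case its conditional
#' inclusion probability is exactly 0.5.
#'
#' @inheritParams sample_coefficients
#' @return Updated `params`.
#' @export
sample_indicators <- function(state, data, covs, prior = prior_config()) {
  params <- state$params
  effort <- "effort" %in% names(params$alpha)
  model <- if (length(params$beta) > 1) "B" else "A"
  ctx <- make_ctx(data, covs, model, effort)
  wv <- w_vectors(ctx, params)
  z <- matrix(state$z, ctx$S, ctx$T_)
  act <- if (ctx$has_obs) z[ctx$cell] == 1L else logical(0)
  Xact <- ctx$X[act, , drop = FALSE]
  yact <- ctx$y[act]
  alpha <- unname(params$alpha[ctx$a_names])
  eta <- as.vector(Xact %*% (alpha * ew_alpha(ctx, wv$a)))
  ga <- gibbs_walpha(ctx, alpha, wv$a, Xact, yact, eta, bern_ll(yact, eta))
  params$w_alpha <- setNames(ga$w, ctx$sel_a)
  if (length(ctx$sel_b))
    params$w_beta <- setNames(
      gibbs_wbeta(ctx, unname(params$beta[ctx$b_names]), wv$b, z[, 1]),
      ctx$sel_b)
  params
}

#' Fit the dynamic occupancy model by MCMC
#'
#' Runs independent Metropolis-within-Gibbs chains with over-dispersed
#' starting values (coefficients from twice the prior scale; latent states
#' set to 1 wherever a detection occurred and Bernoulli(0.5) elsewhere;
#' persistence/colonization uniform; indicators Bernoulli(0.5)). Model A has
#' a constant initial occupancy probability; model B adds depth, RDMV,
#' seasonal maximum current and its square as occupancy covariates. Both
#' share the detection submodel (current speed, bottom type, their
#' interaction, and optionally effort).
#'
#' @param data A [detection_history()].
#' @param covs A [covariate_set()] (standardized automatically if needed).
#' @param model `"A"` or `"B"`.
#' @param effort Include the effort term in the detection submodel?
#' @param prior A [prior_config()].
#' @param chains A [chain_config()].
#' @param verbose Print per-chain progress?
#' @return Object of class `dom_fit` holding thinned post-burn-in draws of
#'   all parameters, indicators and latent states (`$draws`), acceptance
#'   rates, the configurations used, and the standardization constants.
#' @export
fit_dom <- function(data, covs, model = c("A", "B"), effort = TRUE,
                    prior = prior_config(), chains = chain_config(),
                    verbose = FALSE) {
  model <- match.arg(model)
  if (!isTRUE(covs$standardized)) covs <- standardize_covariates(covs)
  n_obs <- sum(data$mask)
  if (n_obs > 0 && max(reps_matrix(data)) < 2L)
    stop("model requires at least one site-season with more than one replicate")
  ctx <- make_ctx(data, covs, model, effort)
  n_store <- floor((chains$n_draws - chains$burn_in) / chains$thin)
  k_a <- length(ctx$a_names); k_b <- length(ctx$b_names)
  n_sa <- length(ctx$sel_a); n_sb <- length(ctx$sel_b)
  res <- vector("list", chains$n_chains)
  for (ch in seq_len(chains$n_chains)) {
    set.seed(derive_seed(chains$seed, ch))
    alpha <- rst(k_a, prior$mu, 2 * prior$sigma, prior$df)
    beta <- rst(k_b, prior$mu, 2 * prior$sigma, prior$df)
    w_a <- rbinom(n_sa, 1, 0.5)
    w_b <- rbinom(n_sb, 1, 0.5)
    phi <- runif(ctx$T_ - 1L); gamma <- runif(ctx$T_ - 1L)
    sa <- rep(chains$proposal_scale, k_a)
    sb <- rep(chains$proposal_scale, k_b)
    acc_a <- try_a <- rep(0, k_a); acc_b <- try_b <- rep(0, k_b)
    post_acc <- post_try <- rep(0, k_a + k_b)
    st <- list(
      alpha = matrix(NA_real_, n_store, k_a, dimnames = list(NULL, ctx$a_names)),
      beta = matrix(NA_real_, n_store, k_b, dimnames = list(NULL, ctx$b_names)),
      phi = matrix(NA_real_, n_store, ctx$T_ - 1L),
      gamma = matrix(NA_real_, n_store, ctx$T_ - 1L),
      w_alpha = matrix(NA_real_, n_store, n_sa, dimnames = list(NULL, ctx$sel_a)),
      w_beta = matrix(NA_real_, n_store, n_sb, dimnames = list(NULL, ctx$sel_b)),
      z = array(NA_integer_, dim = c(n_store, ctx$S, ctx$T_))
    )
    k_store <- 0L
    for (r in seq_len(chains$n_draws)) {
      ew <- ew_alpha(ctx, w_a)
      ewb <- ew_beta(ctx, w_b)[seq_len(k_b)]
      psi <- as.vector(plogis(ctx$Xb %*% (beta * ewb)))
      eta_full <- if (ctx$has_obs) as.vector(ctx$X %*% (alpha * ew)) else numeric(0)
      z <- ffbs_draw(ctx, psi, phi, gamma, ll1_from_eta(ctx, eta_full))
      if (ctx$T_ > 1L) {
        pg <- draw_phigamma(z)
        phi <- pg$phi; gamma <- pg$gamma
      }
      act <- if (ctx$has_obs) z[ctx$cell] == 1L else logical(0)
      Xact <- ctx$X[act, , drop = FALSE]
      yact <- ctx$y[act]
      eta <- eta_full[act]
      ua <- mh_alpha(ctx, alpha, ew, Xact, yact, eta, bern_ll(yact, eta),
                     prior, sa)
      alpha <- ua$alpha
      ga <- gibbs_walpha(ctx, alpha, w_a, Xact, yact, ua$eta, ua$ll)
      w_a <- ga$w
      ub <- mh_beta(ctx, beta, ewb, z[, 1], prior, sb)
      beta <- ub$beta
      if (n_sb) w_b <- gibbs_wbeta(ctx, beta, w_b, z[, 1])
      if (anyNA(alpha) || anyNA(beta)) stop("NaN encountered in posterior state")
      accs <- c(ua$accept, ub$accept)
      if (r <= chains$burn_in) {
        acc_a <- acc_a + ifelse(is.na(ua$accept), 0, ua$accept)
        try_a <- try_a + !is.na(ua$accept)
        acc_b <- acc_b + ifelse(is.na(ub$accept), 0, ub$accept)
        try_b <- try_b + !is.na(ub$accept)
        if (r %% 50 == 0) {          # adapt only during burn-in
          ra <- ifelse(try_a > 0, acc_a / pmax(try_a, 1), 0.35)
          sa <- sa * ifelse(ra > 0.5, 1.3, ifelse(ra < 0.2, 0.7, 1))
          rb <- ifelse(try_b > 0, acc_b / pmax(try_b, 1), 0.35)
          sb <- sb * ifelse(rb > 0.5, 1.3, ifelse(rb < 0.2, 0.7, 1))
          acc_a[] <- try_a[] <- acc_b[] <- try_b[] <- 0
        }
      } else {
        post_acc <- post_acc + ifelse(is.na(accs), 0, accs)
        post_try <- post_try + !is.na(accs)
        if ((r - chains$burn_in) %% chains$thin == 0 && k_store < n_store) {
          k_store <- k_store + 1L
          st$alpha[k_store, ] <- alpha
          st$beta[k_store, ] <- beta
          if (ctx$T_ > 1L) { st$phi[k_store, ] <- phi; st$gamma[k_store, ] <- gamma }
          if (n_sa) st$w_alpha[k_store, ] <- w_a
          if (n_sb) st$w_beta[k_store, ] <- w_b
          st$z[k_store, , ] <- z
        }
      }
    }
    st$acceptance <- setNames(ifelse(post_try > 0, post_acc / post_try, NA_real_),
                              c(ctx$a_names, paste0("beta_", ctx$b_names)))
    res[[ch]] <- st
    if (verbose)
      message(sprintf("chain %d/%d done (%d stored draws)", ch,
                      chains$n_chains, k_store))
  }
  bind <- function(fld) do.call(rbind, lapply(res, `[[`, fld))
  zall <- array(NA_integer_, dim = c(n_store * chains$n_chains, ctx$S, ctx$T_))
  for (ch in seq_len(chains$n_chains))
    zall[(ch - 1L) * n_store + seq_len(n_store), , ] <- res[[ch]]$z
  structure(
    list(
      model = model, effort = effort, prior = prior, chains = chains,
      data = data, covs = covs,
      draws = list(
        alpha = bind("alpha"), beta = bind("beta"),
        phi = bind("phi"), gamma = bind("gamma"),
        w_alpha = bind("w_alpha"), w_beta = bind("w_beta"),
        z = zall,
        chain = rep(seq_len(chains$n_chains), each = n_store)
      ),
      acceptance = do.call(rbind, lapply(res, `[[`, "acceptance")),
      constants = covs$constants, n_store = n_store
    ),
    class = "dom_fit"
  )
}

#' @export
print.dom_fit <- function(x, ...) {
  cat(sprintf(
    "Dynamic occupancy model %s (%s effort term): %d chains x %d stored draws\n",
    x$model, if (x$effort) "with" else "without", x$chains$n_chains, x$n_store
  ))
  print(summary(x))
  invisible(x)
}

#' Posterior summary table
#'
#' One row per coefficient and turnover parameter: posterior mean, SD, 95%
#' credible interval and (for selectable terms) the posterior inclusion
#' probability, the interaction reported through its effective product
#' indicator.
#'
#' @param object A `dom_fit`.
#' @param ... Unused.
#' @return `data.frame` with columns `submodel`, `parameter`, `mean`, `sd`,
#'   `q2.5`, `q97.5`, `inclusion`.
#' @export
summary.dom_fit <- function(object, ...) {
  d <- object$draws
  incl <- inclusion_summary(object)
  row <- function(sub, nm, v, w = NA_real_) data.frame(
    submodel = sub, parameter = nm, mean = mean(v), sd = sd(v),
    q2.5 = unname(quantile(v, 0.025)), q97.5 = unname(quantile(v, 0.975)),
    inclusion = w
  )
  pick <- function(sub, nm) {
    hit <- incl$submodel == sub & incl$term == nm
    if (any(hit)) incl$inclusion[hit] else NA_real_
  }
  out <- list()
  for (nm in colnames(d$alpha))
    out[[length(out) + 1L]] <- row("detection", nm, d$alpha[, nm],
                                   pick("detection", nm))
  for (nm in colnames(d$beta))
    out[[length(out) + 1L]] <- row("occupancy", nm, d$beta[, nm],
                                   pick("occupancy", nm))
  if (ncol(d$phi))
    for (t in seq_len(ncol(d$phi))) {
      out[[length(out) + 1L]] <- row("turnover", paste0("phi_", t), d$phi[, t])
      out[[length(out) + 1L]] <- row("turnover", paste0("gamma_", t), d$gamma[, t])
    }
  do.call(rbind, out)
}
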
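# Conditional-distribution checks for the Gibbs blocks, a grid-posterior
# oracle for the Metropolis kernel, and structural invariants of fits.

test_that("latent states always respect detections", {
  y <- array(NA_real_, c(3, 2, 2))
  y[1, 1, 1] <- 1; y[2, 1, 1] <- 0; y[3, 2, 1] <- 1; y[1, 2, 1] <- 0
  dh <- detection_history(y)
  covs <- manual_covs(3, 2, 2)
  pars <- toy_params(psi = 0.4, phi = 0.6, gamma = 0.3)
  set.seed(1)
  for (k in 1:50) {
    z <- sample_latent_z(pars, dh, covs)
    expect_true(z[1, 1] == 1 && z[3, 2] == 1)
  }
})

test_that("z full conditional matches Bayes' rule by hand", {
  # single season, psi = 0.5, one replicate with p = 0.5, y = 0:
  # P(z=1 | y) = 0.25 / 0.75 = 1/3
  dh <- detection_history(array(0, c(1, 1, 1)))
  covs <- manual_covs(1, 1, 1)
  pars <- toy_params(psi = 0.5)
  set.seed(2)
  zs <- replicate(6000, sample_latent_z(pars, dh, covs)[1, 1])
  expect_lt(abs(mean(zs) - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 6000))
  # detection probability ~ 0: the data carry no information, P(z=1) = psi
  pars0 <- toy_params(psi = 0.5, p_intercept = -40)
  zs0 <- replicate(6000, sample_latent_z(pars0, dh, covs)[1, 1])
  expect_lt(abs(mean(zs0) - 0.5), 3 * sqrt(0.25 / 6000))
})

test_that("vanishing proposal scale drives Metropolis acceptance to one", {
  inst <- random_instance(7)
  state <- list(params = inst$params,
                z = sample_latent_z(inst$params, inst$data, inst$covs))
  set.seed(3)
  acc <- replicate(100, {
    out <- sample_coefficients(state, inst$data, inst$covs,
                               proposal_scales = 1e-10)
    mean(out$accept, na.rm = TRUE)
  })
  expect_gt(mean(acc), 0.999)
})

test_that("sampled posterior matches the brute-force grid posterior", {
  # 2 sites x 2 seasons, all parameters fixed except the detection
  # intercept; its marginal from (alpha1, z) Gibbs must match the exact
  # grid posterior prior(a) * exp(marginal_loglik(a)).
  set.seed(4)
  y <- array(NA_real_, c(2, 2, 2))
  y[, , 1] <- c(1, 0, 0, 1); y[, , 2] <- c(0, 0, 1, NA)
  dh <- detection_history(y)
  covs <- manual_covs(2, 2, 2)
  base <- toy_params(psi = 0.6, phi = 0.7, gamma = 0.4,
                     w_alpha = c(current = 0, none = 0, current_none = 0))
  prior <- prior_config()
  ctx <- occutide:::make_ctx(dh, covs, "A", effort = FALSE)
  psi <- rep(0.6, 2)
  a <- 0
  draws <- numeric(40000)
  for (r in seq_along(draws)) {
    eta_full <- rep(a, length(ctx$y))
    ll1 <- occutide:::ll1_from_eta(ctx, eta_full)
    z <- occutide:::ffbs_draw(ctx, psi, base$phi, base$gamma, ll1)
    act <- z[ctx$cell] == 1
    up <- occutide:::mh_alpha(ctx, c(a, 0, 0, 0), c(1, 0, 0, 0),
                              ctx$X[act, , drop = FALSE], ctx$y[act],
                              rep(a, sum(act)),
                              occutide:::bern_ll(ctx$y[act], rep(a, sum(act))),
                              prior, rep(2, 4))
    a <- up$alpha[1]
    draws[r] <- a
  }
  draws <- draws[-(1:2000)]
  # exact posterior on a fine grid
  grid <- seq(-8, 8, by = 0.02)
  logpost <- vapply(grid, function(g) {
    p <- base
    p$alpha["intercept"] <- g
    dst(g, prior$mu, prior$sigma, prior$df, log = TRUE) +
      marginal_loglik(p, dh, covs)
  }, numeric(1))
  post <- exp(logpost - max(logpost))
  post <- post / sum(post)
  breaks <- quantile(grid, probs = seq(0, 1, length.out = 11))
  bin_exact <- tapply(post, cut(grid, breaks, include.lowest = TRUE), sum)
  bin_mcmc <- table(cut(draws, breaks, include.lowest = TRUE)) / length(draws)
  tv <- 0.5 * sum(abs(as.numeric(bin_exact) - as.numeric(bin_mcmc)), na.rm = TRUE)
  expect_lt(tv, 0.05)
})

test_that("a zero coefficient has conditional inclusion probability one half", {
  inst <- random_instance(11)
  pars <- inst$params
  pars$alpha["current"] <- 0
  pars$w_alpha[] <- 1
  state <- list(params = pars,
                z = sample_latent_z(pars, inst$data, inst$covs))
  set.seed(5)
  ws <- replicate(2000, sample_indicators(state, inst$data,
                                          inst$covs)$w_alpha["current"])
  expect_lt(abs(mean(ws) - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("the interaction only acts when both main effects are in", {
  pars <- toy_params(psi = 0.5, current = -1.2, none = 3, current_none = 1.8,
                     w_alpha = c(current = 0, none = 1, current_none = 1))
  # with w_current = 0 the interaction's effective contribution vanishes
  p1 <- detection_prob(pars, list(current = 1.5, none = 1))
  pars$alpha["current_none"] <- -4
  expect_equal(detection_prob(pars, list(current = 1.5, none = 1)), p1)
})

test_that("fits keep probabilities in bounds and z consistent with detections", {
  sim <- simulate_study(seed = 6)
  fit <- fit_dom(sim$data, sim$covs, "A",
                 chains = chain_config(2, 800, 200, 2, seed = 8))
  expect_true(all(fit$draws$phi >= 0 & fit$draws$phi <= 1))
  expect_true(all(fit$draws$gamma >= 0 & fit$draws$gamma <= 1))
  det <- occutide:::detected_matrix(sim$data)
  for (i in seq_len(nrow(fit$draws$alpha)))
    expect_true(all(fit$draws$z[i, , ][det == 1] == 1L))
  expect_equal(nrow(fit$draws$alpha), 2 * floor(600 / 2))
  # refusing a design with no repeat visits
  y <- array(NA_real_, c(3, 2, 1)); y[, , 1] <- 0
  expect_error(fit_dom(detection_history(y), manual_covs(3, 2, 1), "A"),
               "more than one replicate")
})

test_that("occupancy covariates absent from the truth are not selected", {
  # at the study's 14-site scale, model B fitted to data generated with a
  # constant psi leaves every occupancy indicator equivocal (near 0.5),
  # with larger designs pushing null terms further out, never in
  sim <- simulate_study(seed = 31)    # truth has no occupancy covariates
  fit <- fit_dom(sim$data, sim$covs, "B",
                 chains = chain_config(4, 2000, 500, 3, seed = 32))
  incl <- inclusion_summary(fit)
  binc <- incl$inclusion[incl$submodel == "occupancy"]
  expect_true(all(binc > 0.25 & binc < 0.75))
  expect_true(all(!incl$keep[incl$submodel == "occupancy"] |
                    binc <= 0.75))
})
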
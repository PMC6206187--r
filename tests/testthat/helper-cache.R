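# Expensive shared computations (the replicate recovery study and the
# study-shaped fixture fit) are computed once per test run and reused by
# every test that needs them.

.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache))
    assign(key, force(expr), envir = .fit_cache)
  get(key, envir = .fit_cache)
}

recovery_truth_alpha <- c(intercept = -1.5, current = -1.2, none = 3.0,
                          current_none = 1.8)

# Simulate one 200-site, 4-season, 3-replicate dataset under a strong
# detection signal (plus a truly null effort term), fit model A, and keep
# compact summaries only.
one_recovery_run <- function(k) {
  truth <- dom_params(
    alpha = c(recovery_truth_alpha, effort = 0),
    beta = c(intercept = 0.9),
    phi = c(0.44, 0.56, 0.85), gamma = c(0.52, 0.77, 0.55)
  )
  sim <- simulate_study(
    seed = 1000 + k, n_sites = 200,
    strata_fractions = c(shallow = 1 / 7, intermediate = 3 / 7, deep = 3 / 7),
    params = truth, rep_probs = c(0, 0, 1)
  )
  fit <- fit_dom(sim$data, sim$covs, "A", effort = TRUE,
                 chains = chain_config(4, 4000, 1000, 3, seed = 2000 + k))
  s <- summary(fit)
  det <- s[s$submodel == "detection", ]
  incl <- inclusion_summary(fit)
  set.seed(3000 + k)
  gof <- bayesian_p_value(fit, n_draws = 400)
  # posterior-mean detection curves and bottom-type difference over the
  # observed current range
  cc <- fit$constants$current_ms
  r <- range(fit$covs$current, na.rm = TRUE)
  cg <- seq(r[1], r[2], length.out = 41)
  cstd <- (cg - cc$center) / cc$scale
  pn <- colMeans(occutide:::p_draws_at(fit, cstd, rep(1, 41)))
  pc <- colMeans(occutide:::p_draws_at(fit, cstd, rep(0, 41)))
  dd <- detection_difference(fit, currents_ms = cg)
  list(
    mean = setNames(det$mean, det$parameter),
    lo = setNames(det$q2.5, det$parameter),
    hi = setNames(det$q97.5, det$parameter),
    inclusion = setNames(incl$inclusion, incl$term),
    gof_p = gof$p_value,
    p_none = pn, p_canopy = pc,
    includes_zero = !dd$excludes_zero
  )
}

recovery_runs <- function() cached("recovery", lapply(1:20, one_recovery_run))

# Study-shaped fixture (14 sites) fitted at scaled chain settings.
fixture_fit <- function() cached("fixture_fit", {
  sim <- simulate_study(seed = 1)
  fit_dom(sim$data, sim$covs, "A",
          chains = chain_config(4, 4000, 1000, 3, seed = 11))
})
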
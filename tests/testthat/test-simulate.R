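test_that("site covariates honour the stratified design and the canopy rule", {
  cv <- generate_site_covariates(14, seed = 5)
  expect_equal(as.vector(table(cv$site$stratum)[c("shallow", "intermediate", "deep")]),
               c(2L, 6L, 6L))
  # canopy iff shallower than the 40 m extinction depth
  expect_equal(cv$site$bottom_type, ifelse(cv$site$depth_m > -40, "canopy", "none"))
  expect_true(all(cv$site$bottom_type[cv$site$stratum == "deep"] == "none"))
  expect_true(all(cv$site$bottom_type[cv$site$stratum == "shallow"] == "canopy"))
  # all sites shallower than the limit -> all canopy
  cv2 <- generate_site_covariates(6, strata_fractions = c(
    shallow = 1, intermediate = 0, deep = 0), seed = 5)
  expect_true(all(cv2$site$bottom_type == "canopy"))
  expect_error(generate_site_covariates(5, strata_fractions = c(
    shallow = 0.5, intermediate = 0.4, deep = 0.2)), "sum to 1")
})

test_that("degenerate truths produce the forced histories", {
  field <- generate_tidal_series(4, duration_days = 8, seed = 1)
  cv <- generate_site_covariates(4, strata_fractions = c(
    shallow = 0.25, intermediate = 0.5, deep = 0.25), seed = 2)
  # psi = 1, p = 1 -> every replicate a detection
  sure <- dom_params(alpha = c(intercept = 60, current = 0, none = 0,
                               current_none = 0, effort = 0),
                     beta = c(intercept = 60),
                     phi = rep(1, 2), gamma = rep(0, 2))
  s1 <- simulate_detection_histories(sure, cv, field, n_seasons = 3, seed = 3)
  expect_true(all(s1$data$y[s1$data$mask] == 1))
  # phi = gamma = 0 -> nothing occupied after season one
  dead <- dom_params(alpha = c(intercept = 0, current = 0, none = 0,
                               current_none = 0, effort = 0),
                     beta = c(intercept = 0.9),
                     phi = rep(0, 2), gamma = rep(0, 2))
  s2 <- simulate_detection_histories(dead, cv, field, n_seasons = 3, seed = 4)
  expect_true(all(s2$z[, -1] == 0))
})

test_that("simulated initial occupancy matches psi within binomial error", {
  field <- generate_tidal_series(2000, duration_days = 4, seed = 6)
  cv <- generate_site_covariates(2000, seed = 7)
  truth <- dom_params(alpha = c(intercept = 0, current = 0, none = 0,
                                current_none = 0, effort = 0),
                      beta = c(intercept = qlogis(0.6)),
                      phi = 0.5, gamma = 0.5)
  s <- simulate_detection_histories(truth, cv, field, n_seasons = 2,
                                    seed = 8)
  # 3 binomial SDs at n = 2000: 0.6 +/- 0.033
  expect_lt(abs(mean(s$z[, 1]) - 0.6), 0.033)
})

test_that("latent transition frequencies converge to phi and gamma", {
  field <- generate_tidal_series(1000, duration_days = 4, seed = 9)
  cv <- generate_site_covariates(1000, seed = 10)
  truth <- dom_params(alpha = c(intercept = 0, current = 0, none = 0,
                                current_none = 0, effort = 0),
                      beta = c(intercept = qlogis(0.5)),
                      phi = c(0.44, 0.85), gamma = c(0.52, 0.3))
  s <- simulate_detection_histories(truth, cv, field, n_seasons = 3, seed = 11)
  for (t in 1:2) {
    occ <- s$z[, t] == 1
    phat <- mean(s$z[occ, t + 1])
    ghat <- mean(s$z[!occ, t + 1])
    expect_lt(abs(phat - truth$phi[t]), 3 * sqrt(0.25 / sum(occ)))
    expect_lt(abs(ghat - truth$gamma[t]), 3 * sqrt(0.25 / sum(!occ)))
  }
})

test_that("simulation is bit-reproducible under one seed", {
  s1 <- simulate_study(seed = 21)
  s2 <- simulate_study(seed = 21)
  expect_identical(s1$data$y, s2$data$y)
  expect_identical(s1$z, s2$z)
  expect_identical(s1$covs$site, s2$covs$site)
  expect_identical(s1$field$speed, s2$field$speed)
})

test_that("the default fixture reproduces the study envelope", {
  sim <- simulate_study(seed = 1)
  dh <- sim$data
  expect_equal(dh$n_sites, 14L)
  expect_equal(dh$n_seasons, 4L)
  expect_lte(dh$max_reps, 3L)
  nreps <- sum(dh$mask) / (14 * 4)
  expect_lt(abs(nreps - 2), 0.35)          # mean ~2 replicates
  expect_equal(as.vector(table(sim$covs$site$stratum)[
    c("shallow", "intermediate", "deep")]), c(2L, 6L, 6L))
  expect_gte(min(sim$field$speed), 0.01)
  expect_lte(max(sim$field$speed), 0.31)
  expect_equal(sim$field$period_s, 12.42 * 3600)
  expect_equal(sim$field$step_s, 20 * 60)
  expect_lte(max(sim$field$lag_s), 3600)
  # observed currents attached to replicates stay inside the envelope
  cur <- sim$covs$current[!is.na(sim$covs$current)]
  expect_true(all(cur >= 0.01 & cur <= 0.31))
})
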
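# Closed-form values below were computed by hand from the Bernoulli
# state-space factorization; the brute-force enumerator is the independent
# oracle for everything the forward recursion computes.

test_that("detection and occupancy probabilities match closed forms", {
  p <- dom_params(
    alpha = c(intercept = -1.57, current = -1.26, none = 3.01,
              current_none = 1.77),
    beta = c(intercept = 1.41, depth = -1.66, rdmv = 0.99, curmax = 0.04,
             curmax2 = 0.17)
  )
  # all covariates at their means
  expect_equal(occupancy_prob(p, list(depth = 0, rdmv = 0, curmax = 0)),
               plogis(1.41), tolerance = 1e-12)
  expect_equal(occupancy_prob(p, list(depth = 0, rdmv = 0, curmax = 0)),
               0.8038, tolerance = 1e-3)
  # indicator zeroing: all slopes out leaves the intercept
  p0 <- dom_params(p$alpha, p$beta,
                   w_beta = setNames(rep(0, 4), names(p$beta)[-1]))
  expect_equal(occupancy_prob(p0, list(depth = 3, rdmv = -2, curmax = 1)),
               plogis(1.41), tolerance = 1e-12)
  # p at current 1 on the canopy-free bottom
  expect_equal(detection_prob(p, list(current = 1, none = 1)),
               plogis(-1.57 - 1.26 + 3.01 + 1.77), tolerance = 1e-12)
  expect_equal(detection_prob(p, list(current = 1, none = 1)),
               0.8755, tolerance = 1e-3)
  # canopy at mean current
  expect_equal(detection_prob(p, list(current = 0, none = 0)),
               plogis(-1.57), tolerance = 1e-12)
  z <- dom_params(alpha = c(intercept = 0, current = 0, none = 0,
                            current_none = 0))
  expect_equal(detection_prob(z, list(current = 2.3, none = 1)), 0.5)
})

test_that("probabilities are monotone in each covariate per coefficient sign", {
  p <- dom_params(
    alpha = c(intercept = -1.5, current = -1.2, none = 3.0, current_none = 1.8),
    beta = c(intercept = 1.4, depth = -1.7, rdmv = 1.0, curmax = 0.5,
             curmax2 = 0.2)
  )
  cur <- seq(-2, 2, length.out = 9)
  expect_true(all(diff(detection_prob(
    p, list(current = cur, none = rep(0, 9)))) < 0))          # alpha2 < 0
  expect_true(all(diff(detection_prob(
    p, list(current = cur, none = rep(1, 9)))) > 0))          # alpha2+alpha4 > 0
  dep <- seq(-2, 2, length.out = 9)
  expect_true(all(diff(occupancy_prob(
    p, list(depth = dep, rdmv = rep(0, 9), curmax = rep(0, 9)))) < 0))
  expect_true(all(diff(occupancy_prob(
    p, list(depth = rep(0, 9), rdmv = dep, curmax = rep(0, 9)))) > 0))
})

test_that("complete-data likelihood sums the right Bernoulli terms", {
  covs <- manual_covs(1, 1, 2)
  # 1 site, 1 season, 1 replicate: psi = 1, p = 0.5, z = 1, y = 1
  dh <- detection_history(array(c(1, NA), c(1, 1, 2)))
  ll <- complete_data_loglik(toy_params(psi = 1 - 1e-15), matrix(1), dh, covs)
  expect_equal(ll, log(0.5), tolerance = 1e-9)
  # two all-zero replicates: psi = 0.5, p = 0.5 -> log(0.5 * 0.25)
  dh2 <- detection_history(array(c(0, 0), c(1, 1, 2)))
  expect_equal(complete_data_loglik(toy_params(), matrix(1), dh2, covs),
               log(0.125), tolerance = 1e-12)
  # impossible history: occupied with perfect detection but no detection
  dh3 <- detection_history(array(c(1, 0), c(1, 2, 1)))
  p3 <- toy_params(psi = 0.5, p_intercept = 50, phi = 1, gamma = 0)
  expect_identical(
    complete_data_loglik(p3, matrix(c(1, 1), 1), dh3, manual_covs(1, 2, 1)),
    -Inf)
})

test_that("marginal likelihood equals hand enumeration and the oracle", {
  covs <- manual_covs(1, 1, 1)
  dh <- detection_history(array(0, c(1, 1, 1)))
  # z=1: 0.5 * 0.5; z=0: 0.5
  expect_equal(marginal_loglik(toy_params(), dh, covs), log(0.75),
               tolerance = 1e-12)
  # probability-one history
  dh1 <- detection_history(array(1, c(2, 1, 2)))
  p1 <- toy_params(psi = 1 - 1e-15, p_intercept = 60)
  expect_equal(marginal_loglik(p1, dh1, manual_covs(2, 1, 2)), 0,
               tolerance = 1e-9)
})

test_that("brute force reduces to the single-season closed form", {
  # psi * Bin(y | p) + (1 - psi) * 1{all y = 0}
  covs <- manual_covs(1, 1, 3)
  psi <- 0.3; p <- plogis(0.7)
  pars <- toy_params(psi = psi, p_intercept = 0.7)
  y0 <- detection_history(array(c(0, 0, 0), c(1, 1, 3)))
  expect_equal(exp(brute_force_loglik(pars, y0, covs)),
               psi * (1 - p)^3 + (1 - psi), tolerance = 1e-12)
  y1 <- detection_history(array(c(1, 0, 1), c(1, 1, 3)))
  expect_equal(exp(brute_force_loglik(pars, y1, covs)),
               psi * p^2 * (1 - p), tolerance = 1e-12)
  big <- detection_history(array(0, c(5, 4, 1)))
  expect_error(brute_force_loglik(toy_params(phi = runif(3), gamma = runif(3)),
                                  big, manual_covs(5, 4, 1)),
               "enumeration bound")
})

test_that("setting w = 0 equals removing the column from the design", {
  inst <- random_instance(99)
  pars <- inst$params
  pars$w_alpha[] <- 1
  pars$w_alpha["effort"] <- 0
  # same model with the effort column absent entirely
  pars_no <- dom_params(pars$alpha[names(pars$alpha) != "effort"],
                        pars$beta, pars$phi, pars$gamma,
                        w_alpha = pars$w_alpha[names(pars$w_alpha) != "effort"])
  expect_equal(marginal_loglik(pars, inst$data, inst$covs),
               marginal_loglik(pars_no, inst$data, inst$covs),
               tolerance = 1e-12)
})

test_that("with perfect detection the marginal equals the complete-data likelihood", {
  set.seed(42)
  S <- 3; T_ <- 3
  y <- array(NA_real_, c(S, T_, 2))
  y[, , 1] <- rbinom(S * T_, 1, 0.6)   # every site-season surveyed once
  dh <- detection_history(y)
  covs <- manual_covs(S, T_, 2)
  pars <- toy_params(psi = 0.7, p_intercept = 60, phi = c(0.5, 0.5),
                     gamma = c(0.3, 0.3))
  zdet <- matrix(y[, , 1], S, T_)      # p = 1 makes z the detection pattern
  expect_equal(marginal_loglik(pars, dh, covs),
               complete_data_loglik(pars, zdet, dh, covs), tolerance = 1e-8)
})

test_that("occupancy propagates by the persistence/colonization recursion", {
  expect_equal(recursive_occupancy(0.5, c(1, 1), c(1, 1)), c(0.5, 1, 1))
  expect_equal(recursive_occupancy(1, c(0, 0), c(0, 0)), c(1, 0, 0))
  # fixed point: phi = gamma = c makes every later season c
  expect_equal(recursive_occupancy(0.42, rep(0.3, 3), rep(0.3, 3)),
               c(0.42, 0.3, 0.3, 0.3))
  m <- recursive_occupancy(c(0.2, 0.9), 0.6, 0.1)
  expect_equal(m[, 2], c(0.2, 0.9) * 0.6 + (1 - c(0.2, 0.9)) * 0.1)
})
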
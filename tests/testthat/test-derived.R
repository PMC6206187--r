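test_that("finite-sample estimates follow linearity of expectation", {
  # 14 sites, one season; 8 always occupied (detected), the remaining 6
  # occupied in exactly 30% of draws -> mean (8 + 6 * 0.3) / 14
  n <- 10
  z <- array(0L, c(n, 14, 1))
  z[, 1:8, 1] <- 1L
  z[1:3, 9:14, 1] <- 1L
  y <- array(NA_real_, c(14, 1, 1)); y[, 1, 1] <- c(rep(1, 8), rep(0, 6))
  fit <- fake_fit(z, data = detection_history(y))
  occ <- finite_sample_occupancy(fit)
  expect_equal(occ$table$mean, (8 + 6 * 0.3) / 14, tolerance = 1e-12)
  expect_equal(occ$table$observed, 8 / 14)
  # degenerate cases
  z1 <- array(1L, c(5, 3, 1))
  o1 <- finite_sample_occupancy(fake_fit(z1))
  expect_equal(o1$table$mean, 1)
  expect_equal(o1$table$q2.5, 1)
  o0 <- finite_sample_occupancy(fake_fit(array(0L, c(5, 3, 1))))
  expect_equal(o0$table$mean, 0)
})

test_that("the estimate can never fall below the observed proportion", {
  fit <- fixture_fit()
  occ <- finite_sample_occupancy(fit)
  obs <- occ$table$observed
  for (t in seq_len(ncol(occ$props)))
    expect_true(all(occ$props[, t] >= obs[t] - 1e-12))
})

test_that("perfect detection collapses the estimate onto the observed value", {
  sim <- simulate_study(seed = 14)
  pars <- dom_params(alpha = c(intercept = 40, current = 0, none = 0,
                               current_none = 0, effort = 0),
                     beta = c(intercept = 0.9),
                     phi = c(0.44, 0.56, 0.85), gamma = c(0.52, 0.77, 0.55))
  set.seed(15)
  zs <- replicate(100, sample_latent_z(pars, sim$data, sim$covs))
  z <- aperm(zs, c(3, 1, 2))
  occ <- finite_sample_occupancy(fake_fit(z, data = sim$data))
  expect_equal(occ$table$mean, occ$table$observed, tolerance = 1e-12)
  expect_equal(occ$table$q97.5, occ$table$observed, tolerance = 1e-12)
})

test_that("turnover summaries give complements and exact ratios", {
  n <- 50
  z <- array(0L, c(n, 10, 3))
  z[, 1:2, 1] <- 1L    # 0.2 occupied
  z[, 1:4, 2] <- 1L    # 0.4 occupied: lambda_1 = 2
  z[, 1:4, 3] <- 1L    # lambda_2 = 1
  fit <- fake_fit(z, phi = matrix(0.85, n, 2), gamma = matrix(0.52, n, 2))
  ts <- turnover_summaries(fit)
  ext <- ts$table[ts$table$quantity == "extinction", ]
  expect_equal(ext$mean, c(0.15, 0.15), tolerance = 1e-12)
  gro <- ts$table[ts$table$quantity == "growth", ]
  expect_equal(gro$mean, c(2, 1), tolerance = 1e-12)
  col <- ts$table[ts$table$quantity == "colonization", ]
  expect_equal(col$mean, c(0.52, 0.52), tolerance = 1e-12)
})

test_that("growth uses per-draw ratios, not ratios of posterior means", {
  # two equally likely states: (0.1 -> 0.2) and (0.5 -> 0.5); the mean of
  # per-draw ratios is 1.5 but the ratio of means is 0.7/0.6
  z <- array(0L, c(2, 10, 2))
  z[1, 1, 1] <- 1L; z[1, 1:2, 2] <- 1L
  z[2, 1:5, 1] <- 1L; z[2, 1:5, 2] <- 1L
  fit <- fake_fit(z, phi = matrix(0.5, 2, 1), gamma = matrix(0.5, 2, 1))
  ts <- turnover_summaries(fit)
  lam <- ts$table[ts$table$quantity == "growth", "mean"]
  expect_equal(lam, 1.5, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(lam, 0.7 / 0.6)))
})

test_that("zero-denominator draws are dropped and counted", {
  z <- array(0L, c(4, 6, 2))
  z[1:2, 1, 1] <- 1L              # draws 3,4 are empty in season 1
  z[, 1:3, 2] <- 1L
  fit <- fake_fit(z, phi = matrix(0.5, 4, 1), gamma = matrix(0.5, 4, 1))
  ts <- turnover_summaries(fit)
  expect_equal(ts$n_dropped, 2L)
  lam <- ts$table[ts$table$quantity == "growth", "mean"]
  expect_equal(lam, 3, tolerance = 1e-12)    # (1/6) -> (3/6) in kept draws
})

test_that("inclusion means and the strict keep rule behave at the boundary", {
  w <- cbind(current = c(1, 1, 0, 1), none = c(1, 1, 1, 1),
             current_none = c(1, 0, 1, 1), effort = c(0, 1, 0, 1))
  fit <- fake_fit(array(0L, c(4, 2, 1)), w_alpha = w,
                  alpha = matrix(0, 4, 5,
                                 dimnames = list(NULL, c("intercept", colnames(w)))))
  incl <- inclusion_summary(fit)
  expect_equal(incl$inclusion[incl$term == "current"], 0.75)
  expect_true(incl$keep[incl$term == "current"])
  # exactly 0.5 is dropped (strict inequality)
  expect_equal(incl$inclusion[incl$term == "effort"], 0.5)
  expect_false(incl$keep[incl$term == "effort"])
  # interaction reported through the effective product indicator
  expect_equal(incl$inclusion[incl$term == "current_none"], mean(c(1, 0, 0, 1)))
})

test_that("bottom types coincide when their coefficients vanish", {
  n <- 200
  alpha <- cbind(intercept = rnorm(n, -1), current = rnorm(n, 0.5),
                 none = 0, current_none = 0)
  fit <- fake_fit(array(0L, c(n, 2, 1)), alpha = alpha,
                  w_alpha = matrix(1, n, 3, dimnames = list(
                    NULL, c("current", "none", "current_none"))))
  dd <- detection_difference(fit, currents_ms = seq(-1, 1, length.out = 5))
  expect_equal(dd$diff_mean, rep(0, 5), tolerance = 1e-12)
  expect_false(any(dd$excludes_zero))
})

test_that("surface predictions are invariant to grid cell ordering", {
  fit <- fixture_fit()
  field <- generate_tidal_series(6, duration_days = 2, seed = 16)
  grid <- data.frame(cell_id = 1:6, x = 1:6, y = 1,
                     depth_m = c(-15, -25, -35, -45, -55, -40.5))
  times <- field$times[c(5, 20)]
  s1 <- predict_detection_surface(fit, grid, field, times)
  expect_true(all(s1$p_mean >= 0 & s1$p_mean <= 1))
  expect_true(all(s1$p_lo <= s1$p_mean & s1$p_mean <= s1$p_hi))
  expect_equal(s1$bottom_type, ifelse(s1$depth_m < -40, "none", "canopy"))
  # permuted grid gives the same cell-wise predictions
  perm <- c(4, 2, 6, 1, 3, 5)
  f2 <- field; f2$speed <- field$speed[, perm]
  s2 <- predict_detection_surface(fit, grid[perm, ], f2, times)
  m1 <- s1[order(s1$cell_id, s1$time), ]
  m2 <- s2[order(s2$cell_id, s2$time), ]
  expect_equal(m1$p_mean, m2$p_mean, tolerance = 1e-12)
})
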
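# Shared fixture builders. All data are generated in code; hand-constructed
# covariate sets below carry values already on the standardized scale with
# unit constants, so closed-form likelihood examples stay exact.

manual_covs <- function(S, T, J, current = 0, effort = 0, none = 0,
                        depth = 0, rdmv = 0, curmax = 0) {
  site <- data.frame(
    site_id = paste0("S", seq_len(S)),
    depth_m = rep_len(depth, S), rdmv = rep_len(rdmv, S),
    curmax_ms = rep_len(curmax, S),
    bottom_type = ifelse(rep_len(none, S) == 1, "none", "canopy")
  )
  cv <- covariate_set(site,
                      current = array(rep_len(current, S * T * J), c(S, T, J)),
                      effort = array(rep_len(effort, S * T * J), c(S, T, J)))
  cv$site_std <- cbind(depth = site$depth_m, rdmv = site$rdmv,
                       curmax = site$curmax_ms, curmax2 = site$curmax_ms^2)
  cv$none <- as.numeric(site$bottom_type == "none")
  cv$current_std <- cv$current
  cv$effort_std <- cv$effort
  unit <- list(center = 0, scale = 1)
  cv$constants <- list(depth_m = unit, rdmv = unit, curmax_ms = unit,
                       current_ms = unit, effort_min = unit)
  cv$standardized <- TRUE
  cv
}

# Minimal parameter state: constant psi, optional detection slopes.
toy_params <- function(psi = 0.5, p_intercept = 0, current = 0, none = 0,
                       current_none = 0, effort = NULL, phi = numeric(0),
                       gamma = numeric(0), ...) {
  alpha <- c(intercept = p_intercept, current = current, none = none,
             current_none = current_none)
  if (!is.null(effort)) alpha <- c(alpha, effort = effort)
  dom_params(alpha = alpha, beta = c(intercept = qlogis(psi)),
             phi = phi, gamma = gamma, ...)
}

# Random small instance for oracle-equivalence checks: random ragged design,
# covariates, coefficients and indicator configuration.
random_instance <- function(seed, max_cells = 12) {
  set.seed(seed)
  repeat {
    S <- sample(1:4, 1); T_ <- sample(1:4, 1)
    if (S * T_ <= max_cells) break
  }
  J <- sample(1:3, 1)
  y <- array(NA_real_, c(S, T_, J))
  for (i in seq_len(S)) for (t in seq_len(T_)) {
    nr <- sample(0:J, 1)
    if (nr > 0) y[i, t, seq_len(nr)] <- rbinom(nr, 1, 0.5)
  }
  if (all(is.na(y))) y[1, 1, 1] <- 1   # keep at least one observation
  dh <- detection_history(y)
  covs <- manual_covs(S, T_, J,
                      current = rnorm(S * T_ * J), effort = rnorm(S * T_ * J),
                      none = rbinom(S, 1, 0.5))
  params <- dom_params(
    alpha = c(intercept = rnorm(1), current = rnorm(1), none = rnorm(1),
              current_none = rnorm(1), effort = rnorm(1)),
    beta = c(intercept = rnorm(1)),
    phi = runif(max(T_ - 1, 0)), gamma = runif(max(T_ - 1, 0)),
    w_alpha = setNames(rbinom(4, 1, 0.7),
                       c("current", "none", "current_none", "effort"))
  )
  list(params = params, data = dh, covs = covs)
}

# Fake fit-shaped object for derived-quantity unit tests.
fake_fit <- function(z, phi = NULL, gamma = NULL, alpha = NULL,
                     w_alpha = NULL, data = NULL) {
  n <- dim(z)[1]
  if (is.null(data)) {
    y <- array(NA_real_, c(dim(z)[2], dim(z)[3], 1))
    y[, , 1] <- 0
    data <- detection_history(y)
  }
  list(
    draws = list(
      z = z,
      phi = phi %||% matrix(numeric(0), n, 0),
      gamma = gamma %||% matrix(numeric(0), n, 0),
      alpha = alpha,
      w_alpha = w_alpha %||% matrix(numeric(0), n, 0),
      w_beta = matrix(numeric(0), n, 0),
      chain = rep(1L, n)
    ),
    data = data,
    constants = list(current_ms = list(center = 0, scale = 1)),
    covs = list(current = c(0, 1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
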
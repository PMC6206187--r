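#' Parameter state of the dynamic occupancy model
#'
#' One complete parameter state: detection coefficients `alpha` on the logit
#' scale (intercept, current, none, current:none interaction, and optionally
#' effort), occupancy coefficients `beta` (intercept alone for model A;
#' intercept, depth, rdmv, curmax, curmax^2 for model B), between-season
#' persistence `phi` and colonization `gamma` probabilities (one per
#' interval, constant across sites), and binary inclusion indicators `w` for
#' every non-intercept coefficient. A coefficient whose indicator is 0
#' contributes nothing to its linear predictor; the interaction's effective
#' indicator is the product `w_int * w_current * w_none`, so it can only act
#' when both main effects are in the model.
#'
#' @param alpha Named numeric vector; names from `c("intercept", "current",
#'   "none", "current_none", "effort")` (effort optional).
#' @param beta Named numeric vector; `c(intercept = x)` for model A or names
#'   `c("intercept", "depth", "rdmv", "curmax", "curmax2")` for model B.
#' @param phi,gamma Persistence / colonization probabilities, length
#'   `n_seasons - 1` (may be length 0 for a single season).
#' @param w_alpha,w_beta Binary inclusion indicators for the non-intercept
#'   terms of each block; default all 1 (all terms in).
#' @return Object of class `dom_params`.
#' @examples
#' p <- dom_params(
#'   alpha = c(intercept = -1.57, current = -1.26, none = 3.01,
#'             current_none = 1.77),
#'   beta = c(intercept = 0.9), phi = c(0.44, 0.56, 0.85),
#'   gamma = c(0.52, 0.77, 0.55)
#' )
#' @export
dom_params <- function(alpha, beta = c(intercept = 0), phi = numeric(0),
                       gamma = numeric(0), w_alpha = NULL, w_beta = NULL) {
  a_names <- c("intercept", "current", "none", "current_none", "effort")
  b_names <- c("intercept", "depth", "rdmv", "curmax", "curmax2")
  if (is.null(names(alpha)) || !all(names(alpha) %in% a_names))
    stop("`alpha` must be named from: ", paste(a_names, collapse = ", "))
  if (is.null(names(beta)) || !all(names(beta) %in% b_names))
    stop("`beta` must be named from: ", paste(b_names, collapse = ", "))
  if (!"intercept" %in% names(alpha) || !"intercept" %in% names(beta))
    stop("both coefficient blocks need an intercept")
  if (length(phi) != length(gamma))
    stop("`phi` and `gamma` must have equal length (n_seasons - 1)")
  if (length(phi) && (any(phi < 0 | phi > 1) || any(gamma < 0 | gamma > 1)))
    stop("`phi` and `gamma` must lie in [0, 1]")
  sel_a <- setdiff(names(alpha), "intercept")
  sel_b <- setdiff(names(beta), "intercept")
  if (is.null(w_alpha)) w_alpha <- setNames(rep(1, length(sel_a)), sel_a)
  if (is.null(w_beta)) w_beta <- setNames(rep(1, length(sel_b)), sel_b)
  if (!setequal(names(w_alpha), sel_a) || !setequal(names(w_beta), sel_b))
    stop("inclusion indicators must match the non-intercept coefficients")
  if (!all(c(w_alpha, w_beta) %in% c(0, 1)))
    stop("inclusion indicators must be 0 or 1")
  structure(
    list(alpha = alpha, beta = beta, phi = phi, gamma = gamma,
         w_alpha = w_alpha[sel_a], w_beta = w_beta[sel_b]),
    class = "dom_params"
  )
}

# Effective multiplier per alpha coefficient: intercept always 1; the
# interaction only contributes when itself and both main effects are in.
effective_w_alpha <- function(params) {
  w <- params$w_alpha
  out <- setNames(rep(1, length(params$alpha)), names(params$alpha))
  for (nm in names(w)) out[nm] <- w[[nm]]
  if ("current_none" %in% names(out))
    out["current_none"] <- w[["current_none"]] *
      (if ("current" %in% names(w)) w[["current"]] else 1) *
      (if ("none" %in% names(w)) w[["none"]] else 1)
  out
}

effective_w_beta <- function(params) {
  out <- setNames(rep(1, length(params$beta)), names(params$beta))
  for (nm in names(params$w_beta)) out[nm] <- params$w_beta[[nm]]
  out
}

# Detection design matrix from standardized replicate covariates, columns
# aligned with params$alpha.
detection_design <- function(params, reps) {
  need <- setdiff(names(params$alpha), "intercept")
  cols <- list(intercept = rep(1, NROW(reps$current)))
  for (nm in need) {
    v <- switch(nm,
      current = reps$current,
      none = reps$none,
      current_none = reps$current * reps$none,
      effort = reps$effort
    )
    if (is.null(v) || anyNA(v)) stop("missing replicate covariate for term '", nm, "'")
    cols[[nm]] <- v
  }
  do.call(cbind, cols[names(params$alpha)])
}

occupancy_design <- function(params, site_covs) {
  nms <- names(params$beta)
  if (identical(nms, "intercept"))
    return(matrix(1, NROW(as.data.frame(site_covs)[[1]]) %||% 1, 1,
                  dimnames = list(NULL, "intercept")))
  sc <- as.data.frame(site_covs)
  cols <- list(intercept = rep(1, nrow(sc)))
  for (nm in setdiff(nms, "intercept")) {
    v <- if (nm == "curmax2" && is.null(sc[["curmax2"]])) sc[["curmax"]]^2 else sc[[nm]]
    if (is.null(v) || anyNA(v)) stop("missing site covariate for term '", nm, "'")
    cols[[nm]] <- v
  }
  do.call(cbind, cols[nms])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detection probability for replicate surveys
#'
#' `logit(p) = a1 + a2*current + a3*none + a4*current*none (+ a_eff*effort)`,
#' with each slope multiplied by its (effective) inclusion indicator.
#' Covariates must be on the standardized scale used for fitting.
#'
#' @param params A [dom_params()] state.
#' @param reps List or `data.frame` with elements `current`, `none`, and
#'   `effort` (only needed when the state has an effort term).
#' @return Vector of detection probabilities.
#' @export
detection_prob <- function(params, reps) {
  X <- detection_design(params, reps)
  as.vector(plogis(X %*% (params$alpha * effective_w_alpha(params))))
}

#' Initial occupancy probability per site
#'
#' `logit(psi) = b1 + b2*depth + b3*rdmv + b4*curmax + b5*curmax^2` with each
#' slope multiplied by its inclusion indicator; the intercept is always in.
#' For a model-A state (`beta` = intercept only) covariates are ignored.
#'
#' @param params A [dom_params()] state.
#' @param site_covs List or `data.frame` of standardized site covariates
#'   (`depth`, `rdmv`, `curmax`, optionally `curmax2`).
#' @return Vector of occupancy probabilities.
#' @export
occupancy_prob <- function(params, site_covs) {
  X <- occupancy_design(params, site_covs)
  as.vector(plogis(X %*% (params$beta * effective_w_beta(params))))
}

# psi per site for a detection history's covariate set.
psi_sites <- function(params, covs, n_sites) {
  if (identical(names(params$beta), "intercept"))
    return(rep(plogis(unname(params$beta["intercept"])), n_sites))
  if (!isTRUE(covs$standardized))
    stop("model-B occupancy covariates must be standardized")
  occupancy_prob(params, as.data.frame(covs$site_std))
}
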
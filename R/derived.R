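# Posterior summaries reported for the study: finite-sample occupancy,
# turnover (colonization / extinction / growth), inclusion decisions, and
# detection-probability prediction over space and tidal time.

# Per-draw proportion of sampled sites occupied, one column per season.
occupied_props <- function(fit) {
  apply(fit$draws$z, c(1, 3), mean)
}

#' Finite-sample occupancy estimates
#'
#' The finite-sample estimator summarizes occupancy for the sites actually
#' sampled: in each stored draw and season, the proportion of sites with
#' latent `z = 1`. Because `z = 1` is forced wherever a detection occurred,
#' the estimate is bounded below by the observed (naive) proportion in every
#' draw; the estimated-versus-observed gap is the detectability correction.
#'
#' @param fit A `dom_fit` (or a list with `draws$z` and `data`).
#' @return Object of class `occupancy_summary`: a per-season table with
#'   posterior mean, median, 50% and 95% credible intervals and the observed
#'   proportion, plus the per-draw proportions in `$props`.
#' @export
finite_sample_occupancy <- function(fit) {
  props <- occupied_props(fit)
  obs <- colMeans(detected_matrix(fit$data))
  tab <- data.frame(
    season = seq_len(ncol(props)),
    mean = colMeans(props),
    median = apply(props, 2, median),
    q2.5 = apply(props, 2, quantile, 0.025),
    q25 = apply(props, 2, quantile, 0.25),
    q75 = apply(props, 2, quantile, 0.75),
    q97.5 = apply(props, 2, quantile, 0.975),
    observed = obs
  )
  structure(list(table = tab, props = props), class = "occupancy_summary")
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat("Finite-sample occupancy (proportion of sampled sites occupied):\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Colonization, extinction and growth between seasons
#'
#' Extinction is the complement of persistence (`1 - phi_t`). The growth
#' rate `lambda_t` is the ratio of finite-sample occupied proportions in
#' successive seasons, computed per draw and then summarized (the posterior
#' mean of the ratio is not the ratio of posterior means); draws with a zero
#' denominator are dropped and counted.
#'
#' @param fit A `dom_fit`.
#' @return Object of class `turnover_summary`: `table` with per-interval
#'   posterior means and 95% intervals of colonization, extinction and
#'   growth, plus `lambda_draws` and `n_dropped`.
#' @export
turnover_summaries <- function(fit) {
  d <- fit$draws
  if (!ncol(d$phi)) stop("turnover requires at least two seasons")
  props <- occupied_props(fit)
  T_ <- ncol(props)
  summ <- function(v) c(mean = mean(v), median = median(v),
                        q2.5 = unname(quantile(v, 0.025)),
                        q97.5 = unname(quantile(v, 0.975)))
  rows <- list(); lam_draws <- list(); n_drop <- integer(T_ - 1L)
  for (t in seq_len(T_ - 1L)) {
    lam <- props[, t + 1] / props[, t]
    bad <- props[, t] == 0
    n_drop[t] <- sum(bad)
    lam <- lam[!bad]
    if (!length(lam)) stop("all draws have a zero denominator for interval ", t)
    lam_draws[[t]] <- lam
    rows[[t]] <- data.frame(
      interval = t,
      rbind(
        data.frame(quantity = "colonization", t(summ(d$gamma[, t]))),
        data.frame(quantity = "extinction", t(summ(1 - d$phi[, t]))),
        data.frame(quantity = "growth", t(summ(lam)))
      )
    )
  }
  structure(list(table = do.call(rbind, rows), lambda_draws = lam_draws,
                 n_dropped = n_drop),
            class = "turnover_summary")
}

#' @export
print.turnover_summary <- function(x, ...) {
  cat("Between-season turnover:\n")
  print(x$table, row.names = FALSE, digits = 3)
  if (any(x$n_dropped > 0))
    cat(sprintf("(dropped %s zero-denominator draws per interval)\n",
                paste(x$n_dropped, collapse = "/")))
  invisible(x)
}

#' Posterior inclusion probabilities and keep/drop decisions
#'
#' Posterior mean of each term's inclusion indicator; the interaction is
#' reported through its effective product indicator
#' `w_int * w_current * w_none`. A term is kept when its posterior inclusion
#' mean exceeds 0.5 (strictly).
#'
#' @param fit A `dom_fit`.
#' @return `data.frame` with columns `submodel`, `term`, `inclusion`,
#'   `keep`.
#' @export
inclusion_summary <- function(fit) {
  d <- fit$draws
  out <- list()
  wa <- d$w_alpha
  if (!is.null(wa) && ncol(wa)) {
    for (nm in colnames(wa)) {
      v <- if (nm == "current_none")
        wa[, "current_none"] * wa[, "current"] * wa[, "none"] else wa[, nm]
      out[[length(out) + 1L]] <- data.frame(
        submodel = "detection", term = nm, inclusion = mean(v))
    }
  }
  wb <- d$w_beta
  if (!is.null(wb) && ncol(wb))
    for (nm in colnames(wb))
      out[[length(out) + 1L]] <- data.frame(
        submodel = "occupancy", term = nm, inclusion = mean(wb[, nm]))
  res <- do.call(rbind, out)
  res$keep <- res$inclusion > 0.5
  res
}

# Detection probability draws at given standardized currents and bottom
# types (effort held at its mean, i.e. 0 on the standardized scale).
p_draws_at <- function(fit, current_std, none, means_only = FALSE) {
  d <- fit$draws
  a_names <- colnames(d$alpha)
  Aeff <- d$alpha
  wa <- d$w_alpha
  if (!is.null(wa) && ncol(wa)) {
    for (nm in intersect(colnames(wa), a_names))
      Aeff[, nm] <- Aeff[, nm] * wa[, nm]
    if (all(c("current_none", "current", "none") %in% colnames(wa)))
      Aeff[, "current_none"] <- d$alpha[, "current_none"] *
        wa[, "current_none"] * wa[, "current"] * wa[, "none"]
  }
  if (means_only)
    Aeff <- matrix(colMeans(Aeff), 1, length(a_names),
                   dimnames = list(NULL, a_names))
  X <- cbind(intercept = 1, current = current_std, none = none,
             current_none = current_std * none)
  if ("effort" %in% a_names) X <- cbind(X, effort = 0)
  plogis(Aeff[, colnames(X), drop = FALSE] %*% t(X))
}

#' Detection-probability surfaces over space and tidal time
#'
#' Predicts the detection submodel over a grid of cells and a set of times
#' along the tidal cycle: each cell's bottom type comes from its depth
#' against the canopy extinction limit, its current speed at each time from
#' the supplied current field (nearest time step), standardized with the
#' constants stored on the fit. By default the full posterior is propagated
#' (per-draw coefficients and indicators); `means_only = TRUE` plugs in
#' posterior means instead. Effort is held at its sample mean.
#'
#' @param fit A `dom_fit`.
#' @param grid `data.frame` with columns `cell_id`, `x`, `y`, `depth_m`.
#' @param field A [generate_tidal_series()] current field whose columns map
#'   to grid cells (cell `i` uses column `i`).
#' @param times Times (seconds) at which to predict.
#' @param canopy_depth_limit_m Algal extinction depth (positive metres).
#' @param means_only Plug in posterior means instead of full propagation.
#' @return Long `data.frame`: one row per cell x time with `current_ms`,
#'   `bottom_type`, `p_mean`, `p_lo`, `p_hi` (95% bounds).
#' @export
predict_detection_surface <- function(fit, grid, field, times,
                                      canopy_depth_limit_m = 40,
                                      means_only = FALSE) {
  cc <- fit$constants$current_ms
  if (is.null(cc) || is.na(cc$center))
    stop("fit has no stored standardization constants for current speed")
  out <- do.call(rbind, lapply(times, function(tt) {
    cur <- match_current_to_time(field, rep(tt, nrow(grid)), seq_len(nrow(grid)))
    data.frame(grid, time = tt, current_ms = cur)
  }))
  cstd <- (out$current_ms - cc$center) / cc$scale
  none <- as.numeric(out$depth_m < -canopy_depth_limit_m)
  P <- p_draws_at(fit, cstd, none, means_only = means_only)
  out$bottom_type <- ifelse(none == 1, "none", "canopy")
  out$p_mean <- colMeans(P)
  out$p_lo <- apply(P, 2, quantile, 0.025)
  out$p_hi <- apply(P, 2, quantile, 0.975)
  out
}

#' Posterior difference in detection probability between bottom types
#'
#' For each current speed, the per-draw difference
#' `p(current, none) - p(current, canopy)` with its posterior mean and 95%
#' credible band; where the band includes zero there is no credible
#' difference between bottom types at that current.
#'
#' @param fit A `dom_fit`.
#' @param currents_ms Current speeds (m/s) at which to evaluate; default a
#'   41-point grid over the observed range.
#' @return `data.frame` with `current_ms`, `diff_mean`, `diff_lo`,
#'   `diff_hi`, `excludes_zero`.
#' @export
detection_difference <- function(fit, currents_ms = NULL) {
  cc <- fit$constants$current_ms
  if (is.null(cc) || is.na(cc$center))
    stop("fit has no stored standardization constants for current speed")
  if (is.null(currents_ms)) {
    r <- range(fit$covs$current, na.rm = TRUE)
    currents_ms <- seq(r[1], r[2], length.out = 41)
  }
  cstd <- (currents_ms - cc$center) / cc$scale
  Pn <- p_draws_at(fit, cstd, rep(1, length(cstd)))
  Pc <- p_draws_at(fit, cstd, rep(0, length(cstd)))
  D <- Pn - Pc
  lo <- apply(D, 2, quantile, 0.025)
  hi <- apply(D, 2, quantile, 0.975)
  data.frame(current_ms = currents_ms, diff_mean = colMeans(D),
             diff_lo = lo, diff_hi = hi, excludes_zero = lo > 0 | hi < 0)
}
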
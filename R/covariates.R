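#' Covariate container for occupancy and detection submodels
#'
#' Bundles site-level covariates (depth in metres, negative below datum;
#' RDMV terrain complexity; seasonal maximum current speed in m/s; bottom
#' type) with replicate-level covariates (bottom-current speed at the time of
#' observation in m/s, sampling effort in minutes of bottom time). Replicate
#' arrays are aligned with the detection history's `[site, season, replicate]`
#' layout, with `NA` at masked cells. Bottom type is a site constant.
#'
#' @param site `data.frame` with columns `site_id`, `depth_m`, `rdmv`,
#'   `curmax_ms`, `bottom_type` (`"canopy"` or `"none"`).
#' @param current,effort Optional arrays `[n_sites, n_seasons, max_reps]` of
#'   replicate-level covariates.
#' @return Object of class `covariate_set`.
#' @seealso [standardize_covariates()]
#' @export
covariate_set <- function(site, current = NULL, effort = NULL) {
  req <- c("site_id", "depth_m", "rdmv", "curmax_ms", "bottom_type")
  miss <- setdiff(req, names(site))
  if (length(miss))
    stop("site covariate table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(site$bottom_type %in% c("canopy", "none")))
    stop("`bottom_type` must be 'canopy' or 'none'")
  structure(
    list(
      site = site, current = current, effort = effort,
      standardized = FALSE, constants = NULL
    ),
    class = "covariate_set"
  )
}

#' @export
print.covariate_set <- function(x, ...) {
  cat(sprintf(
    "Covariate set: %d sites (%s)%s\n", nrow(x$site),
    paste(names(table(x$site$bottom_type)),
          table(x$site$bottom_type), sep = "=", collapse = ", "),
    if (x$standardized) " [standardized]" else ""
  ))
  invisible(x)
}

#' Centre and scale a numeric vector
#'
#' Standardization uses the sample standard deviation (n - 1 denominator).
#' With `center`/`scale` supplied, applies stored constants instead of
#' recomputing them (for prediction onto new data).
#'
#' @param x Numeric vector (NAs allowed; ignored when computing constants).
#' @param center,scale Optional stored constants.
#' @param name Covariate name used in error messages.
#' @return List with `values`, `center`, `scale`.
#' @examples
#' zscore(c(1, 2, 3))$values  # -1 0 1
#' @export
zscore <- function(x, center = NULL, scale = NULL, name = deparse(substitute(x))) {
  if (is.null(center)) center <- mean(x, na.rm = TRUE)
  if (is.null(scale)) scale <- sd(x, na.rm = TRUE)
  if (!is.na(scale) && scale == 0)
    stop("covariate '", name, "' has zero variance and cannot be standardized")
  list(values = (x - center) / scale, center = center, scale = scale)
}

#' Standardize continuous covariates
#'
#' Continuous covariates are standardized before analysis: site-level
#' covariates (depth, RDMV, seasonal maximum current) over the sites, and
#' replicate-level covariates (current speed, effort) over the observed
#' replicate records. The quadratic seasonal-current term is the square of
#' the *standardized* maximum current, so it is centred. Constants are stored
#' on the returned object so predictions onto new grids use the fit's scale.
#'
#' @param covs A [covariate_set()].
#' @param constants Optional constants from a previous call (prediction mode).
#' @return The covariate set with standardized fields `site_std` (matrix with
#'   columns `depth`, `rdmv`, `curmax`, `curmax2`), `current_std`,
#'   `effort_std`, `none` (0/1 site indicator for canopy-free bottom), the
#'   `constants`, and `standardized = TRUE`.
#' @export
standardize_covariates <- function(covs, constants = NULL) {
  stopifnot(inherits(covs, "covariate_set"))
  cn <- function(nm) if (is.null(constants)) list(center = NULL, scale = NULL) else constants[[nm]]
  get2 <- function(x, nm) {
    z <- zscore(x, cn(nm)$center, cn(nm)$scale, name = nm)
    z
  }
  dep <- get2(covs$site$depth_m, "depth_m")
  rdm <- get2(covs$site$rdmv, "rdmv")
  cmx <- get2(covs$site$curmax_ms, "curmax_ms")
  site_std <- cbind(
    depth = dep$values, rdmv = rdm$values,
    curmax = cmx$values, curmax2 = cmx$values^2
  )
  out <- covs
  out$site_std <- site_std
  out$none <- as.numeric(covs$site$bottom_type == "none")
  consts <- list(
    depth_m = dep[c("center", "scale")],
    rdmv = rdm[c("center", "scale")],
    curmax_ms = cmx[c("center", "scale")]
  )
  if (!is.null(covs$current)) {
    cur <- get2(as.vector(covs$current), "current_ms")
    out$current_std <- array(cur$values, dim = dim(covs$current))
    consts$current_ms <- cur[c("center", "scale")]
  }
  if (!is.null(covs$effort)) {
    eff <- get2(as.vector(covs$effort), "effort_min")
    out$effort_std <- array(eff$values, dim = dim(covs$effort))
    consts$effort_min <- eff[c("center", "scale")]
  }
  out$constants <- consts
  out$standardized <- TRUE
  out
}

# Replicate-level standardized covariates in obs_table order.
obs_covariates <- function(dh, covs) {
  if (!isTRUE(covs$standardized))
    stop("covariates must be standardized (see standardize_covariates)")
  ot <- obs_table(dh)
  lin <- cbind(ot$site, ot$season, ot$replicate)
  data.frame(
    ot,
    current = if (is.null(covs$current_std)) rep(0, nrow(ot)) else covs$current_std[lin],
    none = covs$none[ot$site],
    effort = if (is.null(covs$effort_std)) rep(0, nrow(ot)) else covs$effort_std[lin]
  )
}
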
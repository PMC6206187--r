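#' Detection history container
#'
#' A detection history is a ragged binary array `y[site, season, replicate]`
#' of detections (1) and non-detections (0) from replicate surveys within
#' seasons. Replicates that were never carried out are encoded as `NA` in `y`
#' and excluded from all likelihood computations via the mask. Each observed
#' replicate may carry an observation time (seconds since the start of the
#' simulated or surveyed period) used to look up the bottom-current speed at
#' the moment of observation.
#'
#' @param y Numeric or integer array `[n_sites, n_seasons, max_reps]` with
#'   values in `{0, 1, NA}`; `NA` marks a missing replicate.
#' @param obs_time Optional array of the same dimensions with observation
#'   times in seconds (`NA` where `y` is `NA`).
#' @param site_ids Optional character vector of site labels.
#' @return An object of class `detection_history` with elements `y`, `mask`,
#'   `obs_time`, `n_sites`, `n_seasons`, `max_reps`, `site_ids`.
#' @examples
#' y <- array(c(1, 0, NA, 1), dim = c(2, 1, 2))
#' dh <- detection_history(y)
#' dh$n_sites
#' @export
detection_history <- function(y, obs_time = NULL, site_ids = NULL) {
  if (length(dim(y)) != 3L)
    stop("`y` must be a 3-d array [site, season, replicate]")
  storage.mode(y) <- "double"
  mask <- !is.na(y)
  vals <- y[mask]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stop("`y` must contain only 0, 1 or NA")
  if (!is.null(obs_time)) {
    if (!identical(dim(obs_time), dim(y)))
      stop("`obs_time` must have the same dimensions as `y`")
    if (any(is.na(obs_time[mask])))
      stop("`obs_time` missing for an observed replicate")
  }
  if (is.null(site_ids)) site_ids <- paste0("S", seq_len(dim(y)[1]))
  structure(
    list(
      y = y, mask = mask, obs_time = obs_time,
      n_sites = dim(y)[1], n_seasons = dim(y)[2], max_reps = dim(y)[3],
      site_ids = site_ids
    ),
    class = "detection_history"
  )
}

#' @export
print.detection_history <- function(x, ...) {
  n_obs <- sum(x$mask)
  n_det <- sum(x$y[x$mask])
  cat(sprintf(
    "Detection history: %d sites x %d seasons, up to %d replicates\n",
    x$n_sites, x$n_seasons, x$max_reps
  ))
  cat(sprintf("  %d observed replicates, %d with detections\n", n_obs, n_det))
  invisible(x)
}

# Long-format view of the observed replicates, in a fixed (site, season,
# replicate) order shared by all likelihood code.
obs_table <- function(dh) {
  idx <- which(dh$mask, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]
  data.frame(
    site = idx[, 1], season = idx[, 2], replicate = idx[, 3],
    cell = idx[, 1] + (idx[, 2] - 1L) * dh$n_sites,
    y = dh$y[dh$mask][ord],
    obs_time = if (is.null(dh$obs_time)) NA_real_ else dh$obs_time[dh$mask][ord]
  )
}

# 1 where a site-season has at least one detection, 0 otherwise (NA-safe).
detected_matrix <- function(dh) {
  d <- apply(dh$y, c(1, 2), function(v) as.numeric(any(v == 1, na.rm = TRUE)))
  matrix(d, dh$n_sites, dh$n_seasons)
}

# Number of observed replicates per site-season.
reps_matrix <- function(dh) {
  apply(dh$mask, c(1, 2), sum)
}
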
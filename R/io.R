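# Readers and writers for the package's plain-text file dialects, plus the
# run configuration.
#
# Detection histories travel as long-format CSV (site_id, season, replicate,
# y, obs_time, effort_min, current_ms); site covariates as CSV keyed by
# site_id; tidal series as (site_id, time_s, speed_ms); terrain grids as
# ASCII grids with an ncols/nrows/cellsize header.

#' Write / read detection histories as long-format CSV
#'
#' One row per observed replicate with its observation time, effort and
#' matched current speed. `read_detection_csv()` validates the dialect —
#' `y` must be 0/1 and `(site_id, season, replicate)` keys unique — and
#' reports offending rows by line number. Reading back a written file
#' reproduces the detection history and replicate covariates exactly;
#' replicate gaps (ragged designs) round-trip through the mask.
#'
#' @param sim_or_parts Either a `sim_truth` or a list with `data`
#'   (a [detection_history()]) and `covs` (a [covariate_set()] carrying
#'   replicate-level `current`/`effort` arrays on the raw scale).
#' @param path File path.
#' @return `read_detection_csv()` returns a list with `data` and the raw
#'   replicate covariate arrays `current`, `effort`.
#' @export
write_detection_csv <- function(sim_or_parts, path) {
  dh <- sim_or_parts$data
  covs <- sim_or_parts$covs
  ot <- obs_table(dh)
  lin <- cbind(ot$site, ot$season, ot$replicate)
  df <- data.frame(
    site_id = dh$site_ids[ot$site], season = ot$season,
    replicate = ot$replicate, y = ot$y, obs_time = ot$obs_time,
    effort_min = if (is.null(covs$effort)) NA_real_ else covs$effort[lin],
    current_ms = if (is.null(covs$current)) NA_real_ else covs$current[lin]
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detection_csv
#' @export
read_detection_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("site_id", "season", "replicate", "y", "obs_time", "effort_min",
           "current_ms")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("detection CSV missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!df$y %in% c(0, 1))
  if (length(bad))
    stop("invalid y value (must be 0 or 1) at data row(s): ",
         paste(head(bad, 5), collapse = ", "))
  key <- paste(df$site_id, df$season, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (site_id, season, replicate) key at data row(s): ",
         paste(head(which(duplicated(key)), 5), collapse = ", "))
  sites <- unique(df$site_id)
  S <- length(sites); T_ <- max(df$season); J <- max(df$replicate)
  mk <- function() array(NA_real_, dim = c(S, T_, J))
  y <- mk(); ot <- mk(); eff <- mk(); cur <- mk()
  lin <- cbind(match(df$site_id, sites), df$season, df$replicate)
  y[lin] <- df$y; ot[lin] <- df$obs_time
  eff[lin] <- df$effort_min; cur[lin] <- df$current_ms
  list(data = detection_history(y, obs_time = ot, site_ids = sites),
       current = cur, effort = eff)
}

#' Write / read site covariates as CSV
#'
#' @param covs A [covariate_set()] (only the site table is written).
#' @param path File path.
#' @return `read_covariates_csv()` returns a [covariate_set()] (site level
#'   only; combine with replicate arrays via [covariate_set()]).
#' @export
write_covariates_csv <- function(covs, path) {
  write.csv(covs$site, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates_csv
#' @export
read_covariates_csv <- function(path) {
  covariate_set(read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read a tidal current series as CSV
#'
#' Long format: `site_id`, `time_s` (seconds since series origin),
#' `speed_ms`.
#'
#' @param field A [generate_tidal_series()] result.
#' @param path File path.
#' @return `read_tidal_csv()` returns a `tidal_field` (times, speed matrix,
#'   step); generator metadata (amplitudes, lags) is not stored in the CSV.
#' @export
write_tidal_csv <- function(field, path) {
  df <- data.frame(
    site_id = rep(seq_len(ncol(field$speed)), each = length(field$times)),
    time_s = rep(field$times, ncol(field$speed)),
    speed_ms = as.vector(field$speed)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tidal_csv
#' @export
read_tidal_csv <- function(path) {
  df <- read.csv(path)
  times <- sort(unique(df$time_s))
  sites <- sort(unique(df$site_id))
  sp <- matrix(NA_real_, length(times), length(sites))
  sp[cbind(match(df$time_s, times), match(df$site_id, sites))] <- df$speed_ms
  structure(list(times = times, speed = sp, amplitude = NULL, lag_s = NULL,
                 period_s = NA_real_, step_s = diff(times[1:2]),
                 floor_ms = min(sp)),
            class = "tidal_field")
}

#' Write / read a terrain grid as a plain-text ASCII grid
#'
#' Header lines `ncols`, `nrows`, `cellsize` followed by one row of
#' elevations per line.
#'
#' @param grid A `terrain_grid`.
#' @param path File path.
#' @return `read_ascii_grid()` returns a `terrain_grid`.
#' @export
write_ascii_grid <- function(grid, path) {
  m <- grid$elevation
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               paste("cellsize", grid$cellsize_m)), con)
  write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 3)
  kv <- function(i) as.numeric(strsplit(hdr[i], "\\s+")[[1]][2])
  m <- as.matrix(read.table(path, skip = 3))
  dimnames(m) <- NULL
  stopifnot(ncol(m) == kv(1), nrow(m) == kv(2))
  structure(list(elevation = m, cellsize_m = kv(3)), class = "terrain_grid")
}

#' Tidy posterior draws and Table-shaped summary CSVs
#'
#' `write_posterior_csv()` writes long-format draws (chain, draw, parameter,
#' value) for the coefficient, turnover and indicator parameters;
#' `write_summary_csv()` writes the [summary.dom_fit()] table.
#'
#' @param fit A `dom_fit`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_posterior_csv <- function(fit, path) {
  d <- fit$draws
  blocks <- list(
    alpha = d$alpha, beta = d$beta,
    phi = `colnames<-`(d$phi, if (ncol(d$phi)) paste0("t", seq_len(ncol(d$phi)))),
    gamma = `colnames<-`(d$gamma, if (ncol(d$gamma)) paste0("t", seq_len(ncol(d$gamma)))),
    w = d$w_alpha
  )
  rows <- list()
  draw_id <- ave(d$chain, d$chain, FUN = seq_along)
  for (bl in names(blocks)) {
    m <- blocks[[bl]]
    if (is.null(m) || !ncol(m)) next
    for (nm in colnames(m))
      rows[[paste(bl, nm)]] <- data.frame(
        chain = d$chain, draw = draw_id,
        parameter = paste(bl, nm, sep = "."), value = m[, nm])
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior_csv
#' @export
write_summary_csv <- function(fit, path) {
  write.csv(summary(fit), path, row.names = FALSE)
  invisible(path)
}

# --- run configuration ------------------------------------------------------

run_config_fields <- c("model", "effort", "prior", "chains", "simulation",
                       "paths", "seed", "verbosity")

#' Run configuration
#'
#' A single structured configuration driving reproducible pipeline runs:
#' model choice (A/B), the effort-term switch, prior and chain settings,
#' simulation parameters, file paths and the master seed. Round-trips
#' losslessly through YAML; unknown keys are rejected.
#'
#' @param model `"A"` or `"B"`.
#' @param effort Include the effort detection term?
#' @param prior A [prior_config()] or preset name.
#' @param chains A [chain_config()].
#' @param simulation Named list of [simulate_study()] overrides.
#' @param paths Named list of file paths.
#' @param seed Master seed.
#' @param verbosity 0 (quiet) or 1 (progress).
#' @return Object of class `run_config`.
#' @export
run_config <- function(model = "A", effort = TRUE, prior = prior_config(),
                       chains = chain_config(4, 4000, 1000, 3),
                       simulation = list(), paths = list(), seed = 1L,
                       verbosity = 0L) {
  if (!model %in% c("A", "B")) stop("config field `model` must be 'A' or 'B'")
  if (is.character(prior)) prior <- prior_presets(prior)[[1]]
  structure(list(model = model, effort = isTRUE(effort), prior = prior,
                 chains = chains, simulation = simulation, paths = paths,
                 seed = as.integer(seed), verbosity = as.integer(verbosity)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config()` returns a validated [run_config()].
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  lst$prior <- unclass(lst$prior)
  lst$chains <- unclass(lst$chains)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  unknown <- setdiff(names(lst), run_config_fields)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  pr <- lst$prior %||% list()
  ch <- lst$chains %||% list()
  run_config(
    model = lst$model %||% "A",
    effort = lst$effort %||% TRUE,
    prior = prior_config(pr$mu %||% 0, pr$sigma %||% 1.566,
                         pr$df %||% 7.763, pr$name %||% "dorazio"),
    chains = chain_config(ch$n_chains %||% 4, ch$n_draws %||% 4000,
                          ch$burn_in %||% 1000, ch$thin %||% 3,
                          ch$proposal_scale %||% 0.5, ch$seed %||% 1L),
    simulation = lst$simulation %||% list(),
    paths = lst$paths %||% list(),
    seed = lst$seed %||% 1L,
    verbosity = lst$verbosity %||% 0L
  )
}
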
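#' Synthetic bathymetric terrain grid
#'
#' A smooth random surface standing in for multibeam bathymetry, sufficient
#' to exercise the RDMV terrain attribute. Built as a sum of a depth trend
#' and smoothed Gaussian bumps; cell size defaults to 5 m.
#'
#' @param nrow,ncol Grid dimensions (>= 3).
#' @param cellsize_m Cell size in metres.
#' @param depth_range_m Range of depths (negative, metres below datum).
#' @param roughness_m SD of the random relief in metres.
#' @param seed Integer seed.
#' @return Object of class `terrain_grid` with `elevation` matrix and
#'   `cellsize_m`.
#' @export
generate_terrain_grid <- function(nrow = 40, ncol = 40, cellsize_m = 5,
                                  depth_range_m = c(-60, -10),
                                  roughness_m = 2, seed = 1L) {
  stopifnot(nrow >= 3, ncol >= 3)
  set.seed(seed)
  trend <- outer(seq(depth_range_m[1], depth_range_m[2], length.out = nrow),
                 rep(1, ncol))
  noise <- matrix(rnorm(nrow * ncol, 0, roughness_m), nrow, ncol)
  # one smoothing pass (3x3 mean) so relief is spatially coherent
  sm <- shift_stack(noise)
  noise <- sm$sum / sm$n
  structure(list(elevation = trend + noise, cellsize_m = cellsize_m),
            class = "terrain_grid")
}

# Sum/count/min/max over the 3x3 neighbourhood of every cell, truncating the
# window at the grid edge (no padding).
shift_stack <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
  mx <- matrix(-Inf, nr, nc); mn <- matrix(Inf, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    ri <- max(1, 1 + di):min(nr, nr + di)
    rj <- max(1, 1 + dj):min(nc, nc + dj)
    si <- ri - di; sj <- rj - dj
    blk <- m[si, sj, drop = FALSE]
    s[ri, rj] <- s[ri, rj] + blk
    n[ri, rj] <- n[ri, rj] + 1
    mx[ri, rj] <- pmax(mx[ri, rj], blk)
    mn[ri, rj] <- pmin(mn[ri, rj], blk)
  }
  list(sum = s, n = n, max = mx, min = mn)
}

#' Relative deviation from the mean value (RDMV)
#'
#' Terrain complexity attribute computed in a 3x3 moving window:
#' `(z_center - mean(window)) / (max(window) - min(window))`, defined as 0
#' where the window range is zero (flat terrain). Edge cells use the
#' truncated window rather than padded values. Values lie in [-1, 1].
#'
#' @param grid A `terrain_grid` or a plain numeric matrix (>= 3x3).
#' @return Matrix of RDMV values, same dimensions as the input.
#' @examples
#' m <- matrix(1, 3, 3); m[2, 2] <- 2
#' rdmv(m)[2, 2]  # (2 - 10/9) / 1 = 8/9
#' @export
rdmv <- function(grid) {
  m <- if (inherits(grid, "terrain_grid")) grid$elevation else grid
  if (nrow(m) < 3 || ncol(m) < 3) stop("grid must be at least 3 x 3")
  st <- shift_stack(m)
  rng <- st$max - st$min
  out <- (m - st$sum / st$n) / rng
  out[rng == 0] <- 0
  out
}
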
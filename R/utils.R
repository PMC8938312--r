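`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific child seed from a master seed
#'
#' Deterministic mixing of a master seed with a stage index, keeping the
#' result inside the 32-bit integer range. Used throughout the package so
#' that one master seed reproducibly drives every stage of an analysis.
#'
#' @param seed integer master seed.
#' @param k integer stage index.
#' @return An integer seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647L * 48271 + k * 7919) %% 2147483647L)
}

## Evaluate `code` under a temporary RNG state seeded with `seed`.
## Restores the caller's RNG stream afterwards so library functions do not
## perturb user-level reproducibility.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Shoelace area of the convex hull of a 2-column coordinate matrix.
## Collinear or degenerate point sets give 0.
hull_area <- function(xy) {
  xy <- unique(xy[stats::complete.cases(xy), , drop = FALSE])
  if (nrow(xy) < 3L) return(0)
  h <- grDevices::chull(xy)
  hx <- xy[h, 1]
  hy <- xy[h, 2]
  n <- length(h)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2
}

#' Project longitude/latitude to planar kilometres
#'
#' Local equirectangular approximation centred on the mean coordinate:
#' adequate for survey extents of tens of kilometres, where all internal
#' distances are treated as planar Euclidean kilometres.
#'
#' @param lon,lat numeric vectors of equal length (decimal degrees).
#' @return A two-column matrix with columns `x`, `y` (km).
#' @export
project_coordinates <- function(lon, lat) {
  stopifnot(length(lon) == length(lat), all(is.finite(lon)), all(is.finite(lat)))
  R <- 6371
  lat0 <- mean(lat)
  x <- R * cos(lat0 * pi / 180) * (lon - mean(lon)) * pi / 180
  y <- R * (lat - lat0) * pi / 180
  cbind(x = x, y = y)
}

## Sample `n` plot combinations of size i from P plots.
## Exhaustive (all C(P, i) combinations) when that is no larger than n or
## when forced; otherwise uniform draws, without replacement within a
## combination but combinations may repeat across draws.
## Returns a list with `combs` (matrix, i rows) and `exhaustive` flag.
sample_combinations <- function(P, i, n, force_exhaustive = FALSE) {
  stopifnot(i >= 1, i <= P)
  n_total <- choose(P, i)
  if (force_exhaustive || n_total <= n) {
    list(combs = utils::combn(P, i), exhaustive = TRUE)
  } else {
    list(combs = replicate(n, sample.int(P, i)), exhaustive = FALSE)
  }
}

## Mean of pairwise absolute differences (1-D values) over an index set.
mean_pairwise_diff <- function(values, idx) {
  mean(stats::dist(values[idx]))
}

## Mean of pairwise Euclidean distances over an index set of coordinates.
mean_pairwise_dist <- function(coords, idx) {
  mean(stats::dist(coords[idx, , drop = FALSE]))
}
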
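## Small internal numerics shared across modules.

clip01 <- function(x) pmin(pmax(x, 0), 1)

## Run `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's stream afterwards. All stochastic operations in the package go
## through this so that identical seeds give identical outputs.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## Trilinear interpolation of a 3D array at continuous 1-based voxel
## coordinates (n x 3 matrix). Points outside the grid return `fill`.
interp_trilinear <- function(arr, coords, fill = 0) {
  d <- dim(arr)
  n <- nrow(coords)
  out <- rep(fill, n)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), max(d[1] - 1L, 1L)); fx <- x - x0
  y0 <- pmin(floor(y), max(d[2] - 1L, 1L)); fy <- y - y0
  z0 <- pmin(floor(z), max(d[3] - 1L, 1L)); fz <- z - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  lin <- function(i, j, k) arr[cbind(i, j, k)]
  v <- lin(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    lin(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    lin(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
    lin(x1, y1, z0) * fx * fy * (1 - fz) +
    lin(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    lin(x1, y0, z1) * fx * (1 - fy) * fz +
    lin(x0, y1, z1) * (1 - fx) * fy * fz +
    lin(x1, y1, z1) * fx * fy * fz
  out[ok] <- v
  out
}

## Nearest-neighbour lookup with the same contract as interp_trilinear.
interp_nearest <- function(arr, coords, fill = 0) {
  d <- dim(arr)
  n <- nrow(coords)
  out <- rep(fill, n)
  i <- round(coords[, 1]); j <- round(coords[, 2]); k <- round(coords[, 3])
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(out)
  out[ok] <- arr[cbind(i[ok], j[ok], k[ok])]
  out
}

## Grid of voxel-centre coordinates, 1-based indices, as an nvox x 3 matrix
## in R array linearization order (x fastest).
voxel_index_grid <- function(dims) {
  cbind(
    rep_len(seq_len(dims[1]), prod(dims)),
    rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
    rep(seq_len(dims[3]), each = dims[1] * dims[2])
  )
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}
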
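#' Grid specification for planar scene rasters
#'
#' All scene layers share one regular grid in a planar metric CRS: cell
#' centres are at `x = x0 + (col - 0.5) * px` and `y = y0 + (row - 0.5) * px`,
#' with row 1 at the southern edge. Distances and speeds computed on these
#' coordinates are exact Euclidean quantities in metres.
#'
#' @param x0,y0 Coordinates of the grid's lower-left corner (metres).
#' @param px Pixel size (metres); pixels are square.
#' @param n_rows,n_cols Grid dimensions.
#' @param crs CRS label; `"planar"` marks synthetic metric coordinates.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(x0 = 0, y0 = 0, px = 500, n_rows, n_cols, crs = "planar") {
  stopifnot(n_rows >= 1, n_cols >= 1, px > 0)
  structure(list(x0 = x0, y0 = y0, px = px, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), crs = crs),
            class = "grid_spec")
}

#' Cell centre coordinates
#' @param grid A [grid_spec()].
#' @param row,col Cell indices (vectorised).
#' @return List with `x`, `y` centre coordinates in metres.
#' @export
cell_xy <- function(grid, row, col) {
  list(x = grid$x0 + (col - 0.5) * grid$px,
       y = grid$y0 + (row - 0.5) * grid$px)
}

#' Containing cell of a point
#'
#' Pixel containment is half-open: a point exactly on a shared cell edge
#' belongs to the cell whose lower/left edge it lies on, so every point maps
#' to exactly one pixel. Points outside the grid return `NA` indices.
#'
#' @param grid A [grid_spec()].
#' @param x,y Point coordinates (vectorised).
#' @return List with integer `row`, `col` (`NA` outside the grid).
#' @export
xy_cell <- function(grid, x, y) {
  col <- floor((x - grid$x0) / grid$px) + 1L
  row <- floor((y - grid$y0) / grid$px) + 1L
  bad <- is.na(row) | is.na(col) |
    row < 1L | row > grid$n_rows | col < 1L | col > grid$n_cols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Sample a raster layer at point locations by pixel containment
#' @param mat Matrix layer on the scene grid (`[row, col]`).
#' @param grid A [grid_spec()].
#' @param x,y Point coordinates.
#' @return Vector of sampled values; `NA` outside the grid.
#' @export
sample_layer <- function(mat, grid, x, y) {
  rc <- xy_cell(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- mat[cbind(rc$row[ok], rc$col[ok])]
  out
}

# 1-d squared Euclidean distance transform (Felzenszwalb & Huttenlocher).
# f: squared distances along a line in pixel units; BIG stands in for +Inf
# so the lower-envelope intersections stay finite.
.edt_1d <- function(f, big) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -big
  z[2L] <- big
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- big
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Exact Euclidean distance transform of a source mask
#'
#' Computes, for every pixel, the centre-to-centre Euclidean distance in
#' metres to the nearest source pixel, using the exact two-pass separable
#' lower-envelope algorithm. Source pixels get distance 0; if the mask has
#' no source pixel the result is all `Inf` and carries attribute
#' `all_infinite = TRUE`.
#'
#' @param source Logical or 0/1 matrix; `TRUE`/1 marks source pixels.
#' @param px Pixel size in metres.
#' @return Numeric matrix of distances (metres).
#' @export
distance_transform <- function(source, px = 1) {
  src <- matrix(as.logical(source), nrow(source), ncol(source))
  nr <- nrow(src); nc <- ncol(src)
  if (!any(src)) {
    out <- matrix(Inf, nr, nc)
    attr(out, "all_infinite") <- TRUE
    return(out)
  }
  big <- (nr * nr + nc * nc + 1) * 4
  f <- matrix(big, nr, nc)
  f[src] <- 0
  # pass 1: along columns (within each column, over rows)
  for (j in seq_len(nc)) f[, j] <- .edt_1d(f[, j], big)
  # pass 2: along rows
  for (i in seq_len(nr)) f[i, ] <- .edt_1d(f[i, ], big)
  out <- sqrt(f) * px
  out[f >= big] <- Inf
  attr(out, "all_infinite") <- FALSE
  out
}

# Band-limited Gaussian random field: white noise smoothed with a circular
# Gaussian kernel via FFT, standardised to zero mean / unit variance.
# Consumes the current RNG stream (callers manage seeding).
gaussian_field <- function(n_rows, n_cols, range_px = 8) {
  w <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  di <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dj <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  k <- exp(-(outer(di^2, dj^2, `+`)) / (2 * range_px^2))
  sm <- Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) /
    (n_rows * n_cols)
  (sm - mean(sm)) / stats::sd(sm)
}
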
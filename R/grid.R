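#' Regular raster grid
#'
#' A minimal in-memory raster: a numeric matrix plus planar georeference
#' (origin and square cell size, coordinates in km). Row 1 of the matrix is
#' the *bottom* row of the grid, so `values[r, c]` sits at
#' `x = xmin + (c - 0.5) * cellsize`, `y = ymin + (r - 0.5) * cellsize`.
#'
#' @param values numeric matrix of cell values (`NA` = no data).
#' @param xmin,ymin coordinates of the lower-left corner (km).
#' @param cellsize cell edge length (km).
#' @return an object of class `rgrid`.
#' @export
rgrid <- function(values, xmin = 0, ymin = 0, cellsize = 1) {
  if (!is.matrix(values)) stopf("`values` must be a matrix")
  if (cellsize <= 0) stopf("`cellsize` must be positive")
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize),
            class = "rgrid")
}

#' @export
print.rgrid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<rgrid> %d x %d cells of %g km, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cellsize, x$xmin, x$ymin))
  cat(sprintf("  values: [%g, %g], %d NA\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.rgrid <- function(x) dim(x$values)

grid_compatible <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize),
                     c(b$xmin, b$ymin, b$cellsize), tolerance = 1e-9))
}

#' Cell-center coordinates of a grid
#'
#' @param g an [rgrid].
#' @return list with matrices `x` and `y` of the same shape as `g$values`.
#' @export
cell_centers <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  x <- matrix(g$xmin + (seq_len(nc) - 0.5) * g$cellsize, nr, nc, byrow = TRUE)
  y <- matrix(g$ymin + (seq_len(nr) - 0.5) * g$cellsize, nr, nc)
  list(x = x, y = y)
}

#' Write / read a grid as ESRI ASCII raster
#'
#' Plain-text `.asc` interchange format: a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of cell values from the top row down.
#'
#' @param g an [rgrid].
#' @param path file path.
#' @param nodata value written for `NA` cells.
#' @return `write_asc` returns `path` invisibly; `read_asc` returns an [rgrid].
#' @export
write_asc <- function(g, path, nodata = -9999) {
  v <- g$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %.10g", nodata)), con)
  # top row first
  for (r in rev(seq_len(nrow(v)))) {
    writeLines(paste(format(v[r, ], digits = 10, trim = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  keys <- vapply(hdr, `[[`, "", 1L)
  vals <- as.numeric(vapply(hdr, `[[`, "", 2L))
  names(vals) <- keys
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # back to bottom-row-first
  m[m == vals[["nodata_value"]]] <- NA_real_
  rgrid(m, vals[["xllcorner"]], vals[["yllcorner"]], vals[["cellsize"]])
}

# Gaussian smoothing of a matrix by exact banded-kernel matrix products,
# normalized at the edges (no wrap-around).
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-d^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Global Moran's I of a grid (rook contiguity)
#'
#' Spatial autocorrelation diagnostic used to verify that simulated
#' environmental layers are spatially structured.
#'
#' @param g an [rgrid] or numeric matrix.
#' @return Moran's I statistic (scalar).
#' @export
moran_i <- function(g) {
  m <- if (inherits(g, "rgrid")) g$values else g
  z <- m - mean(m, na.rm = TRUE)
  z[is.na(z)] <- 0
  nr <- nrow(m); nc <- ncol(m)
  # sum of z_i * z_j over rook-adjacent pairs, each direction counted once
  cross <- sum(z[-nr, ] * z[-1, ]) + sum(z[, -nc] * z[, -1])
  w_sum <- 2 * ((nr - 1) * nc + nr * (nc - 1))  # symmetric weights
  n <- sum(!is.na(m))
  (n / w_sum) * (2 * cross / sum(z^2))
}
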
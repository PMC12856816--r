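#' Regular hexagon geometry
#'
#' Perimeter and area of a regular hexagon of a given side length:
#' `perimeter = 6 s`, `area = (3 sqrt(3) / 2) s^2`. A side of 7.5 km gives a
#' 45-km perimeter and a 146 km2 area (integer-rounded).
#'
#' @param side_km side length (km, > 0).
#' @return list with `perimeter_km` and `area_km2`.
#' @export
hexagon_geometry <- function(side_km) {
  if (side_km <= 0) stopf("side length must be positive")
  list(perimeter_km = 6 * side_km,
       area_km2 = 1.5 * sqrt(3) * side_km^2)
}

# Vertices of a flat-top regular hexagon centered at (cx, cy): two
# horizontal edges, vertices at angles 0, 60, ..., 300 degrees.
hex_vertices <- function(cx, cy, side) {
  ang <- pi / 3 * (0:5)
  cbind(cx + side * cos(ang), cy + side * sin(ang))
}

#' Tessellate a region with hexagonal planning units
#'
#' Lays a flat-top hexagon lattice over the boundary polygon's bounding box
#' (columns spaced `1.5 s`, rows `sqrt(3) s`, odd columns shifted by
#' `sqrt(3) s / 2`; origin at the bounding-box lower-left corner), clips
#' every hexagon to the boundary, and keeps planning units whose clipped
#' area fraction `w` is at least `w_floor`. Interior units have `w = 1`;
#' boundary units are cropped.
#'
#' @param boundary two-column matrix of boundary polygon vertices (km).
#' @param side_km hexagon side length (km).
#' @param w_floor minimum retained area fraction.
#' @return a data.frame of class `pu_lattice` with columns `id`, `x`, `y`
#'   (center), `w` (area fraction in (0, 1]), `area_km2`; attributes:
#'   `side_km`, `vertices` (list of clipped polygons), `hex_vertices`
#'   (uncropped), `boundary`, `adjacency` (two-column matrix of adjacent id
#'   pairs on the uncropped lattice).
#' @export
tessellate_hexagons <- function(boundary, side_km, w_floor = 0.01) {
  if (nrow(boundary) < 3L) stopf("boundary must be a polygon")
  boundary <- ccw(as.matrix(boundary))
  s <- side_km
  full_area <- hexagon_geometry(s)$area_km2
  bx <- range(boundary[, 1]); by <- range(boundary[, 2])
  dxc <- 1.5 * s; dyr <- sqrt(3) * s
  cols <- seq(bx[1] - s, bx[2] + s, by = dxc)
  keep <- list(); centers <- list()
  for (ci in seq_along(cols)) {
    yoff <- if (ci %% 2 == 0) dyr / 2 else 0
    rows <- seq(by[1] - s + yoff, by[2] + s + yoff, by = dyr)
    for (y in rows) centers[[length(centers) + 1L]] <- c(cols[ci], y)
  }
  centers <- do.call(rbind, centers)
  n <- 0L
  ids <- integer(0); xs <- ys <- ws <- numeric(0)
  clipped <- list(); hexes <- list()
  for (i in seq_len(nrow(centers))) {
    hx <- hex_vertices(centers[i, 1], centers[i, 2], s)
    clip <- clip_polygon_convex(boundary, hx)
    a <- polygon_area(clip)
    w <- min(a / full_area, 1)
    if (w < w_floor) next
    n <- n + 1L
    ids <- c(ids, n); xs <- c(xs, centers[i, 1]); ys <- c(ys, centers[i, 2])
    ws <- c(ws, w)
    clipped[[n]] <- clip
    hexes[[n]] <- hx
  }
  if (n == 0L) stopf("boundary does not intersect the hexagon lattice")
  pus <- data.frame(id = ids, x = xs, y = ys, w = ws,
                    area_km2 = ws * full_area)
  # adjacency: all 6 lattice neighbors sit at center distance sqrt(3) s
  d <- as.matrix(stats::dist(cbind(xs, ys)))
  adj <- which(d > 0 & d < sqrt(3) * s * 1.01, arr.ind = TRUE)
  adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
  structure(pus, class = c("pu_lattice", "data.frame"),
            side_km = s, vertices = clipped, hex_vertices = hexes,
            boundary = boundary, adjacency = adj)
}

#' @export
print.pu_lattice <- function(x, ...) {
  cat(sprintf("<pu_lattice> %d hexagonal planning units, side %g km (%d cropped)\n",
              nrow(x), attr(x, "side_km"), sum(x$w < 1 - 1e-9)))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}
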
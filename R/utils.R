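#' @keywords internal
"_PACKAGE"

# Sample skewness (m3 / m2^1.5). Used to decide which predictors get a log
# transform before standardization.
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Shoelace area of a closed or open polygon ring (n x 2 matrix).
polygon_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(0)
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Sutherland-Hodgman clipping of an arbitrary simple polygon `subject`
# against a convex polygon `clip` (both n x 2, counter-clockwise).
# Returns the clipped polygon (possibly with zero rows).
clip_polygon_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[e, ]
    b <- clip[if (e == nc) 1L else e + 1L, ]
    # inside = left of directed edge a->b for CCW clip polygon
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    inp <- out
    out <- matrix(numeric(0), ncol = 2L)
    n <- nrow(inp)
    sv <- inp[n, ]
    s_in <- side(sv) >= -1e-12
    for (i in seq_len(n)) {
      ev <- inp[i, ]
      e_in <- side(ev) >= -1e-12
      if (e_in) {
        if (!s_in) out <- rbind(out, segment_intersect(sv, ev, a, b))
        out <- rbind(out, ev)
      } else if (s_in) {
        out <- rbind(out, segment_intersect(sv, ev, a, b))
      }
      sv <- ev
      s_in <- e_in
    }
  }
  out
}

# Intersection of segment p1-p2 with the infinite line a-b.
segment_intersect <- function(p1, p2, a, b) {
  d1 <- p2 - p1
  d2 <- b - a
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(denom) < 1e-300) return(p2)
  t <- ((a[1] - p1[1]) * d2[2] - (a[2] - p1[2]) * d2[1]) / denom
  p1 + t * d1
}

# Ensure a polygon ring is counter-clockwise.
ccw <- function(xy) {
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1L))
  s <- sum(xy[j, 1L] * xy[, 2L] - xy[, 1L] * xy[j, 2L]) / 2
  if (s < 0) xy[rev(seq_len(n)), , drop = FALSE] else xy
}

# Point-in-polygon test (boundary counts as inside).
points_in_polygon <- function(x, y, poly) {
  sp::point.in.polygon(x, y, poly[, 1L], poly[, 2L]) > 0L
}
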
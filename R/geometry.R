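# Planar polygon primitives shared by the volumetry, decomposition and phantom
# code. Contours are n x 2 matrices of (x, y) vertices in mm, implicitly closed.

# Signed shoelace area; positive when vertices run counter-clockwise.
polygon_area_signed <- function(xy) {
  x <- xy[, 1L]
  y <- xy[, 2L]
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(xy) abs(polygon_area_signed(xy))

polygon_centroid <- function(xy) {
  x <- xy[, 1L]
  y <- xy[, 2L]
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) {
    return(c(mean(x), mean(y)))
  }
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a)
}

# Orient counter-clockwise (interior to the left of travel).
polygon_ccw <- function(xy) {
  if (polygon_area_signed(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

# Robust simplicity check: any two non-adjacent edges must not intersect.
# All O(n^2) pairs are tested in one vectorised call.
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  p <- xy
  q <- xy[c(2:n, 1L), , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j) {
    j > i + 1L & !(i == 1L & j == n)
  }), arr.ind = TRUE)
  if (!nrow(idx)) return(TRUE)
  i <- idx[, 1L]
  j <- idx[, 2L]
  !any(segments_intersect(
    p[i, 1L], p[i, 2L], q[i, 1L], q[i, 2L],
    p[j, 1L], p[j, 2L], q[j, 1L], q[j, 2L]
  ))
}

# Proper/improper intersection test between segment (ax,ay)-(bx,by) and the
# vectorised segments (cx,cy)-(dx,dy).
segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  proper <- (sign(d1) * sign(d2) < 0) & (sign(d3) * sign(d4) < 0)
  # collinear overlaps count as intersections too
  col <- (d1 == 0 & on_segment(ax, ay, bx, by, cx, cy)) |
    (d2 == 0 & on_segment(ax, ay, bx, by, dx, dy)) |
    (d3 == 0 & on_segment(cx, cy, dx, dy, ax, ay)) |
    (d4 == 0 & on_segment(cx, cy, dx, dy, bx, by))
  proper | col
}

on_segment <- function(ax, ay, bx, by, px, py) {
  px >= pmin(ax, bx) & px <= pmax(ax, bx) & py >= pmin(ay, by) & py <= pmax(ay, by)
}

# Minimum distance from point (px, py) to the closed polyline xy.
point_polygon_distance <- function(px, py, xy) {
  n <- nrow(xy)
  x1 <- xy[, 1L]
  y1 <- xy[, 2L]
  x2 <- c(x1[-1L], x1[1L])
  y2 <- c(y1[-1L], y1[1L])
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- ((px - x1) * dx + (py - y1) * dy) / pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  qx <- x1 + t * dx
  qy <- y1 + t * dy
  sqrt(min((px - qx)^2 + (py - qy)^2))
}

# Even-odd point-in-polygon for a single point (used by validation).
point_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  x1 <- xy[, 1L]
  y1 <- xy[, 2L]
  x2 <- c(x1[-1L], x1[1L])
  y2 <- c(y1[-1L], y1[1L])
  crosses <- ((y1 > py) != (y2 > py)) &
    (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
  sum(crosses) %% 2L == 1L
}

# Vectorised even-odd test: are the points (px, py) inside polygon xy?
points_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  x1 <- xy[, 1L]
  y1 <- xy[, 2L]
  x2 <- c(x1[-1L], x1[1L])
  y2 <- c(y1[-1L], y1[1L])
  crossings <- integer(length(px))
  for (e in seq_len(n)) {
    if (y1[e] == y2[e]) next
    hit <- ((y1[e] > py) != (y2[e] > py)) &
      (px < (x2[e] - x1[e]) * (py - y1[e]) / (y2[e] - y1[e]) + x1[e])
    crossings <- crossings + hit
  }
  crossings %% 2L == 1L
}

# Scanline rasterization: number of pixel centres inside the polygon on a grid
# with spacing `res` anchored at half-pixel offsets of the supplied bounding
# box. Returns the pixel count; area = count * res^2. The grid is defined by
# the caller's bbox so that two polygons can share one grid exactly.
raster_pixel_count <- function(xy, res, bbox) {
  ys <- seq(bbox[3L] + res / 2, bbox[4L], by = res)
  if (!length(ys)) return(0)
  n <- nrow(xy)
  x1 <- xy[, 1L]
  y1 <- xy[, 2L]
  x2 <- c(x1[-1L], x1[1L])
  y2 <- c(y1[-1L], y1[1L])
  keep <- y1 != y2 # horizontal edges never cross a scanline properly
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  x0 <- bbox[1L] + res / 2
  total <- 0
  for (y in ys) {
    hit <- (y1 > y) != (y2 > y)
    if (!any(hit)) next
    xc <- sort(x1[hit] + (x2[hit] - x1[hit]) * (y - y1[hit]) / (y2[hit] - y1[hit]))
    m <- length(xc)
    if (m %% 2L == 1L) xc <- xc[-m] # numerically degenerate vertex graze
    if (!length(xc)) next
    lo <- xc[seq(1L, length(xc), by = 2L)]
    hi <- xc[seq(2L, length(xc), by = 2L)]
    # pixel centres x0 + k*res within [lo, hi]
    total <- total + sum(pmax(0, floor((hi - x0) / res) - ceiling((lo - x0) / res) + 1))
  }
  total
}

# Shared bounding box of a list of polygons, padded by `pad`.
polygons_bbox <- function(polys, pad = 0) {
  xs <- unlist(lapply(polys, function(p) range(p[, 1L])))
  ys <- unlist(lapply(polys, function(p) range(p[, 2L])))
  c(min(xs) - pad, max(xs) + pad, min(ys) - pad, max(ys) + pad)
}

# Regular m-gon whose *polygon* area is exactly `area` (not the circumscribed
# circle area), centred at (cx, cy). Used by the phantom so that shoelace
# volumetry reproduces prescribed volumes to machine precision.
circle_polygon_exact_area <- function(area, n_vertices, cx = 0, cy = 0, phase = 0) {
  r <- sqrt(2 * area / (n_vertices * sin(2 * pi / n_vertices)))
  th <- phase + 2 * pi * seq(0L, n_vertices - 1L) / n_vertices
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Trapezoidal integral of y over x (used for flow curves; x in ms handled by
# the caller).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}
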
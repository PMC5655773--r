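# Independent oracles, deliberately implemented with different algorithms
# than the package (winding-number point test vs the package's scanline
# fill / crossing count).

# Winding-number point-in-polygon: sum of signed angles subtended by edges.
winding_inside <- function(px, py, xy) {
  n <- nrow(xy)
  x1 <- xy[, 1L] - px
  y1 <- xy[, 2L] - py
  x2 <- c(x1[-1L], x1[1L])
  y2 <- c(y1[-1L], y1[1L])
  ang <- atan2(x1 * y2 - y1 * x2, x1 * x2 + y1 * y2)
  abs(sum(ang)) > pi
}

# Monte-Carlo area of a polygon from uniform points in a bounding box.
mc_polygon_area <- function(xy, n_points, bbox = NULL) {
  if (is.null(bbox)) {
    bbox <- c(min(xy[, 1L]), max(xy[, 1L]), min(xy[, 2L]), max(xy[, 2L]))
  }
  px <- runif(n_points, bbox[1L], bbox[2L])
  py <- runif(n_points, bbox[3L], bbox[4L])
  inside <- vapply(seq_len(n_points), function(i) {
    winding_inside(px[i], py[i], xy)
  }, logical(1L))
  mean(inside) * (bbox[2L] - bbox[1L]) * (bbox[4L] - bbox[3L])
}

# Faster vectorised Monte-Carlo area via a crossing test written against
# matrix recycling (still independent of the package's scanline path).
mc_polygon_area_fast <- function(xy, n_points, bbox = NULL) {
  if (is.null(bbox)) {
    bbox <- c(min(xy[, 1L]), max(xy[, 1L]), min(xy[, 2L]), max(xy[, 2L]))
  }
  px <- runif(n_points, bbox[1L], bbox[2L])
  py <- runif(n_points, bbox[3L], bbox[4L])
  x1 <- xy[, 1L]
  y1 <- xy[, 2L]
  x2 <- c(x1[-1L], x1[1L])
  y2 <- c(y1[-1L], y1[1L])
  crossings <- integer(n_points)
  for (e in seq_len(nrow(xy))) {
    if (y1[e] == y2[e]) next
    t <- (py - y1[e]) / (y2[e] - y1[e])
    hit <- (t >= 0) & (t < 1) & (px < x1[e] + t * (x2[e] - x1[e]))
    crossings <- crossings + hit
  }
  mean(crossings %% 2L == 1L) * (bbox[2L] - bbox[1L]) * (bbox[4L] - bbox[3L])
}

# Monte-Carlo estimate of area(A) - area(B) with common random points
# (classic variance reduction: only points in the symmetric difference
# contribute to the estimator's variance).
mc_region_diff <- function(a, b, n_points, bbox) {
  px <- runif(n_points, bbox[1L], bbox[2L])
  py <- runif(n_points, bbox[3L], bbox[4L])
  inside <- function(xy) {
    x1 <- xy[, 1L]
    y1 <- xy[, 2L]
    x2 <- c(x1[-1L], x1[1L])
    y2 <- c(y1[-1L], y1[1L])
    crossings <- integer(n_points)
    for (e in seq_len(nrow(xy))) {
      if (y1[e] == y2[e]) next
      t <- (py - y1[e]) / (y2[e] - y1[e])
      crossings <- crossings + ((t >= 0) & (t < 1) &
                                  (px < x1[e] + t * (x2[e] - x1[e])))
    }
    crossings %% 2L == 1L
  }
  (mean(inside(a)) - mean(inside(b))) *
    (bbox[2L] - bbox[1L]) * (bbox[4L] - bbox[3L])
}

# Extract the polygon of one structure from a study (test-side convenience).
get_poly <- function(study, frame, slice, structure) {
  k <- study$contours
  sub <- k[k$frame == frame & k$slice == slice & k$structure == structure, ]
  sub <- sub[order(sub$vertex), ]
  cbind(sub$x_mm, sub$y_mm)
}
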
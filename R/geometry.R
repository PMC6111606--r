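# Minimal planar-geometry kernel for polygon footprints in a projected CRS.
#
# Polygons are n x 2 numeric matrices (columns x, y), open rings (the first
# vertex is not repeated at the end), vertices in any consistent winding.
# Footprints in practice are small simple polygons (rectangles in the
# synthetic cities); admin units and grid cells may be arbitrary simple
# polygons on the subject side of a clip.

poly_matrix <- function(x, y) {
  m <- cbind(x = as.numeric(x), y = as.numeric(y))
  if (nrow(m) >= 2 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  if (nrow(m) < 3) abort("a polygon needs at least 3 distinct vertices")
  m
}

# Axis-aligned rectangle as a polygon (counter-clockwise).
rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

# Signed shoelace area; poly_area() is the absolute area in m2.
poly_signed_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

poly_area <- function(p) abs(poly_signed_area(p))

poly_bbox <- function(p) {
  c(xmin = min(p[, 1]), ymin = min(p[, 2]), xmax = max(p[, 1]), ymax = max(p[, 2]))
}

# Area-weighted centroid; degenerate (zero-area) polygons fall back to the
# vertex mean. Used as the representative point for containment fallbacks.
poly_centroid <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((p[, 1] + p[j, 1]) * cr), sum((p[, 2] + p[j, 2]) * cr)) / (6 * a)
}

# Even-odd ray casting; boundary points count as inside.
point_in_poly <- function(pt, p) {
  x <- pt[1]; y <- pt[2]
  n <- nrow(p)
  j <- c(2:n, 1)
  x1 <- p[, 1]; y1 <- p[, 2]; x2 <- p[j, 1]; y2 <- p[j, 2]
  # on-edge check
  dx <- x2 - x1; dy <- y2 - y1
  t_num <- (x - x1) * dx + (y - y1) * dy
  len2 <- dx^2 + dy^2
  tt <- ifelse(len2 > 0, pmin(1, pmax(0, t_num / len2)), 0)
  d2 <- (x1 + tt * dx - x)^2 + (y1 + tt * dy - y)^2
  if (any(d2 < 1e-18)) return(TRUE)
  crosses <- ((y1 > y) != (y2 > y)) &
    (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
  sum(crosses) %% 2 == 1
}

# Sutherland-Hodgman: clip an arbitrary simple subject polygon against a
# CONVEX clip polygon. The output may contain coincident edges when the
# subject is concave; its shoelace area still equals the intersection area.
clip_poly_convex <- function(subject, clip) {
  if (poly_signed_area(clip) < 0) clip <- clip[nrow(clip):1, , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (k in seq_len(nc)) {
    if (nrow(out) == 0) return(out)
    a <- clip[k, ]
    b <- clip[if (k == nc) 1 else k + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # inside = left of directed edge a->b (CCW clip polygon)
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    inside <- side >= -1e-9
    n <- nrow(out)
    res_x <- numeric(0); res_y <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      p1 <- out[i, ]; p2 <- out[j, ]
      in1 <- inside[i]; in2 <- inside[j]
      if (in1) { res_x <- c(res_x, p1[1]); res_y <- c(res_y, p1[2]) }
      if (xor(in1, in2)) {
        denom <- side[i] - side[j]
        t <- if (abs(denom) < 1e-30) 0 else side[i] / denom
        res_x <- c(res_x, p1[1] + t * (p2[1] - p1[1]))
        res_y <- c(res_y, p1[2] + t * (p2[2] - p1[2]))
      }
    }
    out <- cbind(x = res_x, y = res_y)
  }
  out
}

is_axis_rect <- function(p) {
  if (nrow(p) != 4) return(FALSE)
  xs <- sort(unique(round(p[, 1], 9))); ys <- sort(unique(round(p[, 2], 9)))
  length(xs) == 2 && length(ys) == 2
}

# Intersection area of a simple polygon with a convex polygon, with a fast
# path when both are axis-aligned rectangles.
intersection_area <- function(subject, clip) {
  bs <- poly_bbox(subject); bc <- poly_bbox(clip)
  if (bs["xmin"] >= bc["xmax"] || bs["xmax"] <= bc["xmin"] ||
      bs["ymin"] >= bc["ymax"] || bs["ymax"] <= bc["ymin"]) {
    return(0)
  }
  if (is_axis_rect(subject) && is_axis_rect(clip)) {
    w <- min(bs["xmax"], bc["xmax"]) - max(bs["xmin"], bc["xmin"])
    h <- min(bs["ymax"], bc["ymax"]) - max(bs["ymin"], bc["ymin"])
    return(max(0, w) * max(0, h))
  }
  clipped <- clip_poly_convex(subject, clip)
  if (nrow(clipped) < 3) 0 else poly_area(clipped)
}

# Minimum Euclidean distance from a point to a polyline (k x 2 matrix).
point_segline_dist <- function(x, y, line) {
  n <- nrow(line)
  if (n == 1) return(sqrt((x - line[1, 1])^2 + (y - line[1, 2])^2))
  x1 <- line[-n, 1]; y1 <- line[-n, 2]
  x2 <- line[-1, 1]; y2 <- line[-1, 2]
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  tt <- ifelse(len2 > 0, pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / len2)), 0)
  min(sqrt((x1 + tt * dx - x)^2 + (y1 + tt * dy - y)^2))
}
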
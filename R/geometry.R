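# Planar primitives for closed contours stored as n x 2 matrices (mm).
# Contours are open-ring matrices: the edge from the last row back to the
# first row is implicit.  All arc positions are measured counter-clockwise
# from the first vertex.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("zero-length direction vector", call. = FALSE)
  v / n
}

# 90 degree counter-clockwise rotation
perp_vec <- function(v) c(-v[2], v[1])

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

as_contour <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || ncol(m) != 2) {
    stop("a contour must be a numeric matrix with two columns", call. = FALSE)
  }
  # drop an explicitly repeated closing vertex
  n <- nrow(m)
  if (n > 1 && isTRUE(all(m[1, ] == m[n, ]))) m <- m[-n, , drop = FALSE]
  if (nrow(m) < 3) stop("a contour needs at least 3 vertices", call. = FALSE)
  if (!all(is.finite(m))) stop("contour coordinates must be finite", call. = FALSE)
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}

poly_signed_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

poly_ensure_ccw <- function(m) {
  if (poly_signed_area(m) < 0) m[rev(seq_len(nrow(m))), , drop = FALSE] else m
}

poly_next <- function(m) m[c(seq_len(nrow(m))[-1], 1L), , drop = FALSE]

poly_edge_lengths <- function(m) {
  d <- poly_next(m) - m
  sqrt(rowSums(d * d))
}

poly_perimeter <- function(m) sum(poly_edge_lengths(m))

# arc position of vertex i (counter-clockwise from vertex 1)
poly_vertex_s <- function(m) {
  len <- poly_edge_lengths(m)
  c(0, cumsum(len)[-length(len)])
}

poly_centroid <- function(m) colMeans(m)

poly_is_convex <- function(m, tol = 1e-9) {
  m <- poly_ensure_ccw(m)
  e <- poly_next(m) - m
  en <- e[c(seq_len(nrow(e))[-1], 1L), , drop = FALSE]
  cr <- e[, 1] * en[, 2] - e[, 2] * en[, 1]
  scale <- max(abs(m))^2 + 1
  all(cr >= -tol * scale)
}

seg_intersects <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) {
    return(TRUE)
  }
  FALSE
}

# Simplicity check: no two non-adjacent edges properly intersect.
poly_is_simple <- function(m) {
  n <- nrow(m)
  nxt <- poly_next(m)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in seq(i + 2, jmax)) {
      if (seg_intersects(m[i, ], nxt[i, ], m[j, ], nxt[j, ])) return(FALSE)
    }
  }
  TRUE
}

# Point at arc position s (wrapped into [0, perimeter)).
poly_point_at <- function(m, s) {
  per <- poly_perimeter(m)
  s <- s %% per
  starts <- poly_vertex_s(m)
  len <- poly_edge_lengths(m)
  i <- findInterval(s, starts)
  t <- (s - starts[i]) / len[i]
  a <- m[i, ]
  b <- poly_next(m)[i, ]
  a + t * (b - a)
}

# Nearest point on the closed contour; returns arc position, point, distance.
poly_snap <- function(m, p) {
  a <- m
  b <- poly_next(m)
  e <- b - a
  len2 <- rowSums(e * e)
  len2[len2 == 0] <- 1
  t <- ((p[1] - a[, 1]) * e[, 1] + (p[2] - a[, 2]) * e[, 2]) / len2
  t <- pmin(pmax(t, 0), 1)
  qx <- a[, 1] + t * e[, 1]
  qy <- a[, 2] + t * e[, 2]
  d2 <- (p[1] - qx)^2 + (p[2] - qy)^2
  i <- which.min(d2)
  starts <- poly_vertex_s(m)
  len <- poly_edge_lengths(m)
  list(
    s = starts[i] + t[i] * len[i],
    point = c(x = qx[i], y = qy[i]),
    dist = sqrt(d2[i]),
    edge = i,
    t = t[i]
  )
}

arc_forward <- function(s_from, s_to, per) (s_to - s_from) %% per

# Sub-polyline along the contour from arc position s_from to s_to,
# travelling counter-clockwise (increasing s, wrapping at the perimeter).
poly_subpath <- function(m, s_from, s_to) {
  per <- poly_perimeter(m)
  starts <- poly_vertex_s(m)
  span <- arc_forward(s_from, s_to, per)
  rel <- arc_forward(s_from, starts, per)
  keep <- which(rel > 1e-12 & rel < span - 1e-12)
  keep <- keep[order(rel[keep])]
  pts <- rbind(poly_point_at(m, s_from), m[keep, , drop = FALSE],
               poly_point_at(m, s_to))
  dimnames(pts) <- list(NULL, c("x", "y"))
  pts
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- diff(pts)
  # accumulate exactly as polyline_snap does, so that the arc position of
  # the final vertex equals the total length to the last bit
  cs <- cumsum(sqrt(rowSums(d * d)))
  cs[length(cs)]
}

# Nearest point on an open polyline; s is arc position along the polyline.
polyline_snap <- function(pts, p) {
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1, , drop = FALSE]
  e <- b - a
  len2 <- rowSums(e * e)
  len <- sqrt(len2)
  len2[len2 == 0] <- 1
  t <- ((p[1] - a[, 1]) * e[, 1] + (p[2] - a[, 2]) * e[, 2]) / len2
  t <- pmin(pmax(t, 0), 1)
  qx <- a[, 1] + t * e[, 1]
  qy <- a[, 2] + t * e[, 2]
  d2 <- (p[1] - qx)^2 + (p[2] - qy)^2
  i <- which.min(d2)
  starts <- c(0, cumsum(len))[seq_len(nrow(a))]
  list(
    s = starts[i] + t[i] * len[i],
    point = c(x = qx[i], y = qy[i]),
    dist = sqrt(d2[i])
  )
}

# All crossings of the infinite line p0 + t*u with the contour edges.
# Returns a list of parallel vectors: t (signed distance along u for unit
# u), the crossing point x/y, the host edge and the contour arc position.
line_poly_crossings <- function(m, p0, u, eps = 1e-9) {
  a <- m
  b <- poly_next(m)
  e <- b - a
  len <- poly_edge_lengths(m)
  denom <- u[1] * e[, 2] - u[2] * e[, 1]        # cross(u, e)
  w1 <- a[, 1] - p0[1]
  w2 <- a[, 2] - p0[2]
  # solve p0 + t u = a + s e  =>  t = cross(w, e)/cross(u, e); s = cross(w, u)/cross(u, e)
  ok <- abs(denom) > 1e-14 * (max(abs(m)) + 1)
  t <- (w1 * e[, 2] - w2 * e[, 1]) / denom
  s <- (w1 * u[2] - w2 * u[1]) / denom
  tol_s <- eps / pmax(len, eps)
  hit <- ok & s >= -tol_s & s <= 1 + tol_s
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) {
    return(list(t = numeric(0), x = numeric(0), y = numeric(0),
                edge = integer(0), s_arc = numeric(0), n = 0L))
  }
  idx <- which(hit)
  sc <- pmin(pmax(s[idx], 0), 1)
  px <- a[idx, 1] + sc * e[idx, 1]
  py <- a[idx, 2] + sc * e[idx, 2]
  starts <- poly_vertex_s(m)
  tt <- t[idx]
  s_arc <- starts[idx] + sc * len[idx]
  if (length(idx) > 1) {
    o <- order(tt)
    tt <- tt[o]; px <- px[o]; py <- py[o]; idx <- idx[o]; s_arc <- s_arc[o]
    # de-duplicate vertex hits shared by adjacent edges
    keep <- c(TRUE, sqrt(diff(px)^2 + diff(py)^2) > 10 * eps |
                diff(tt) > 10 * eps)
    tt <- tt[keep]; px <- px[keep]; py <- py[keep]
    idx <- idx[keep]; s_arc <- s_arc[keep]
  }
  list(t = tt, x = px, y = py, edge = idx, s_arc = s_arc, n = length(tt))
}

# Does the infinite line through p0 with direction u meet the polygon?
# A pass within eps of any vertex counts as a tangency hit.
line_hits_poly <- function(m, p0, u, eps = 1e-9) {
  a <- m
  b <- poly_next(m)
  e <- b - a
  denom <- u[1] * e[, 2] - u[2] * e[, 1]
  w1 <- a[, 1] - p0[1]
  w2 <- a[, 2] - p0[2]
  s <- (w1 * u[2] - w2 * u[1]) / denom
  ok <- abs(denom) > 1e-14 * (max(abs(m)) + 1)
  if (any(ok & s >= 0 & s <= 1, na.rm = TRUE)) return(TRUE)
  # vertex tangency (also covers edges parallel to the line)
  dv <- abs(u[1] * (m[, 2] - p0[2]) - u[2] * (m[, 1] - p0[1]))
  any(dv <= eps)
}

points_in_poly <- function(m, px, py) {
  pracma::inpolygon(px, py, m[, 1], m[, 2], boundary = TRUE)
}

point_in_poly <- function(m, p) {
  as.logical(points_in_poly(m, p[1], p[2]))
}

# Signed perpendicular distance of points from the line a -> b
# (positive on the left of a->b).
signed_line_dist <- function(a, b, px, py) {
  u <- unit_vec(b - a)
  u[1] * (py - a[2]) - u[2] * (px - a[1])
}
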
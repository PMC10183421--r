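# Fixtures and independent oracles used across the suite.  Oracles are
# deliberately written against first principles (explicit per-edge loops,
# raster containment, generic optimisation) rather than the package's
# solvers.

# A triangular section from explicit apexes.  Anchors default to the
# medial wedge facing the apex chord (both apexes are silhouette vertices
# from there).
tri_section <- function(v7 = c(12.5, 0), v8 = c(-12.5, 0), v9 = c(0, 15),
                        anchor1 = c(10, -20), anchor4 = c(-10, -20),
                        step = NULL, id = "tri") {
  contour <- rbind(v7, v9, v8)
  if (!is.null(step)) {
    dens <- function(a, b) {
      k <- max(1L, ceiling(sqrt(sum((b - a)^2)) / step))
      t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
      cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    }
    contour <- rbind(dens(v7, v9), dens(v9, v8), dens(v8, v7))
  }
  cross_section(contour,
                list(anterior_anchor = anchor1, posterior_anchor = anchor4,
                     anterior_apex = v7, posterior_apex = v8,
                     lateral_apex = v9),
                subject_id = id)
}

# Default-geometry convex cohort (no landmark noise) for solver tests.
convex_cohort <- function(n, seed, oblique = TRUE, noise = 0) {
  p <- cohort_params(
    n_subjects = n,
    shape_mixture = c(triangular_convex = 0.9, triangular = 0,
                      quadrilateral = 0.1, irregular = 0),
    landmark_noise_sd_mm = noise,
    seed = seed
  )
  if (!oblique) {
    # medial-wedge anchors at full tibial depth: both apexes are
    # silhouette vertices from here
    p$anterior_anchor_offset_mm <- c(x = 8, y = -28)
    p$posterior_anchor_offset_mm <- c(x = -8, y = -28)
    p$anchor_jitter_sd_mm <- 1
  }
  generate_cohort(p)
}

rand_similarity <- function() {
  list(theta = stats::runif(1, 0, 2 * pi),
       s = stats::runif(1, 0.6, 1.8),
       t = stats::runif(2, -30, 30))
}

apply_sim <- function(sim, pts) {
  R <- matrix(c(cos(sim$theta), sin(sim$theta),
                -sin(sim$theta), cos(sim$theta)), 2)
  single <- is.null(dim(pts))
  p <- if (single) matrix(pts, 1) else as.matrix(pts)
  out <- sweep(sim$s * (p %*% t(R)), 2, sim$t, `+`)
  if (single) c(out) else out
}

# Rebuild a section from transformed raw coordinates (does not reuse the
# package's transform_section).
transform_section_raw <- function(cs, sim) {
  lm <- lapply(cs$landmarks[c("anterior_anchor", "posterior_anchor",
                              "anterior_apex", "posterior_apex",
                              "lateral_apex")],
               function(p) apply_sim(sim, p))
  cross_section(apply_sim(sim, cs$contour), lm, subject_id = cs$subject_id,
                side = cs$side, snap_tol = cs$snap_tol * sim$s)
}

# Brute-force line/polygon crossings: explicit per-edge 2x2 solve.
oracle_line_crossings <- function(m, p0, u) {
  n <- nrow(m)
  out <- NULL
  for (i in seq_len(n)) {
    a <- m[i, ]; b <- m[if (i == n) 1 else i + 1, ]
    A <- cbind(u, -(b - a))
    if (abs(det(A)) < 1e-12) next
    ts <- solve(A, a - p0)
    if (ts[2] >= 0 && ts[2] <= 1) out <- c(out, ts[1])
  }
  if (is.null(out)) return(numeric(0))
  sort(unique(round(out, 9)))
}

# Raster containment oracle for strip feasibility on convex sections:
# both strip boundary lines must contain at least one sample point (0.05
# mm spacing) inside the polygon, with half-grid boundary coverage.
raster_line_hits <- function(hull, p0, u, res = 0.05) {
  tproj <- as.numeric((sweep(hull, 2, p0) %*% u))
  # regular 0.05 mm sampling plus the perpendicular feet of the hull
  # vertices, so a tangency chord always carries a sample point
  ts <- c(seq(min(tproj) - 2, max(tproj) + 2, by = res), tproj)
  px <- p0[1] + ts * u[1]
  py <- p0[2] + ts * u[2]
  a <- hull
  b <- hull[c(seq_len(nrow(hull))[-1], 1L), , drop = FALSE]
  e <- b - a
  len <- sqrt(rowSums(e * e))
  # pure point containment: signed distance to every edge line of the ccw
  # convex hull must be non-negative (boundary inclusive)
  inside <- rep(TRUE, length(ts))
  for (i in seq_len(nrow(hull))) {
    sd <- (e[i, 1] * (py - a[i, 2]) - e[i, 2] * (px - a[i, 1])) / len[i]
    inside <- inside & (sd >= -1e-9)
    if (!any(inside)) return(FALSE)
  }
  any(inside)
}

raster_strip_feasible <- function(hull, anchor, theta, d, res = 0.05) {
  u <- c(cos(theta), sin(theta))
  nv <- c(-u[2], u[1])
  raster_line_hits(hull, anchor + nv * d / 2, u, res) &&
    raster_line_hits(hull, anchor - nv * d / 2, u, res)
}

# Vectorised brute-force crossings of a line with all contour edges
# (independent re-derivation of the standard 2x2 solve).
oracle_crossings_fast <- function(m, p0, u) {
  n <- nrow(m)
  a <- m
  b <- m[c(2:n, 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  den <- u[1] * ey - u[2] * ex
  wx <- a[, 1] - p0[1]; wy <- a[, 2] - p0[2]
  s <- (wx * u[2] - wy * u[1]) / den
  t <- (wx * ey - wy * ex) / den
  ok <- is.finite(s) & s >= -1e-9 & s <= 1 + 1e-9
  list(t = t[ok], x = a[ok, 1] + pmin(pmax(s[ok], 0), 1) * ex[ok],
       y = a[ok, 2] + pmin(pmax(s[ok], 0), 1) * ey[ok])
}

# Arc position of the contour point nearest to p (independent snap).
oracle_arc_pos <- function(m, p) {
  n <- nrow(m)
  a <- m
  b <- m[c(2:n, 1), , drop = FALSE]
  e <- b - a
  L2 <- rowSums(e * e)
  L <- sqrt(L2)
  t <- pmin(pmax(((p[1] - a[, 1]) * e[, 1] + (p[2] - a[, 2]) * e[, 2]) / L2, 0), 1)
  qx <- a[, 1] + t * e[, 1]; qy <- a[, 2] + t * e[, 2]
  d2 <- (p[1] - qx)^2 + (p[2] - qy)^2
  i <- which.min(d2)
  starts <- c(0, cumsum(L))
  c(s = starts[i] + t[i] * L[i], per = sum(L))
}

# Does the axis at angle theta exit through the lateral cortex (the arc
# between the apexes passing the lateral apex), taking the crossing
# farthest from the anchor?
oracle_exit_lateral <- function(m, apexes, anchor, theta) {
  u <- c(cos(theta), sin(theta))
  cr <- oracle_crossings_fast(m, anchor, u)
  if (length(cr$t) == 0) return(FALSE)
  i <- which.max(abs(cr$t))
  p <- c(cr$x[i], cr$y[i])
  per <- oracle_arc_pos(m, apexes$a7)["per"]
  s7 <- oracle_arc_pos(m, apexes$a7)["s"]
  s8 <- oracle_arc_pos(m, apexes$a8)["s"]
  s9 <- oracle_arc_pos(m, apexes$a9)["s"]
  sp <- oracle_arc_pos(m, p)["s"]
  fwd <- function(x, y) (y - x) %% per
  tol <- 1e-6 * per
  if (fwd(s7, s9) <= fwd(s7, s8)) {
    fwd(s7, sp) <= fwd(s7, s8) + tol
  } else {
    fwd(s8, sp) <= fwd(s8, s7) + tol
  }
}

# Brute-force angular sweep with the raster containment oracle plus the
# lateral-exit condition: 0.01 degree steps around the coarse
# feasibility boundaries.
oracle_extremes_raster <- function(cs, anchor, d, res = 0.05,
                                   coarse_deg = 0.5, fine_deg = 0.01) {
  m <- cs$contour
  hull <- m[rev(grDevices::chull(m)), , drop = FALSE]  # ccw hull
  apexes <- list(a7 = cs$landmarks$anterior_apex,
                 a8 = cs$landmarks$posterior_apex,
                 a9 = cs$landmarks$lateral_apex)
  feasible <- function(th) {
    raster_strip_feasible(hull, anchor, th, d, res) &&
      oracle_exit_lateral(m, apexes, anchor, th)
  }
  ctr <- colMeans(m)
  base <- atan2(ctr[2] - anchor[2], ctr[1] - anchor[1])
  ang <- atan2(m[, 2] - anchor[2], m[, 1] - anchor[1])
  rel <- (ang - base + pi) %% (2 * pi) - pi
  lo <- base + min(rel); hi <- base + max(rel)
  coarse <- seq(lo, hi, by = coarse_deg * pi / 180)
  feas <- vapply(coarse, feasible, logical(1))
  stopifnot(any(feas))
  i1 <- which(feas)[1]; i2 <- which(feas)[sum(feas)]
  fine_scan <- function(center) {
    fs <- seq(center - 1.2 * coarse_deg * pi / 180,
              center + 1.2 * coarse_deg * pi / 180, by = fine_deg * pi / 180)
    ok <- vapply(fs, feasible, logical(1))
    fs[ok]
  }
  lo_fine <- fine_scan(coarse[i1])
  hi_fine <- fine_scan(coarse[i2])
  c(min(lo_fine), max(hi_fine))
}

# Independent least-squares similarity fit.  A rotation-plus-scale map is
# linear in (p, q, tx, ty) with x' = p x - q y + tx, y' = q x + p y + ty
# (reflection excluded by construction), so the exact least-squares
# solution comes from a QR solve of the stacked linear system -- a
# different derivation and solver from the package's complex closed form.
oracle_procrustes <- function(src, ref) {
  n <- nrow(src)
  X <- rbind(cbind(src[, 1], -src[, 2], 1, 0),
             cbind(src[, 2],  src[, 1], 0, 1))
  yv <- c(ref[, 1], ref[, 2])
  beta <- qr.solve(X, yv)
  fitv <- X %*% beta
  fit <- cbind(fitv[1:n], fitv[(n + 1):(2 * n)])
  list(value = sum((fit - ref)^2),
       mean_distance_error = mean(sqrt(rowSums((fit - ref)^2))),
       rotation = atan2(beta[2], beta[1]),
       scale = sqrt(beta[1]^2 + beta[2]^2))
}

expect_rel_equal <- function(a, b, tol) {
  testthat::expect_lt(max(abs(a - b) / pmax(abs(b), 1e-12)), tol)
}
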
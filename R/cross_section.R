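#' Build a fibular cross-section object
#'
#' A cross-section bundles one subject's axial slice in physical units (mm):
#' the closed fibular contour, the named landmarks used throughout the
#' analysis, an optional tibial contour, and slice-height scalars.  Analysis
#' is carried out in a canonical right-side frame with +x pointing anterior
#' and +y pointing lateral; left-sided raw data are mirrored about the
#' y axis at ingest (see [read_cohort()]).
#'
#' Landmarks follow the standard annotation scheme: the anteromedial and
#' posteromedial tibial anchor points (just medial to the anterior tibial
#' tendon and just anterior to the posterior tibial tendon groove), and the
#' anterior, posterior and lateral cortical apexes of the fibula.  The
#' tibial and fibular centres (anchor midpoint and apex-chord midpoint) are
#' derived automatically.
#'
#' @param fibula_contour numeric matrix (n x 2) of contour vertices in mm;
#'   orientation is normalised to counter-clockwise.
#' @param landmarks named list with numeric `c(x, y)` entries
#'   `anterior_anchor`, `posterior_anchor`, `anterior_apex`,
#'   `posterior_apex`, `lateral_apex`.
#' @param subject_id subject identifier.
#' @param side `"left"` or `"right"` (label only; coordinates are assumed
#'   canonical, use [mirror_cross_section()] for raw left-side data).
#' @param tibia_contour optional tibial contour matrix (n x 2).
#' @param shape_class optional known shape class.
#' @param height_from_plafond,height_from_fibular_tip slice heights in mm.
#' @param snap_tol tolerance (mm) for snapping apex landmarks onto the
#'   contour; apexes farther away raise a landmark-mismatch error.
#' @return an object of class `cross_section`.
#' @export
cross_section <- function(fibula_contour, landmarks,
                          subject_id = "s1", side = c("right", "left"),
                          tibia_contour = NULL, shape_class = NULL,
                          height_from_plafond = NA_real_,
                          height_from_fibular_tip = NA_real_,
                          snap_tol = 0.1) {
  side <- match.arg(side)
  m <- poly_ensure_ccw(as_contour(fibula_contour))
  if (!poly_is_simple(m)) {
    stop("fibula contour is self-intersecting", call. = FALSE)
  }
  if (poly_perimeter(m) <= 0) stop("contour perimeter must be positive", call. = FALSE)

  need <- c("anterior_anchor", "posterior_anchor",
            "anterior_apex", "posterior_apex", "lateral_apex")
  if (!all(need %in% names(landmarks))) {
    stop("landmarks must contain: ", paste(need, collapse = ", "), call. = FALSE)
  }
  lm <- lapply(landmarks[need], function(p) {
    p <- as.numeric(p)
    if (length(p) != 2 || !all(is.finite(p))) {
      stop("each landmark must be a finite (x, y) pair", call. = FALSE)
    }
    c(x = p[1], y = p[2])
  })

  # snap apexes onto the contour within tolerance
  snaps <- lapply(lm[c("anterior_apex", "posterior_apex", "lateral_apex")],
                  function(p) poly_snap(m, p))
  offs <- vapply(snaps, `[[`, numeric(1), "dist")
  if (any(offs > snap_tol)) {
    bad <- names(offs)[offs > snap_tol]
    stop("landmark-mismatch: apex landmark(s) not on the contour (> ",
         snap_tol, " mm): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  lm$anterior_apex  <- snaps$anterior_apex$point
  lm$posterior_apex <- snaps$posterior_apex$point
  lm$lateral_apex   <- snaps$lateral_apex$point
  s_ap <- vapply(snaps, `[[`, numeric(1), "s")

  if (anyDuplicated(round(do.call(rbind, lm[c("anterior_apex", "posterior_apex",
                                              "lateral_apex")]), 9))) {
    stop("apex landmarks must be pairwise distinct", call. = FALSE)
  }

  # anchors must lie outside the fibula, on the far (medial) side of the
  # apex chord 7-8 relative to the lateral apex
  for (nm in c("anterior_anchor", "posterior_anchor")) {
    if (point_in_poly(m, lm[[nm]])) {
      stop("anchor landmark '", nm, "' lies inside the fibular contour",
           call. = FALSE)
    }
  }
  side_ref <- signed_line_dist(lm$anterior_apex, lm$posterior_apex,
                               lm$lateral_apex[1], lm$lateral_apex[2])
  for (nm in c("anterior_anchor", "posterior_anchor")) {
    d <- signed_line_dist(lm$anterior_apex, lm$posterior_apex,
                          lm[[nm]][1], lm[[nm]][2])
    if (d * side_ref > 0) {
      stop("anchor landmark '", nm, "' is not medial to the fibula",
           call. = FALSE)
    }
  }

  lm$tibial_center  <- (lm$anterior_anchor + lm$posterior_anchor) / 2
  lm$fibular_center <- (lm$anterior_apex + lm$posterior_apex) / 2

  if (!is.na(height_from_plafond) && height_from_plafond <= 0) {
    stop("height_from_plafond must be positive", call. = FALSE)
  }
  if (!is.na(height_from_fibular_tip) && height_from_fibular_tip <= 0) {
    stop("height_from_fibular_tip must be positive", call. = FALSE)
  }

  cs <- structure(
    list(
      subject_id = as.character(subject_id),
      side = side,
      contour = m,
      tibia_contour = if (!is.null(tibia_contour)) as_contour(tibia_contour),
      landmarks = lm,
      s_apex = c(anterior = unname(s_ap["anterior_apex"]),
                 posterior = unname(s_ap["posterior_apex"]),
                 lateral = unname(s_ap["lateral_apex"])),
      shape_class = shape_class,
      height_from_plafond = height_from_plafond,
      height_from_fibular_tip = height_from_fibular_tip,
      snap_tol = snap_tol
    ),
    class = "cross_section"
  )
  cs$paths <- lateral_paths_impl(cs)
  cs
}

#' @export
print.cross_section <- function(x, ...) {
  cat("<cross_section> subject", x$subject_id, "(", x$side, ")\n")
  cat("  contour:", nrow(x$contour), "vertices, perimeter",
      sprintf("%.1f", poly_perimeter(x$contour)), "mm\n")
  cat("  anterolateral", sprintf("%.2f", x$paths$anterior_length), "mm,",
      "posterolateral", sprintf("%.2f", x$paths$posterior_length), "mm\n")
  invisible(x)
}

# Internal: the two lateral cortex sub-paths, each starting at the lateral
# apex (9) and ending at the anterior (7) or posterior (8) apex, following
# the contour on the side that avoids the opposite apex.
lateral_paths_impl <- function(cs) {
  m <- cs$contour
  per <- poly_perimeter(m)
  s9 <- cs$s_apex["lateral"]; s7 <- cs$s_apex["anterior"]; s8 <- cs$s_apex["posterior"]

  path_between <- function(s_from, s_to, s_avoid) {
    fwd_span <- arc_forward(s_from, s_to, per)
    fwd_has_avoid <- arc_forward(s_from, s_avoid, per) < fwd_span
    if (!fwd_has_avoid) {
      list(pts = poly_subpath(m, s_from, s_to), forward = TRUE,
           span = fwd_span)
    } else {
      # travel the other way round: take the ccw path s_to -> s_from, reversed
      pts <- poly_subpath(m, s_to, s_from)
      list(pts = pts[rev(seq_len(nrow(pts))), , drop = FALSE],
           forward = FALSE, span = arc_forward(s_to, s_from, per))
    }
  }
  ant <- path_between(s9, s7, s8)
  post <- path_between(s9, s8, s7)
  list(
    anterior = ant$pts, posterior = post$pts,
    anterior_length = polyline_length(ant$pts),
    posterior_length = polyline_length(post$pts),
    anterior_forward = ant$forward, posterior_forward = post$forward,
    anterior_span = ant$span, posterior_span = post$span,
    s9 = unname(s9), perimeter = per
  )
}

#' Anterior and posterior lateral cortex paths
#'
#' Splits the fibular contour at the lateral apex into the anterolateral
#' path (lateral apex to anterior apex) and the posterolateral path
#' (lateral apex to posterior apex).  Both are returned as ordered
#' polylines starting at the lateral apex, together with their arc lengths.
#'
#' @param cs a [cross_section()].
#' @return list with elements `anterior`, `posterior` (polyline matrices)
#'   and `anterior_length`, `posterior_length` (mm).
#' @export
lateral_cortex_paths <- function(cs) {
  stopifnot(inherits(cs, "cross_section"))
  cs$paths
}

#' Signed normalized location of a point on the lateral cortex
#'
#' Positions on the lateral fibular cortex are expressed as a signed
#' percentage of the arc length of the respective cortical edge: the
#' lateral apex maps to 0, the anterior apex to +100 and the posterior
#' apex to -100, with anterior-cortex locations positive and
#' posterior-cortex locations negative.
#'
#' @param cs a [cross_section()].
#' @param p numeric `c(x, y)` point expected to lie on (or within `tol` of)
#'   one of the two lateral cortex paths.
#' @param tol maximal distance (mm) from the cortex before a
#'   location-off-cortex error is raised.
#' @return one-row tibble with `value` (signed percent), `cortex`
#'   (`"anterior"`, `"posterior"` or `"apex"`) and the snapped exit point
#'   `x`, `y`.
#' @export
signed_location <- function(cs, p, tol = 0.1) {
  stopifnot(inherits(cs, "cross_section"))
  p <- as.numeric(p)
  sa <- polyline_snap(cs$paths$anterior, p)
  sp <- polyline_snap(cs$paths$posterior, p)
  if (min(sa$dist, sp$dist) > tol) {
    stop("location-off-cortex: point is ", sprintf("%.3g", min(sa$dist, sp$dist)),
         " mm from the lateral cortex (tol = ", tol, " mm)", call. = FALSE)
  }
  if (sa$dist <= sp$dist) {
    value <- unname(100 * sa$s / cs$paths$anterior_length)
    pt <- sa$point
  } else {
    value <- unname(-100 * sp$s / cs$paths$posterior_length)
    pt <- sp$point
  }
  cortex <- if (value > 0) "anterior" else if (value < 0) "posterior" else "apex"
  tibble::tibble(value = value, cortex = cortex, x = unname(pt[1]), y = unname(pt[2]))
}

#' Construct a tunnel axis
#'
#' An oriented drilling axis: the line through a fixed (medial) anchor
#' point with a unit direction, modelling the longitudinal axis of the
#' guide K-wire.
#'
#' @param through numeric `c(x, y)` anchor point in mm.
#' @param direction numeric `c(x, y)` direction (normalised internally).
#' @return object of class `tunnel_axis`.
#' @export
tunnel_axis <- function(through, direction) {
  through <- as.numeric(through)
  stopifnot(length(through) == 2, all(is.finite(through)))
  structure(list(through = c(x = through[1], y = through[2]),
                 direction = unit_vec(as.numeric(direction))),
            class = "tunnel_axis")
}

#' Axis through two points
#' @param p,q points `c(x, y)`; the axis passes through `p` towards `q`.
#' @return a [tunnel_axis()].
#' @export
axis_through <- function(p, q) tunnel_axis(p, as.numeric(q) - as.numeric(p))

# Internal: rich exit record (point, axis parameter, arc position, cortex).
axis_lateral_exit <- function(cs, axis, eps = 1e-9) {
  m <- cs$contour
  cr <- line_poly_crossings(m, axis$through, axis$direction, eps)
  if (cr$n == 0) stop("no-lateral-exit: axis misses the fibula", call. = FALSE)
  pa <- cs$paths
  tol_s <- 1e-9 * (1 + pa$perimeter)
  on_one <- function(forward, span) {
    d <- if (forward) arc_forward(pa$s9, cr$s_arc, pa$perimeter) else
      arc_forward(cr$s_arc, pa$s9, pa$perimeter)
    d <= span + tol_s
  }
  on_path <- on_one(pa$anterior_forward, pa$anterior_span) |
    on_one(pa$posterior_forward, pa$posterior_span)
  if (!any(on_path)) {
    stop("no-lateral-exit: axis exits only through the medial cortex", call. = FALSE)
  }
  idx <- which(on_path)
  i <- idx[which.max(abs(cr$t[idx]))]
  list(point = c(x = cr$x[i], y = cr$y[i]), t = cr$t[i], s_arc = cr$s_arc[i])
}

#' Intersection of a tunnel axis with the lateral cortex
#'
#' Intersects the axis line with the two lateral cortex paths and returns
#' the crossing farthest from the anchor (the drill exits the far cortex
#' when the lateral cortex is crossed more than once).
#'
#' @param cs a [cross_section()].
#' @param axis a [tunnel_axis()].
#' @param eps geometric tolerance in mm.
#' @return one-row tibble `x`, `y` of the exit point.
#' @export
intersect_axis_with_lateral_cortex <- function(cs, axis, eps = 1e-9) {
  ex <- axis_lateral_exit(cs, axis, eps)
  tibble::tibble(x = unname(ex$point[1]), y = unname(ex$point[2]))
}

#' Finite-diameter strip feasibility
#'
#' Models the drill hole of diameter `d` as the strip (slab) of width `d`
#' centred on the axis.  The configuration is feasible when both boundary
#' lines of the strip still intersect the closed fibular contour (the hole
#' does not break out through the anterior or posterior cortex) and the
#' axis itself exits through the lateral cortex.
#'
#' @param cs a [cross_section()].
#' @param axis a [tunnel_axis()].
#' @param d tunnel diameter in mm (>= 0).
#' @param eps geometric tolerance in mm; a strip edge passing within `eps`
#'   of a contour vertex counts as tangent.
#' @return `TRUE`/`FALSE`; degenerate inputs return `FALSE`.
#' @export
strip_within_fibula <- function(cs, axis, d, eps = 1e-9) {
  stopifnot(inherits(cs, "cross_section"), inherits(axis, "tunnel_axis"))
  if (!is.finite(d) || d < 0) return(FALSE)
  u <- axis$direction
  nv <- perp_vec(u)
  p0 <- axis$through
  half <- d / 2
  ok <- line_hits_poly(cs$contour, p0 + nv * half, u, eps) &&
    line_hits_poly(cs$contour, p0 - nv * half, u, eps)
  if (!ok) return(FALSE)
  !inherits(try(axis_lateral_exit(cs, axis, eps), silent = TRUE), "try-error")
}

#' Mirror a cross-section about the y axis
#'
#' Converts raw left-sided coordinates into the canonical right-side frame
#' (or back).  All contours and landmarks are mirrored (x -> -x) and the
#' contour orientation re-normalised to counter-clockwise.
#'
#' @param cs a [cross_section()].
#' @return the mirrored `cross_section`.
#' @export
mirror_cross_section <- function(cs) {
  flip <- function(p) { p[1] <- -p[1]; p }
  flipm <- function(m) { m[, 1] <- -m[, 1]; m }
  lm <- lapply(cs$landmarks[c("anterior_anchor", "posterior_anchor",
                              "anterior_apex", "posterior_apex",
                              "lateral_apex")], flip)
  cross_section(
    fibula_contour = flipm(cs$contour),
    landmarks = lm,
    subject_id = cs$subject_id,
    side = cs$side,
    tibia_contour = if (!is.null(cs$tibia_contour)) flipm(cs$tibia_contour),
    shape_class = cs$shape_class,
    height_from_plafond = cs$height_from_plafond,
    height_from_fibular_tip = cs$height_from_fibular_tip,
    snap_tol = cs$snap_tol
  )
}
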
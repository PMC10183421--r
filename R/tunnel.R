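# Finite-diameter drill-tunnel simulation: extreme feasible borders about a
# fixed medial anchor, the ideal (bisector) axis, and the center-center axis.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

dir_at <- function(theta) c(cos(theta), sin(theta))

# Angular window, about `anchor`, inside which an axis can meet the
# contour: the angular hull of the vertices, unwrapped around the
# anchor-to-centroid direction.
anchor_angle_range <- function(cs, anchor) {
  ctr <- poly_centroid(cs$contour)
  base <- unname(atan2(ctr[2] - anchor[2], ctr[1] - anchor[1]))
  ang <- atan2(cs$contour[, 2] - anchor[2], cs$contour[, 1] - anchor[1])
  rel <- (ang - base + pi) %% (2 * pi) - pi
  c(base + min(rel), base + max(rel), base)
}

feasible_at <- function(cs, anchor, theta, d, eps) {
  strip_within_fibula(cs, tunnel_axis(anchor, dir_at(theta)), d, eps)
}

exit_at <- function(cs, anchor, theta, eps, snap_vertex = NULL) {
  ex <- axis_lateral_exit(cs, tunnel_axis(anchor, dir_at(theta)), eps)
  p <- ex$point
  if (!is.null(snap_vertex)) {
    if (vec_norm(p - snap_vertex) <= 1e-9 * (1 + max(abs(cs$contour)))) {
      p <- c(x = snap_vertex[1], y = snap_vertex[2])
    }
  }
  p
}

# Analytic extreme angles for convex contours: at an extreme rotation one
# strip boundary line is tangent to the contour at a vertex, so candidate
# angles are atan2(v - anchor) +/- asin(d / (2 |v - anchor|)) over all
# vertices; the feasible extremes are the outermost feasible candidates.
extremes_analytic <- function(cs, anchor, d, eps) {
  # candidate pivots: the contour vertices (strip-edge tangency) plus the
  # apex landmarks, which bound the lateral-exit condition -- they sit in
  # the interior of an edge whenever annotations were projected onto the
  # contour, so they are not necessarily vertices
  m <- rbind(cs$contour,
             cs$landmarks$anterior_apex, cs$landmarks$posterior_apex,
             cs$landmarks$lateral_apex)
  rng <- anchor_angle_range(cs, anchor)
  base <- rng[3]
  cand_theta <- numeric(0)
  cand_vertex <- list()
  for (i in seq_len(nrow(m))) {
    w <- m[i, ] - anchor
    wn <- vec_norm(w)
    if (d / 2 > wn) next
    phi <- atan2(w[2], w[1])
    delta <- asin(d / (2 * wn))
    # phi +/- delta: strip-edge tangency at the vertex; phi itself: the
    # axis through the vertex (where the lateral exit hands over at an
    # apex, the binding constraint switches from tangency to exit side)
    ths <- if (d == 0) phi else c(phi - delta, phi, phi + delta)
    for (th in ths) {
      cand_theta <- c(cand_theta, th)
      cand_vertex <- c(cand_vertex, list(m[i, ]))
    }
  }
  rel <- (cand_theta - base + pi) %% (2 * pi) - pi
  feas <- vapply(cand_theta, function(th) feasible_at(cs, anchor, th, d, eps),
                 logical(1))
  if (!any(feas)) return(NULL)
  ilo <- which(feas)[which.min(rel[feas])]
  ihi <- which(feas)[which.max(rel[feas])]
  list(theta = c(base + rel[ilo], base + rel[ihi]),
       vertex = list(cand_vertex[[ilo]], cand_vertex[[ihi]]))
}

# Sweep solver (authoritative for non-convex contours): coarse angular
# grid over the anchor's angular window, then bisection refinement of the
# outermost feasibility boundaries.
extremes_sweep <- function(cs, anchor, d, eps, step_deg = 0.2,
                           refine_tol_deg = 1e-4) {
  rng <- anchor_angle_range(cs, anchor)
  thetas <- seq(rng[1], rng[2], by = deg2rad(step_deg))
  if (length(thetas) < 2) thetas <- seq(rng[1], rng[2], length.out = 5)
  feas <- vapply(thetas, function(th) feasible_at(cs, anchor, th, d, eps),
                 logical(1))
  if (!any(feas)) {
    thetas <- seq(rng[1], rng[2], by = deg2rad(step_deg / 8))
    feas <- vapply(thetas, function(th) feasible_at(cs, anchor, th, d, eps),
                   logical(1))
    if (!any(feas)) return(NULL)
  }
  tol <- deg2rad(refine_tol_deg)
  refine <- function(th_feas, th_infeas) {
    while (abs(th_infeas - th_feas) > tol) {
      mid <- (th_feas + th_infeas) / 2
      if (feasible_at(cs, anchor, mid, d, eps)) th_feas <- mid else th_infeas <- mid
    }
    th_feas
  }
  ilo <- which(feas)[1]
  ihi <- which(feas)[sum(feas)]
  th_lo <- if (ilo == 1) thetas[1] else refine(thetas[ilo], thetas[ilo - 1])
  th_hi <- if (ihi == length(thetas)) thetas[length(thetas)] else
    refine(thetas[ihi], thetas[ihi + 1])
  list(theta = c(th_lo, th_hi), vertex = list(NULL, NULL))
}

#' Extreme feasible drill tunnels about a fixed anchor
#'
#' Rotates the tunnel axis about the fixed medial anchor (the single
#' degree of freedom) and finds the most anteriorly and posteriorly
#' rotated axes for which the finite-diameter strip still lies within the
#' bone ([strip_within_fibula()]).  For convex contours the extremes are
#' solved analytically (at the extreme the strip edge is tangent to the
#' contour at a vertex); non-convex contours fall back to an angular sweep
#' with bisection refinement.
#'
#' @param cs a [cross_section()].
#' @param anchor the anchor point `c(x, y)`, or one of `"anterior"` /
#'   `"posterior"` to use the stored anchor landmarks.
#' @param d tunnel diameter (mm).
#' @param eps geometric tolerance (mm).
#' @param method `"auto"` (analytic when convex), `"analytic"` or `"sweep"`.
#' @param step_deg,refine_tol_deg sweep grid step and bisection tolerance
#'   in degrees.
#' @return tibble with rows `border = c("anterior", "posterior")`
#'   (anterior = the border with the larger signed exit location), the
#'   signed exit `value` (percent), `cortex`, exit `x`, `y` and the axis
#'   `angle_deg` measured from the +x (anterior) axis.
#' @export
extreme_tunnels <- function(cs, anchor = "anterior", d = 3.5, eps = 1e-9,
                            method = c("auto", "analytic", "sweep"),
                            step_deg = 0.2, refine_tol_deg = 1e-4) {
  method <- match.arg(method)
  anchor <- resolve_anchor(cs, anchor)
  use_analytic <- switch(method,
    auto = poly_is_convex(cs$contour),
    analytic = TRUE,
    sweep = FALSE
  )
  sol <- if (use_analytic) extremes_analytic(cs, anchor, d, eps) else NULL
  if (is.null(sol)) sol <- extremes_sweep(cs, anchor, d, eps, step_deg, refine_tol_deg)
  if (is.null(sol)) {
    stop("infeasible-tunnel: no axis of diameter ", d,
         " mm fits within the fibula from this anchor", call. = FALSE)
  }
  locs <- lapply(1:2, function(i) {
    p <- exit_at(cs, anchor, sol$theta[i], eps, snap_vertex = sol$vertex[[i]])
    loc <- signed_location(cs, p, tol = 0.5)
    loc$angle_deg <- rad2deg(sol$theta[i])
    loc
  })
  res <- dplyr::bind_rows(locs)
  o <- order(-res$value)
  res <- res[o, ]
  res$border <- c("anterior", "posterior")
  dplyr::relocate(res, "border")
}

resolve_anchor <- function(cs, anchor) {
  if (is.character(anchor)) {
    anchor <- match.arg(anchor, c("anterior", "posterior"))
    anchor <- if (anchor == "anterior") cs$landmarks$anterior_anchor else
      cs$landmarks$posterior_anchor
  }
  as.numeric(anchor)
}

#' Ideal (central) drill tunnel through the fibular-width bisector
#'
#' The ideal axis for an angulated tunnel runs from the anchor through
#' point M, the bisector of the fibular width.  By default M is the
#' midpoint of the anterior-posterior apex chord; `m_definition =
#' "chord_midpoint"` instead takes the midpoint of the bone chord cut by
#' the axis (computed with one fixed-point refinement step).
#'
#' @inheritParams extreme_tunnels
#' @param m_definition `"apex_midpoint"` (default) or `"chord_midpoint"`.
#' @return one-row tibble: signed exit `value`, `cortex`, `x`, `y`,
#'   `angle_deg`, and `feasible` (whether the finite-diameter strip along
#'   the ideal axis stays within the bone; an infeasible central axis is
#'   flagged, not an error).
#' @export
ideal_tunnel <- function(cs, anchor = "anterior", d = 3.5, eps = 1e-9,
                         m_definition = c("apex_midpoint", "chord_midpoint")) {
  m_definition <- match.arg(m_definition)
  anchor <- resolve_anchor(cs, anchor)
  M <- cs$landmarks$fibular_center
  if (m_definition == "chord_midpoint") {
    ax0 <- axis_through(anchor, M)
    cr <- line_poly_crossings(cs$contour, ax0$through, ax0$direction, eps)
    if (cr$n >= 2) {
      M <- c(mean(range(cr$x)), mean(range(cr$y)))
    }
  }
  ax <- axis_through(anchor, M)
  p <- axis_lateral_exit(cs, ax, eps)$point
  loc <- signed_location(cs, p, tol = 0.5)
  loc$angle_deg <- rad2deg(atan2(ax$direction[2], ax$direction[1]))
  loc$feasible <- strip_within_fibula(cs, ax, d, eps)
  loc
}

#' Center-center drill axis
#'
#' The center-center orientation runs through the bisector of the tibial
#' landing zone (midpoint of the two anchors) and the bisector of the
#' fibular width (midpoint of the anterior and posterior apexes); its exit
#' through the lateral cortex is returned as a signed location.
#'
#' @inheritParams extreme_tunnels
#' @return one-row tibble: `value`, `cortex`, `x`, `y`, `angle_deg`,
#'   `feasible`.
#' @export
center_center_axis <- function(cs, d = 3.5, eps = 1e-9) {
  stopifnot(inherits(cs, "cross_section"))
  ax <- axis_through(cs$landmarks$tibial_center, cs$landmarks$fibular_center)
  p <- axis_lateral_exit(cs, ax, eps)$point
  loc <- signed_location(cs, p, tol = 0.5)
  loc$angle_deg <- rad2deg(atan2(ax$direction[2], ax$direction[1]))
  loc$feasible <- strip_within_fibula(cs, ax, d, eps)
  loc
}

#' Solve the three tunnel orientations for one subject
#'
#' Runs the anteriorly angulated (anteromedial anchor), posteriorly
#' angulated (posteromedial anchor) and center-center orientations.  For
#' the two angulated orientations the extreme anterior/posterior borders
#' and the ideal central axis are reported; the center-center orientation
#' is a single axis, so its borders are undefined.  Infeasibility in one
#' orientation is recorded (`feasible = FALSE`, `NA` locations) without
#' aborting the others.
#'
#' @param cs a [cross_section()].
#' @param d tunnel diameter (mm); defaults to 3.5.
#' @param eps geometric tolerance (mm).
#' @param ... passed to [extreme_tunnels()].
#' @return tibble with one row per orientation: `subject_id`,
#'   `orientation`, `border_anterior_pct`, `border_posterior_pct`,
#'   `central_pct`, `angle_anterior_deg`, `angle_posterior_deg`,
#'   `angle_central_deg`, `feasible`, `central_feasible`.
#' @export
solve_subject <- function(cs, d = 3.5, eps = 1e-9, ...) {
  stopifnot(inherits(cs, "cross_section"))
  one <- function(orientation) {
    if (orientation == "center_center") {
      row <- tryCatch({
        cc <- center_center_axis(cs, d = d, eps = eps)
        tibble::tibble(border_anterior_pct = NA_real_,
                       border_posterior_pct = NA_real_,
                       central_pct = cc$value,
                       angle_anterior_deg = NA_real_,
                       angle_posterior_deg = NA_real_,
                       angle_central_deg = cc$angle_deg,
                       feasible = cc$feasible,
                       central_feasible = cc$feasible)
      }, error = function(e) empty_solution())
    } else {
      who <- if (orientation == "anterior_angulated") "anterior" else "posterior"
      row <- tryCatch({
        ext <- extreme_tunnels(cs, anchor = who, d = d, eps = eps, ...)
        ctr <- ideal_tunnel(cs, anchor = who, d = d, eps = eps)
        tibble::tibble(border_anterior_pct = ext$value[ext$border == "anterior"],
                       border_posterior_pct = ext$value[ext$border == "posterior"],
                       central_pct = ctr$value,
                       angle_anterior_deg = ext$angle_deg[ext$border == "anterior"],
                       angle_posterior_deg = ext$angle_deg[ext$border == "posterior"],
                       angle_central_deg = ctr$angle_deg,
                       feasible = TRUE,
                       central_feasible = ctr$feasible)
      }, error = function(e) empty_solution())
    }
    dplyr::mutate(row, subject_id = cs$subject_id, orientation = orientation,
                  .before = 1)
  }
  dplyr::bind_rows(lapply(c("anterior_angulated", "posterior_angulated",
                            "center_center"), one))
}

empty_solution <- function() {
  tibble::tibble(border_anterior_pct = NA_real_, border_posterior_pct = NA_real_,
                 central_pct = NA_real_, angle_anterior_deg = NA_real_,
                 angle_posterior_deg = NA_real_, angle_central_deg = NA_real_,
                 feasible = FALSE, central_feasible = FALSE)
}

#' Tunnel solutions for a whole cohort
#'
#' @param cohort cohort tibble with a `section` list-column (and
#'   optionally a `tunnel_diameter_mm` column used when `d` is `NULL`).
#' @param d tunnel diameter (mm); `NULL` uses the per-subject cohort
#'   column, falling back to 3.5.
#' @param ... passed to [solve_subject()].
#' @return tibble of per-subject, per-orientation solutions.
#' @export
simulate_tunnels <- function(cohort, d = NULL, ...) {
  stopifnot(is.data.frame(cohort), "section" %in% names(cohort))
  ds <- if (!is.null(d)) {
    rep_len(d, nrow(cohort))
  } else if ("tunnel_diameter_mm" %in% names(cohort)) {
    cohort$tunnel_diameter_mm
  } else {
    rep(3.5, nrow(cohort))
  }
  purrr::map2_dfr(cohort$section, ds, function(cs, di) solve_subject(cs, d = di, ...))
}
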
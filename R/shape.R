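# Shape classification of the axial cross-section and the lateral-surface
# aspect ratio.

# Dominant corners of a closed contour: the turning angle at every vertex
# is integrated over a sliding arc window; contiguous runs of vertices
# whose window-integrated turn exceeds the threshold are merged into one
# corner, located at the turning-weighted vertex.
find_corners <- function(m, angle_deg = 35, window_mm = 2) {
  m <- poly_ensure_ccw(m)
  n <- nrow(m)
  prev <- m[c(n, seq_len(n - 1)), , drop = FALSE]
  nxt <- poly_next(m)
  e_in <- m - prev
  e_out <- nxt - m
  turn <- atan2(e_in[, 1] * e_out[, 2] - e_in[, 2] * e_out[, 1],
                e_in[, 1] * e_out[, 1] + e_in[, 2] * e_out[, 2])
  s <- poly_vertex_s(m)
  per <- poly_perimeter(m)
  half <- window_mm / 2
  wturn <- vapply(seq_len(n), function(i) {
    d <- pmin(abs(s - s[i]), per - abs(s - s[i]))
    sum(turn[d <= half])
  }, numeric(1))
  hot <- which(abs(wturn) * 180 / pi > angle_deg)
  if (length(hot) == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0),
                          s = numeric(0), turn_deg = numeric(0)))
  }
  # cluster hot vertices closer than the window along the arc (wrap-aware)
  hs <- s[hot]
  o <- order(hs)
  hot <- hot[o]; hs <- hs[o]
  gaps <- diff(hs)
  brk <- c(0, which(gaps > window_mm), length(hot))
  groups <- mapply(function(a, b) hot[(a + 1):b], brk[-length(brk)], brk[-1],
                   SIMPLIFY = FALSE)
  # merge first and last group across the wrap
  if (length(groups) > 1) {
    wrap_gap <- (hs[1] + per) - hs[length(hs)]
    if (wrap_gap <= window_mm) {
      groups[[1]] <- c(groups[[length(groups)]], groups[[1]])
      groups[[length(groups)]] <- NULL
    }
  }
  rows <- lapply(groups, function(g) {
    wt <- abs(turn[g])
    if (sum(wt) == 0) wt <- rep(1, length(g))
    i_star <- g[which.max(wt)]
    tibble::tibble(x = m[i_star, 1], y = m[i_star, 2], s = s[i_star],
                   turn_deg = sum(turn[g]) * 180 / pi)
  })
  out <- dplyr::bind_rows(rows)
  # a cluster must itself carry a dominant total turn
  out[abs(out$turn_deg) > angle_deg, , drop = FALSE]
}

#' Detect candidate cortical apexes on an unlandmarked contour
#'
#' For contours in the canonical right-side frame (+x anterior, +y
#' lateral): the lateral apex is the contour point with maximal lateral
#' coordinate; the anterior and posterior apexes are the dominant-corner
#' points with maximal and minimal anterior coordinate.  Ties are broken
#' by the larger turning angle.
#'
#' @param contour n x 2 contour matrix (mm), or a [cross_section()].
#' @param angle_deg corner threshold: window-integrated turning angle in
#'   degrees above which a vertex cluster counts as a corner.
#' @param window_mm arc-length integration window (mm).
#' @return list with `anterior_apex`, `posterior_apex`, `lateral_apex`
#'   points.
#' @export
detect_apexes <- function(contour, angle_deg = 35, window_mm = 2) {
  m <- if (inherits(contour, "cross_section")) contour$contour else as_contour(contour)
  m <- poly_ensure_ccw(m)
  corners <- find_corners(m, angle_deg, window_mm)
  if (nrow(corners) < 3) {
    stop("detection-failure: fewer than 3 dominant corners; supply landmarks",
         call. = FALSE)
  }
  lat <- m[which.max(m[, 2]), ]
  corners <- corners[order(-abs(corners$turn_deg)), ]
  ant <- corners[which.max(corners$x), ]
  post <- corners[which.min(corners$x), ]
  list(
    anterior_apex = c(x = ant$x, y = ant$y),
    posterior_apex = c(x = post$x, y = post$y),
    lateral_apex = c(x = unname(lat[1]), y = unname(lat[2]))
  )
}

#' Classify the cross-sectional shape
#'
#' Rule-based operationalization of the visual shape taxonomy: count the
#' dominant corners (turning angle above `angle_deg` integrated over a
#' `window_mm` arc window).  Three corners with an (outward) medially
#' convex apex-chord edge give `triangular_convex`; three corners with a
#' straight medial edge (maximal perpendicular deviation below
#' `straight_tol` of the chord) give `triangular`; four corners give
#' `quadrilateral`; everything else is `irregular`.
#'
#' @param cs a [cross_section()].
#' @param angle_deg,window_mm corner rule, see [detect_apexes()].
#' @param straight_tol medial-edge straightness threshold as a fraction of
#'   the 7-8 chord.
#' @return one of `"triangular_convex"`, `"triangular"`, `"quadrilateral"`,
#'   `"irregular"`.
#' @export
classify_shape <- function(cs, angle_deg = 35, window_mm = 2,
                           straight_tol = 0.04) {
  stopifnot(inherits(cs, "cross_section"))
  corners <- find_corners(cs$contour, angle_deg, window_mm)
  ncor <- nrow(corners)
  if (ncor == 4) return("quadrilateral")
  if (ncor != 3) return("irregular")

  # medial path 7 -> 8 (the side avoiding the lateral apex)
  m <- cs$contour
  per <- poly_perimeter(m)
  s7 <- cs$s_apex["anterior"]; s8 <- cs$s_apex["posterior"]; s9 <- cs$s_apex["lateral"]
  med <- if (arc_forward(s7, s9, per) < arc_forward(s7, s8, per)) {
    pts <- poly_subpath(m, s8, s7)
    pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  } else {
    poly_subpath(m, s7, s8)
  }
  a <- cs$landmarks$anterior_apex
  b <- cs$landmarks$posterior_apex
  chord <- vec_norm(b - a)
  if (nrow(med) <= 2 || chord == 0) return("triangular")
  interior <- med[-c(1, nrow(med)), , drop = FALSE]
  dev <- signed_line_dist(a, b, interior[, 1], interior[, 2])
  lat_side <- sign(signed_line_dist(a, b, cs$landmarks$lateral_apex[1],
                                    cs$landmarks$lateral_apex[2]))
  dev_out <- -lat_side * dev            # positive = away from the lateral apex
  if (max(abs(dev_out)) < straight_tol * chord) return("triangular")

  # convex hypotenuse: all interior points bulge medially and the medial
  # path turns consistently in one direction
  if (min(dev_out) > -0.02 * chord && max(dev_out) >= straight_tol * chord) {
    d <- diff(med)
    if (nrow(d) >= 2) {
      t1 <- d[-nrow(d), , drop = FALSE]
      t2 <- d[-1, , drop = FALSE]
      tu <- atan2(t1[, 1] * t2[, 2] - t1[, 2] * t2[, 1],
                  rowSums(t1 * t2))
      consistency <- if (sum(abs(tu)) == 0) 1 else abs(sum(tu)) / sum(abs(tu))
      if (consistency >= 0.9) return("triangular_convex")
    } else {
      return("triangular_convex")
    }
  }
  "irregular"
}

#' Lateral-surface aspect ratio of one cross-section
#'
#' Ratio of the anterolateral cortical edge length (lateral apex to
#' anterior apex, along the cortex) to the posterolateral edge length
#' (lateral apex to posterior apex).  Arc length along the cortex is used;
#' set `chord = TRUE` to use the straight apex-to-apex chords instead.
#'
#' @param cs a [cross_section()].
#' @param chord use straight chords instead of cortical arc length.
#' @return one-row tibble: `subject_id`, `aspect_ratio`,
#'   `anterolateral_mm`, `posterolateral_mm`.
#' @export
aspect_ratio <- function(cs, chord = FALSE) {
  stopifnot(inherits(cs, "cross_section"))
  if (chord) {
    ant <- vec_norm(cs$landmarks$anterior_apex - cs$landmarks$lateral_apex)
    post <- vec_norm(cs$landmarks$posterior_apex - cs$landmarks$lateral_apex)
  } else {
    ant <- cs$paths$anterior_length
    post <- cs$paths$posterior_length
  }
  if (ant <= 0 || post <= 0) {
    stop("degenerate-contour: zero-length lateral cortex path", call. = FALSE)
  }
  tibble::tibble(subject_id = cs$subject_id, aspect_ratio = ant / post,
                 anterolateral_mm = ant, posterolateral_mm = post)
}

#' Per-subject shape metrics for a cohort
#'
#' Classifies every section and computes its lateral aspect ratio.
#'
#' @param cohort cohort tibble from [generate_cohort()] or [read_cohort()]
#'   (any data frame with a `section` list-column works).
#' @param ... passed to [classify_shape()].
#' @return tibble: `subject_id`, `side`, `shape_class`, `aspect_ratio`,
#'   `anterolateral_mm`, `posterolateral_mm`.
#' @export
shape_metrics <- function(cohort, ...) {
  stopifnot(is.data.frame(cohort), "section" %in% names(cohort))
  purrr::map_dfr(cohort$section, function(cs) {
    dplyr::mutate(aspect_ratio(cs),
                  side = cs$side,
                  shape_class = classify_shape(cs, ...),
                  .after = "subject_id")
  })
}
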
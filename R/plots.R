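# Figures: per-section views, registration overlays, corridor diagrams.
# Colour semantics follow the field convention: red/pink for the
# anteriorly angulated tunnels, dark/light blue for the posteriorly
# angulated tunnels, green for center-center.

orientation_colours <- c(anterior_angulated = "#c0392b",
                         posterior_angulated = "#1f4e9c",
                         center_center = "#1e8449")

contour_df <- function(m, what, subject_id = "s") {
  ring <- rbind(m, m[1, ])
  tibble::tibble(x = ring[, 1], y = ring[, 2], what = what,
                 subject_id = subject_id)
}

#' Plot one cross-section with its landmarks
#'
#' @param cs a [cross_section()].
#' @param solution optional one-subject solution tibble from
#'   [solve_subject()]; exits and axes are drawn coloured by orientation.
#' @return a ggplot object.
#' @export
plot_cross_section <- function(cs, solution = NULL) {
  df <- contour_df(cs$contour, "fibula", cs$subject_id)
  if (!is.null(cs$tibia_contour)) {
    df <- dplyr::bind_rows(df, contour_df(cs$tibia_contour, "tibia", cs$subject_id))
  }
  lms <- purrr::imap_dfr(cs$landmarks, function(p, nm) {
    tibble::tibble(x = p[1], y = p[2], landmark = nm)
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(ggplot2::aes(linetype = .data$what), colour = "grey20") +
    ggplot2::geom_point(data = lms, ggplot2::aes(shape = .data$landmark),
                        size = 2, colour = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "anterior [mm]", y = "lateral [mm]",
                  title = paste("subject", cs$subject_id)) +
    ggplot2::theme_minimal()
  if (!is.null(solution)) {
    segs <- solution_segments(cs, solution)
    p <- p + ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$orientation),
      inherit.aes = FALSE, linewidth = 0.4) +
      ggplot2::scale_colour_manual(values = orientation_colours)
  }
  p
}

solution_segments <- function(cs, solution) {
  rows <- list()
  add <- function(orientation, anchor, angle_deg) {
    if (is.na(angle_deg)) return()
    th <- angle_deg * pi / 180
    ex <- tryCatch(
      axis_lateral_exit(cs, tunnel_axis(anchor, c(cos(th), sin(th))))$point,
      error = function(e) NULL)
    if (is.null(ex)) return()
    rows[[length(rows) + 1]] <<- tibble::tibble(
      orientation = orientation, x0 = anchor[1], y0 = anchor[2],
      x1 = ex[1], y1 = ex[2])
  }
  for (i in seq_len(nrow(solution))) {
    s <- solution[i, ]
    anchor <- switch(s$orientation,
                     anterior_angulated = cs$landmarks$anterior_anchor,
                     posterior_angulated = cs$landmarks$posterior_anchor,
                     center_center = cs$landmarks$tibial_center)
    add(s$orientation, anchor, s$angle_central_deg)
    add(s$orientation, anchor, s$angle_anterior_deg)
    add(s$orientation, anchor, s$angle_posterior_deg)
  }
  dplyr::bind_rows(rows)
}

#' Registration overlay (before / after)
#'
#' Draws every subject's contour and drill axes before and after
#' Procrustes transformation to the reference, with the reference
#' landmarks in black.
#'
#' @param registration a [register_cohort()] result.
#' @param solutions optional solution tibble; axes are drawn coloured by
#'   orientation.
#' @param max_subjects cap on the number of subjects drawn.
#' @return a ggplot object.
#' @export
plot_overlay <- function(registration, solutions = NULL, max_subjects = 50) {
  stopifnot(inherits(registration, "cohort_registration"))
  cohort <- registration$cohort
  idx <- seq_len(min(nrow(cohort), max_subjects))
  panels <- list()
  segs <- list()
  for (i in idx) {
    cs <- cohort$section[[i]]
    fit <- registration$transforms[[i]]
    cst <- transform_section(cs, fit)
    panels[[length(panels) + 1]] <-
      dplyr::mutate(contour_df(cs$contour, "fibula", cs$subject_id),
                    panel = "before registration")
    panels[[length(panels) + 1]] <-
      dplyr::mutate(contour_df(cst$contour, "fibula", cs$subject_id),
                    panel = "after registration")
    if (!is.null(solutions)) {
      sol <- solutions[solutions$subject_id == cs$subject_id, , drop = FALSE]
      s0 <- dplyr::mutate(solution_segments(cs, sol), panel = "before registration")
      s1 <- dplyr::mutate(solution_segments(cst, sol), panel = "after registration")
      segs[[length(segs) + 1]] <- dplyr::bind_rows(s0, s1)
    }
  }
  df <- dplyr::bind_rows(panels)
  df$panel <- factor(df$panel, c("before registration", "after registration"))
  refdf <- tibble::tibble(x = registration$reference[, 1],
                          y = registration$reference[, 2],
                          panel = factor("after registration",
                                         levels(df$panel)))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        group = .data$subject_id)) +
    ggplot2::geom_path(alpha = 0.25, colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_point(data = refdf, inherit.aes = FALSE,
                        ggplot2::aes(.data$x, .data$y),
                        colour = "black", size = 2, shape = 17) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "anterior [mm]", y = "lateral [mm]") +
    ggplot2::theme_minimal()
  if (length(segs)) {
    sdf <- dplyr::bind_rows(segs)
    sdf$panel <- factor(sdf$panel, levels(df$panel))
    p <- p + ggplot2::geom_segment(
      data = sdf,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$orientation),
      inherit.aes = FALSE, alpha = 0.35, linewidth = 0.3) +
      ggplot2::scale_colour_manual(values = orientation_colours)
  }
  p
}

#' @rdname plot_overlay
#' @param object a `cohort_registration`.
#' @param ... passed to [plot_overlay()].
#' @export
autoplot.cohort_registration <- function(object, ...) plot_overlay(object, ...)

#' Corridor diagram
#'
#' Shows each orientation's cohort safe corridor as a band on the signed
#' lateral-cortex axis (negative: posterior cortex, 0: lateral apex,
#' positive: anterior cortex), with the central-alignment mean +/- sd as
#' point and whiskers.
#'
#' @param object a [corridor_report()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.corridor_report <- function(object, ...) {
  cor <- dplyr::mutate(object$corridors,
                       orientation = factor(.data$orientation,
                                            names(orientation_colours)))
  cen <- dplyr::mutate(object$central,
                       orientation = factor(.data$orientation,
                                            names(orientation_colours)))
  ggplot2::ggplot(cor) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                                    ymin = as.integer(.data$orientation) - 0.3,
                                    ymax = as.integer(.data$orientation) + 0.3,
                                    fill = .data$orientation), alpha = 0.5) +
    ggplot2::geom_pointrange(
      data = cen,
      ggplot2::aes(x = .data$mean, y = as.integer(.data$orientation),
                   xmin = .data$mean - .data$sd, xmax = .data$mean + .data$sd,
                   colour = .data$orientation)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_y_continuous(breaks = seq_along(levels(cor$orientation)),
                                labels = levels(cor$orientation)) +
    ggplot2::scale_fill_manual(values = orientation_colours, guide = "none") +
    ggplot2::scale_colour_manual(values = orientation_colours, guide = "none") +
    ggplot2::labs(x = "signed location on the lateral cortex [%]", y = NULL,
                  caption = "negative: posterior cortex; positive: anterior cortex") +
    ggplot2::theme_minimal()
}
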
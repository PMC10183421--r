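# File formats: contour JSON (one file per cohort, one record per
# subject), WKT POLYGON text, landmark CSV keyed by the standard point
# numbering (1, 4, 7, 8, 9), and an ImageJ-style multi-point XY CSV
# dialect mapped through a row-order configuration.

POINT_IDS <- c(anterior_anchor = 1L, posterior_anchor = 4L,
               anterior_apex = 7L, posterior_apex = 8L, lateral_apex = 9L)

mirror_matrix <- function(m) { m[, 1] <- -m[, 1]; m }

#' Write cohort contour and landmark files
#'
#' Serialises a cohort to the formats the ingest reads: a contour JSON
#' file (per subject: `subject_id`, `side`, `pixel_spacing_mm`, vertex
#' list, optional tibial contour, heights, tunnel diameter), a landmark
#' CSV (`subject_id`, `point_id`, `x`, `y`), and a ground-truth CSV with
#' the plain (non-list) cohort columns.  Left-sided subjects are written
#' in their raw (mirrored) frame, as they would come off an image.
#'
#' @param cohort cohort tibble with a `section` list-column.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is.data.frame(cohort), "section" %in% names(cohort))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- lapply(cohort$section, function(cs) {
    m <- cs$contour
    tib <- cs$tibia_contour
    if (cs$side == "left") {
      m <- mirror_matrix(m)
      if (!is.null(tib)) tib <- mirror_matrix(tib)
    }
    rec <- list(
      subject_id = cs$subject_id,
      side = cs$side,
      pixel_spacing_mm = 1.0,
      fibula_contour = unname(apply(m, 1, function(r) c(r[1], r[2]),
                                    simplify = FALSE)),
      height_from_plafond_mm = cs$height_from_plafond,
      height_from_fibular_tip_mm = cs$height_from_fibular_tip
    )
    if (!is.null(tib)) {
      rec$tibia_contour <- unname(apply(tib, 1, function(r) c(r[1], r[2]),
                                        simplify = FALSE))
    }
    rec
  })
  contour_path <- file.path(dir, "contours.json")
  jsonlite::write_json(recs, contour_path, auto_unbox = TRUE, digits = NA)

  lmk <- purrr::map_dfr(cohort$section, function(cs) {
    sgn <- if (cs$side == "left") -1 else 1
    purrr::map_dfr(names(POINT_IDS), function(nm) {
      p <- cs$landmarks[[nm]]
      tibble::tibble(subject_id = cs$subject_id, point_id = POINT_IDS[[nm]],
                     x = sgn * unname(p[1]), y = unname(p[2]))
    })
  })
  landmark_path <- file.path(dir, "landmarks.csv")
  readr::write_csv(lmk, landmark_path)

  truth_path <- file.path(dir, "truth.csv")
  truth <- cohort[vapply(cohort, function(col) !is.list(col), logical(1))]
  readr::write_csv(truth, truth_path)

  invisible(c(contours = contour_path, landmarks = landmark_path,
              truth = truth_path))
}

#' Read a cohort from contour and landmark files
#'
#' Rebuilds [cross_section()] objects from the contour JSON and landmark
#' CSV written by [write_cohort()] (or assembled by hand in the same
#' formats).  Left-sided subjects are mirrored about the y axis into the
#' canonical right-side frame at ingest.
#'
#' @param contour_file contour JSON path.
#' @param landmark_file landmark CSV path (`subject_id`, `point_id`
#'   in \{1, 4, 7, 8, 9\}, `x`, `y`).
#' @param snap_tol landmark snap tolerance (mm).
#' @return cohort tibble with `subject_id`, `side` and the `section`
#'   list-column.
#' @examples
#' dir <- system.file("extdata", "synthetic_cohort", package = "fibsafe")
#' cohort <- read_cohort(file.path(dir, "contours.json"),
#'                       file.path(dir, "landmarks.csv"))
#' shape_metrics(cohort)
#' @export
read_cohort <- function(contour_file, landmark_file, snap_tol = 0.1) {
  recs <- jsonlite::read_json(contour_file, simplifyVector = FALSE)
  lmk <- readr::read_csv(landmark_file, show_col_types = FALSE)
  stopifnot(all(c("subject_id", "point_id", "x", "y") %in% names(lmk)))
  id2name <- stats::setNames(names(POINT_IDS), POINT_IDS)

  sections <- lapply(recs, function(rec) {
    m <- do.call(rbind, lapply(rec$fibula_contour, function(v) {
      as.numeric(unlist(v))
    }))
    spacing <- rec$pixel_spacing_mm %||% 1
    m <- m * spacing
    tib <- if (!is.null(rec$tibia_contour)) {
      do.call(rbind, lapply(rec$tibia_contour, function(v) as.numeric(unlist(v)))) * spacing
    }
    sub <- lmk[lmk$subject_id == rec$subject_id, , drop = FALSE]
    if (nrow(sub) < 5) {
      stop("missing landmarks for subject ", rec$subject_id, call. = FALSE)
    }
    lm <- stats::setNames(
      lapply(seq_len(nrow(sub)), function(i) c(sub$x[i], sub$y[i]) * spacing),
      id2name[as.character(sub$point_id)]
    )
    side <- rec$side %||% "right"
    if (side == "left") {
      m <- mirror_matrix(m)
      if (!is.null(tib)) tib <- mirror_matrix(tib)
      lm <- lapply(lm, function(p) c(-p[1], p[2]))
    }
    cross_section(
      fibula_contour = m, landmarks = lm,
      subject_id = rec$subject_id, side = side, tibia_contour = tib,
      height_from_plafond = rec$height_from_plafond_mm %||% NA_real_,
      height_from_fibular_tip = rec$height_from_fibular_tip_mm %||% NA_real_,
      snap_tol = snap_tol
    )
  })
  tibble::tibble(
    subject_id = vapply(sections, `[[`, character(1), "subject_id"),
    side = vapply(sections, `[[`, character(1), "side"),
    section = sections
  )
}

#' Parse a WKT POLYGON into a contour matrix
#'
#' Accepts `POLYGON ((x y, x y, ...))` text (outer ring only).
#'
#' @param wkt a WKT string, or the path of a file containing one.
#' @return n x 2 contour matrix.
#' @export
read_contour_wkt <- function(wkt) {
  if (length(wkt) == 1 && !grepl("POLYGON", wkt, ignore.case = TRUE) &&
      file.exists(wkt)) {
    wkt <- paste(readLines(wkt, warn = FALSE), collapse = " ")
  }
  m <- regmatches(wkt, regexpr("\\(\\s*\\(([^)]*)\\)", wkt))
  if (length(m) == 0) stop("not a WKT POLYGON", call. = FALSE)
  body <- gsub("[()]", "", m)
  pairs <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
  out <- do.call(rbind, lapply(pairs, function(p) as.numeric(p[1:2])))
  if (any(!is.finite(out))) stop("malformed WKT coordinates", call. = FALSE)
  as_contour(out)
}

#' Format a contour as WKT POLYGON text
#' @param m n x 2 contour matrix.
#' @return a WKT string (ring explicitly closed).
#' @export
format_contour_wkt <- function(m) {
  m <- as_contour(m)
  ring <- rbind(m, m[1, ])
  paste0("POLYGON ((",
         paste(sprintf("%.9g %.9g", ring[, 1], ring[, 2]), collapse = ", "),
         "))")
}

#' Read ImageJ-style multi-point measurement CSV
#'
#' ImageJ multi-point measurements export one row per click with upper
#' case `X` and `Y` columns; the anatomical identity of each point is
#' implied by the clicking order.  `point_order` maps row order to the
#' standard point numbering (1 anteromedial anchor, 4 posteromedial
#' anchor, 7 anterior apex, 8 posterior apex, 9 lateral apex) and can be
#' supplied inline or via the `landmark_order:` field of a YAML mapping
#' file.
#'
#' @param path CSV path.
#' @param subject_id subject these points belong to.
#' @param point_order integer vector of point ids in row order, or a YAML
#'   file with a `landmark_order` field.
#' @param pixel_spacing_mm scale applied to the pixel coordinates.
#' @return standard landmark tibble (`subject_id`, `point_id`, `x`, `y`).
#' @export
read_imagej_landmarks <- function(path, subject_id,
                                  point_order = c(1, 4, 7, 8, 9),
                                  pixel_spacing_mm = 1) {
  if (is.character(point_order) && length(point_order) == 1) {
    cfg <- yaml::read_yaml(point_order)
    point_order <- as.integer(cfg$landmark_order)
  }
  df <- readr::read_csv(path, show_col_types = FALSE,
                        name_repair = "unique_quiet")
  xcol <- intersect(c("X", "x"), names(df))[1]
  ycol <- intersect(c("Y", "y"), names(df))[1]
  if (is.na(xcol) || is.na(ycol)) stop("no X/Y columns found", call. = FALSE)
  if (nrow(df) != length(point_order)) {
    stop("point_order maps ", length(point_order), " rows but the file has ",
         nrow(df), call. = FALSE)
  }
  tibble::tibble(subject_id = subject_id, point_id = as.integer(point_order),
                 x = df[[xcol]] * pixel_spacing_mm,
                 y = df[[ycol]] * pixel_spacing_mm)
}

#' Write a landmark CSV
#' @param landmarks tibble with `subject_id`, `point_id`, `x`, `y`.
#' @param path output path.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  readr::write_csv(landmarks, path)
  invisible(path)
}
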
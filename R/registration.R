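# Procrustes superimposition of landmark configurations under similarity
# transforms (rotation + uniform scale + translation; no reflection, since
# sides are canonicalized at ingest).

as_landmark_matrix <- function(x) {
  if (inherits(x, "cross_section")) {
    x <- rbind(x$landmarks$anterior_apex, x$landmarks$posterior_apex,
               x$landmarks$lateral_apex)
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2, nrow(x) >= 2, all(is.finite(x)))
  dimnames(x) <- list(NULL, c("x", "y"))
  x
}

collinear_check <- function(x) {
  if (nrow(x) == 3) {
    ab <- x[2, ] - x[1, ]; ac <- x[3, ] - x[1, ]
    area2 <- abs(cross2(ab, ac))
    if (area2 <= 1e-12 * (max(abs(x)) + 1)^2) {
      stop("degenerate-configuration: landmarks are collinear", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Least-squares similarity alignment of landmark configurations
#'
#' Finds the similarity transform (rotation, uniform scale, translation;
#' reflection excluded) minimizing the sum of squared distances between
#' matched landmarks, in closed form via complex least squares.  The
#' registration quality metric is the mean distance of the transformed
#' source landmarks from the reference landmarks.
#'
#' @param source,reference landmark matrices (n x 2, matched rows) or
#'   [cross_section()] objects (whose fibular apexes 7, 8, 9 are used).
#' @param allow_scale include uniform scaling (default); `FALSE` fits a
#'   rigid rotation + translation.
#' @return object of class `procrustes_fit`: `rotation` (radians),
#'   `scale`, `translation` (mm), `reflected` (always `FALSE`),
#'   `per_landmark_residuals` (mm), `mean_distance_error` (mm), and the
#'   transformed source landmarks `fitted`.
#' @export
procrustes_align <- function(source, reference, allow_scale = TRUE) {
  src <- as_landmark_matrix(source)
  ref <- as_landmark_matrix(reference)
  stopifnot(nrow(src) == nrow(ref))
  collinear_check(src)
  collinear_check(ref)
  zs <- complex(real = src[, 1], imaginary = src[, 2])
  zr <- complex(real = ref[, 1], imaginary = ref[, 2])
  cs <- mean(zs); cr <- mean(zr)
  zs0 <- zs - cs; zr0 <- zr - cr
  num <- sum(Conj(zs0) * zr0)
  if (allow_scale) {
    a <- num / sum(Mod(zs0)^2)
  } else {
    a <- exp(1i * Arg(num))
  }
  b <- cr - a * cs
  fit <- a * zs + b
  res <- Mod(fit - zr)
  structure(
    list(
      rotation = Arg(a),
      scale = Mod(a),
      translation = c(tx = Re(b), ty = Im(b)),
      reflected = FALSE,
      per_landmark_residuals = res,
      mean_distance_error = mean(res),
      fitted = cbind(x = Re(fit), y = Im(fit))
    ),
    class = "procrustes_fit"
  )
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat("<procrustes_fit> rotation", sprintf("%.2f", x$rotation * 180 / pi),
      "deg, scale", sprintf("%.4f", x$scale),
      ", mean distance error", sprintf("%.4g", x$mean_distance_error), "mm\n")
  invisible(x)
}

#' Apply a similarity transform to points
#'
#' @param fit a `procrustes_fit` (or a list with `rotation`, `scale`,
#'   `translation`).
#' @param pts n x 2 matrix or length-2 vector.
#' @return transformed coordinates, same shape as the input.
#' @export
apply_transform <- function(fit, pts) {
  single <- is.null(dim(pts))
  p <- if (single) matrix(as.numeric(pts), 1) else as.matrix(pts)
  a <- fit$scale * exp(1i * fit$rotation)
  z <- a * complex(real = p[, 1], imaginary = p[, 2]) +
    complex(real = fit$translation[1], imaginary = fit$translation[2])
  out <- cbind(x = Re(z), y = Im(z))
  if (single) c(x = out[1, 1], y = out[1, 2]) else out
}

#' Invert a similarity transform
#' @param fit a `procrustes_fit`.
#' @return a transform list usable with [apply_transform()].
#' @export
invert_transform <- function(fit) {
  a <- fit$scale * exp(1i * fit$rotation)
  b <- complex(real = fit$translation[1], imaginary = fit$translation[2])
  ai <- 1 / a
  bi <- -b / a
  structure(list(rotation = Arg(ai), scale = Mod(ai),
                 translation = c(tx = Re(bi), ty = Im(bi)),
                 reflected = FALSE),
            class = "procrustes_fit")
}

#' Transform a whole annotated cross-section
#'
#' Applies a similarity transform consistently to the fibular and tibial
#' contours and all landmarks.  Signed normalized exit locations are
#' invariant under this operation (arc-length ratios are similarity
#' invariants).
#'
#' @param cs a [cross_section()].
#' @param fit a `procrustes_fit`.
#' @return the transformed `cross_section`.
#' @export
transform_section <- function(cs, fit) {
  stopifnot(inherits(cs, "cross_section"))
  lm <- lapply(cs$landmarks[c("anterior_anchor", "posterior_anchor",
                              "anterior_apex", "posterior_apex",
                              "lateral_apex")],
               function(p) apply_transform(fit, p))
  cross_section(
    fibula_contour = apply_transform(fit, cs$contour),
    landmarks = lm,
    subject_id = cs$subject_id,
    side = cs$side,
    tibia_contour = if (!is.null(cs$tibia_contour))
      apply_transform(fit, cs$tibia_contour),
    shape_class = cs$shape_class,
    height_from_plafond = cs$height_from_plafond,
    height_from_fibular_tip = cs$height_from_fibular_tip,
    snap_tol = cs$snap_tol * fit$scale
  )
}

#' Register a cohort onto a reference configuration
#'
#' Aligns every subject's fibular apex landmarks (7, 8, 9) onto a
#' reference by Procrustes superimposition.  The reference is chosen by
#' policy: `"mean"` iterates the generalized-Procrustes mean shape until
#' convergence, `"first"` uses the first subject, and any subject id uses
#' that subject (the single-reference-image design).
#'
#' @param cohort cohort tibble with a `section` list-column.
#' @param reference `"mean"`, `"first"`, or a subject id.
#' @param allow_scale include uniform scaling in the fits.
#' @param tol,max_iter convergence control for the mean-shape iteration
#'   (maximal coordinate change between iterations).
#' @return object of class `cohort_registration`: `results` tibble
#'   (`subject_id`, `rotation_deg`, `scale`, `tx`, `ty`,
#'   `mean_distance_error_mm`), the `reference` landmark matrix, the
#'   per-subject `transforms`, and the input `cohort` (for overlays).
#' @export
register_cohort <- function(cohort, reference = "mean", allow_scale = TRUE,
                            tol = 1e-8, max_iter = 100) {
  stopifnot(is.data.frame(cohort), "section" %in% names(cohort))
  if (nrow(cohort) < 1) stop("empty cohort", call. = FALSE)
  lms <- lapply(cohort$section, as_landmark_matrix)

  ref <- if (identical(reference, "mean")) {
    mean_shape(lms, allow_scale = allow_scale, tol = tol, max_iter = max_iter)
  } else if (identical(reference, "first")) {
    lms[[1]]
  } else {
    i <- match(reference, cohort$subject_id)
    if (is.na(i)) stop("reference subject '", reference, "' not in cohort",
                       call. = FALSE)
    lms[[i]]
  }

  fits <- lapply(lms, function(x) procrustes_align(x, ref, allow_scale = allow_scale))
  results <- tibble::tibble(
    subject_id = cohort$subject_id,
    rotation_deg = vapply(fits, function(f) f$rotation * 180 / pi, numeric(1)),
    scale = vapply(fits, `[[`, numeric(1), "scale"),
    tx = vapply(fits, function(f) unname(f$translation[1]), numeric(1)),
    ty = vapply(fits, function(f) unname(f$translation[2]), numeric(1)),
    mean_distance_error_mm = vapply(fits, `[[`, numeric(1), "mean_distance_error")
  )
  structure(
    list(results = results, reference = ref, transforms = fits, cohort = cohort),
    class = "cohort_registration"
  )
}

# Generalized-Procrustes mean shape, size-normalized to the mean centroid
# size of the input configurations.
mean_shape <- function(lms, allow_scale = TRUE, tol = 1e-8, max_iter = 100) {
  csize <- function(x) sqrt(sum(scale(x, scale = FALSE)^2))
  target_size <- mean(vapply(lms, csize, numeric(1)))
  ref <- lms[[1]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(lms, function(x) {
      procrustes_align(x, ref, allow_scale = allow_scale)$fitted
    })
    new_ref <- Reduce(`+`, aligned) / length(aligned)
    new_ref <- scale(new_ref, scale = FALSE)
    new_ref <- new_ref * (target_size / csize(new_ref))
    attr(new_ref, "scaled:center") <- NULL
    dimnames(new_ref) <- list(NULL, c("x", "y"))
    if (max(abs(new_ref - ref)) < tol && it > 1) {
      return(new_ref)
    }
    ref <- new_ref
  }
  ref
}

#' @export
print.cohort_registration <- function(x, ...) {
  cat("<cohort_registration>", nrow(x$results), "subjects; mean distance error",
      sprintf("%.3f", mean(x$results$mean_distance_error_mm)), "mm\n")
  invisible(x)
}
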
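# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Procrustes fit
#' @param x a [procrustes_align()] result.
#' @param ... unused.
#' @return one row per landmark with its residual distance (mm).
#' @export
tidy.procrustes_fit <- function(x, ...) {
  tibble::tibble(landmark = seq_along(x$per_landmark_residuals),
                 residual_mm = x$per_landmark_residuals)
}

#' @rdname tidy.procrustes_fit
#' @return for `glance()`: one row with the transform parameters and the
#'   mean distance error.
#' @export
glance.procrustes_fit <- function(x, ...) {
  tibble::tibble(rotation_deg = x$rotation * 180 / pi, scale = x$scale,
                 tx = unname(x$translation[1]), ty = unname(x$translation[2]),
                 reflected = x$reflected,
                 mean_distance_error_mm = x$mean_distance_error)
}

#' Tidy a cohort registration
#' @param x a [register_cohort()] result.
#' @param ... unused.
#' @return per-subject transform parameters and registration errors.
#' @export
tidy.cohort_registration <- function(x, ...) x$results

#' @rdname tidy.cohort_registration
#' @return for `glance()`: cohort summary of the registration error.
#' @export
glance.cohort_registration <- function(x, ...) {
  s <- summarize_values(x$results$mean_distance_error_mm)
  tibble::tibble(n_subjects = s$n, mean_error_mm = s$mean, sd_error_mm = s$sd,
                 min_error_mm = s$min, max_error_mm = s$max)
}

#' Tidy a corridor report
#' @param x a [corridor_report()] result.
#' @param ... unused.
#' @return the per-orientation corridor tibble.
#' @export
tidy.corridor_report <- function(x, ...) x$corridors

#' @rdname tidy.corridor_report
#' @return for `glance()`: one row with the corridor bounds and central
#'   alignment summaries in wide format.
#' @export
glance.corridor_report <- function(x, ...) {
  wide_cor <- tidyr::pivot_wider(
    x$corridors[, c("orientation", "lower", "upper")],
    names_from = "orientation", values_from = c("lower", "upper"),
    names_glue = "{orientation}_{.value}")
  wide_cen <- tidyr::pivot_wider(
    x$central[, c("orientation", "mean", "sd")],
    names_from = "orientation", values_from = c("mean", "sd"),
    names_glue = "central_{orientation}_{.value}")
  dplyr::bind_cols(tibble::tibble(n_subjects = x$n_subjects),
                   wide_cor, wide_cen)
}
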
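# Cohort-level safe corridors and summary statistics.

#' Cohort safe corridor for an angulated orientation
#'
#' The cohort safe corridor of an angulated orientation is the segment of
#' the lateral cortex usable as a drilling starting point in every
#' subject: the intersection of the per-subject feasible exit intervals,
#' i.e. the minimum of the anterior borders and the maximum of the
#' posterior borders (in the signed-percent convention).  Subjects with an
#' infeasible solution are excluded and counted.
#'
#' @param solutions tunnel-solution tibble from [simulate_tunnels()].
#' @param orientation `"anterior_angulated"` or `"posterior_angulated"`.
#' @param mode `"intersection"` (the safe-corridor definition) or
#'   `"range"` (cohort min/max of the borders, for comparison).
#' @return one-row tibble: `orientation`, `lower`, `upper`, `mode`,
#'   `empty` (flag for an empty intersection), `n_subjects`,
#'   `n_infeasible`.
#' @export
cohort_corridor_angulated <- function(solutions,
                                      orientation = c("anterior_angulated",
                                                      "posterior_angulated"),
                                      mode = c("intersection", "range")) {
  orientation <- match.arg(orientation)
  mode <- match.arg(mode)
  sol <- solutions[solutions$orientation == orientation, , drop = FALSE]
  n_inf <- sum(!sol$feasible | is.na(sol$border_anterior_pct))
  sol <- sol[sol$feasible & !is.na(sol$border_anterior_pct), , drop = FALSE]
  if (nrow(sol) == 0) {
    stop("no feasible subject solutions for ", orientation, call. = FALSE)
  }
  if (mode == "intersection") {
    upper <- min(sol$border_anterior_pct)
    lower <- max(sol$border_posterior_pct)
  } else {
    upper <- max(sol$border_anterior_pct)
    lower <- min(sol$border_posterior_pct)
  }
  tibble::tibble(orientation = orientation, lower = lower, upper = upper,
                 mode = mode, empty = lower > upper,
                 n_subjects = nrow(sol), n_infeasible = n_inf)
}

#' Cohort safe corridor for the center-center orientation
#'
#' The central corridor spans the most anterior and most posterior
#' center-center exit locations across the cohort (a range, not an
#' intersection: the orientation has a single axis per subject).
#'
#' @param solutions tunnel-solution tibble from [simulate_tunnels()].
#' @return one-row tibble as in [cohort_corridor_angulated()] with
#'   `mode = "range"`.
#' @export
cohort_corridor_central <- function(solutions) {
  sol <- solutions[solutions$orientation == "center_center", , drop = FALSE]
  vals <- sol$central_pct[!is.na(sol$central_pct)]
  if (length(vals) == 0) stop("no center-center locations", call. = FALSE)
  tibble::tibble(orientation = "center_center",
                 lower = min(vals), upper = max(vals), mode = "range",
                 empty = FALSE, n_subjects = length(vals),
                 n_infeasible = sum(is.na(sol$central_pct)))
}

#' Mean, standard deviation and range
#'
#' Cohort descriptive summary in the mean +/- sd (range) convention; the
#' sample standard deviation uses the n - 1 denominator.
#'
#' @param values numeric vector (n >= 2 for the sd).
#' @return one-row tibble: `mean`, `sd`, `min`, `max`, `n`.
#' @export
summarize_values <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    stop("at least 2 values are needed for a standard deviation", call. = FALSE)
  }
  tibble::tibble(mean = mean(values), sd = stats::sd(values),
                 min = min(values), max = max(values), n = length(values))
}

#' Paired t-test and Pearson correlation for paired cohort measures
#'
#' Two-sided paired t-test on the differences and the Pearson correlation
#' with its two-sided p-value (t transform of r).  Degenerate cases are
#' flagged rather than raised: all-zero differences give `t = 0`,
#' `p_t = 1`; a zero-variance input leaves `r` as `NA`.
#'
#' @param x,y paired numeric vectors of equal length (n >= 3).
#' @return one-row tibble: `n`, `t`, `df`, `p_t`, `r`, `p_r`, `degenerate`.
#' @export
paired_t_and_pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d <- x - y
  degenerate <- stats::sd(d) == 0 || stats::sd(x) == 0 || stats::sd(y) == 0
  if (stats::sd(d) == 0) {
    tt <- list(statistic = c(t = 0), parameter = c(df = n - 1), p.value = 1)
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_; p_r <- NA_real_
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate); p_r <- ct$p.value
  }
  tibble::tibble(n = n, t = unname(tt$statistic), df = unname(tt$parameter),
                 p_t = tt$p.value, r = r, p_r = p_r, degenerate = degenerate)
}

#' Cohort corridor report
#'
#' Aggregates per-subject tunnel solutions into the three cohort safe
#' corridors plus the central-alignment summaries (ideal-axis locations of
#' the angulated orientations and the center-center locations).
#'
#' @param solutions tunnel-solution tibble from [simulate_tunnels()].
#' @param mode corridor semantics for the angulated orientations, see
#'   [cohort_corridor_angulated()].
#' @return object of class `corridor_report`: `corridors` tibble and
#'   `central` tibble (per-orientation mean, sd, range of the central
#'   alignment), plus counts.
#' @export
corridor_report <- function(solutions, mode = "intersection") {
  corridors <- dplyr::bind_rows(
    cohort_corridor_angulated(solutions, "anterior_angulated", mode = mode),
    cohort_corridor_angulated(solutions, "posterior_angulated", mode = mode),
    cohort_corridor_central(solutions)
  )
  central <- solutions |>
    dplyr::filter(!is.na(.data$central_pct)) |>
    dplyr::group_by(.data$orientation) |>
    dplyr::summarise(mean = mean(.data$central_pct),
                     sd = stats::sd(.data$central_pct),
                     min = min(.data$central_pct),
                     max = max(.data$central_pct),
                     n = dplyr::n(), .groups = "drop")
  structure(
    list(corridors = corridors, central = central,
         n_subjects = length(unique(solutions$subject_id)),
         n_infeasible = sum(!solutions$feasible, na.rm = TRUE)),
    class = "corridor_report"
  )
}

#' @export
print.corridor_report <- function(x, ...) {
  cat("<corridor_report>", x$n_subjects, "subjects\n")
  for (i in seq_len(nrow(x$corridors))) {
    r <- x$corridors[i, ]
    cat(sprintf("  %-20s [%6.1f%%, %6.1f%%] (%s%s)\n", r$orientation,
                r$lower, r$upper, r$mode, if (r$empty) ", EMPTY" else ""))
  }
  for (i in seq_len(nrow(x$central))) {
    r <- x$central[i, ]
    cat(sprintf("  central %-12s %5.1f +/- %4.1f%% (range %5.1f to %5.1f)\n",
                r$orientation, r$mean, r$sd, r$min, r$max))
  }
  invisible(x)
}
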
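# End-to-end orchestration: generate or ingest a cohort, run shape
# metrics, per-subject tunnel simulation, registration, corridor
# statistics; emit tables, a report JSON and (optionally) figures.

#' Pipeline configuration
#'
#' Exactly one of a synthetic-cohort parameter set or a pair of input
#' paths must be supplied.
#'
#' @param cohort a [cohort_params()] object (synthetic mode), or `NULL`.
#' @param input list with `contours` and `landmarks` paths (ingest mode),
#'   or `NULL`.
#' @param tunnel_diameter_mm tunnel diameter; `NULL` defers to the cohort.
#' @param reference_policy registration reference: `"mean"`, `"first"` or
#'   a subject id.
#' @param epsilon geometric tolerance (mm).
#' @param out_dir output directory for artifact files (`NULL`: no files).
#' @param seed integer seed applied to all randomness of the run.
#' @param write_figures also write overlay/corridor figures (PDF).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_params(), input = NULL,
                            tunnel_diameter_mm = NULL,
                            reference_policy = "mean", epsilon = 1e-9,
                            out_dir = NULL, seed = 1L,
                            write_figures = FALSE) {
  if (is.null(cohort) == is.null(input)) {
    stop("supply exactly one of `cohort` (synthetic) or `input` (files)",
         call. = FALSE)
  }
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_params"))
  if (!is.null(input)) stopifnot(all(c("contours", "landmarks") %in% names(input)))
  structure(
    list(cohort = cohort, input = input,
         tunnel_diameter_mm = tunnel_diameter_mm,
         reference_policy = reference_policy, epsilon = epsilon,
         out_dir = out_dir, seed = as.integer(seed),
         write_figures = isTRUE(write_figures)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] arguments; synthetic cohort
#' parameters live under a `cohort:` block and are passed to
#' [cohort_params()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort)) {
    cp <- y$cohort
    for (nm in intersect(names(cp), c("shape_mixture", "aspect_ratio_bounds",
                                      "fibula_ap_width_mm", "fibula_ml_depth_mm",
                                      "anterior_anchor_offset_mm",
                                      "posterior_anchor_offset_mm",
                                      "height_from_plafond_mm", "height_from_tip_mm",
                                      "injured_height_shift_mm", "patient_height_cm",
                                      "irregular_amplitude_range"))) {
      cp[[nm]] <- unlist(cp[[nm]])
    }
    do.call(cohort_params, cp)
  }
  pipeline_config(
    cohort = cohort,
    input = y$input,
    tunnel_diameter_mm = y$tunnel_diameter_mm,
    reference_policy = y$reference_policy %||% "mean",
    epsilon = y$epsilon %||% 1e-9,
    out_dir = y$out_dir,
    seed = y$seed %||% 1L,
    write_figures = isTRUE(y$write_figures)
  )
}

#' Run the full corridor analysis pipeline
#'
#' Stages, in order: cohort generation or ingest, shape metrics,
#' per-subject tunnel simulation, Procrustes registration (overlay / QC;
#' corridor statistics consume the raw per-subject percent locations,
#' which are similarity invariants), and cohort corridor statistics.
#' Per-subject failures are logged and carried as infeasible; the
#' pipeline aborts only when every subject fails a stage.  Identical
#' config and seed give a byte-identical report JSON.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @return object of class `pipeline_result`: `report`
#'   ([corridor_report()]), `shapes`, `solutions`, `registration`,
#'   `cohort`, `cohort_stats` and the `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(format(length(log_lines) + 1, width = 4), " ", ...)
    log_lines <<- c(log_lines, msg)
  }

  if (!is.null(config$cohort)) {
    params <- config$cohort
    params$seed <- config$seed
    cohort <- generate_cohort(params)
    note("generated synthetic cohort: n=", nrow(cohort), " seed=", config$seed)
  } else {
    cohort <- read_cohort(config$input$contours, config$input$landmarks)
    note("ingested cohort: n=", nrow(cohort))
  }

  shapes <- shape_metrics(cohort)
  note("shape metrics: ", paste(names(table(shapes$shape_class)),
                                table(shapes$shape_class),
                                sep = "=", collapse = " "))

  d <- config$tunnel_diameter_mm
  solutions <- simulate_tunnels(cohort, d = d, eps = config$epsilon)
  n_bad <- sum(!solutions$feasible)
  note("tunnel simulation: ", nrow(solutions), " solutions, ",
       n_bad, " infeasible")
  if (all(!solutions$feasible)) {
    stop("all subjects infeasible at the requested tunnel diameter",
         call. = FALSE)
  }

  registration <- register_cohort(cohort, reference = config$reference_policy)
  note("registration: mean distance error ",
       sprintf("%.3f", mean(registration$results$mean_distance_error_mm)), " mm")

  report <- corridor_report(solutions)
  note("corridors computed")

  cohort_stats <- NULL
  if (all(c("height_from_plafond_mm", "injured_height_from_plafond_mm",
            "patient_height_cm") %in% names(cohort))) {
    cohort_stats <- list(
      height_paired = paired_t_and_pearson(cohort$injured_height_from_plafond_mm,
                                           cohort$height_from_plafond_mm),
      height_vs_patient = paired_t_and_pearson(cohort$height_from_plafond_mm,
                                               cohort$patient_height_cm)
    )
  }

  res <- structure(
    list(report = report, shapes = shapes, solutions = solutions,
         registration = registration, cohort = cohort,
         cohort_stats = cohort_stats, config = config,
         log = log_lines),
    class = "pipeline_result"
  )

  if (!is.null(config$out_dir)) {
    write_pipeline_artifacts(res, config$out_dir)
  }
  res
}

report_as_list <- function(res) {
  rep <- res$report
  list(
    seed = res$config$seed,
    n_subjects = rep$n_subjects,
    config_hash = rlang::hash(res$config[c("cohort", "input",
                                           "tunnel_diameter_mm",
                                           "reference_policy", "epsilon",
                                           "seed")]),
    corridors = rep$corridors,
    central_alignment = rep$central,
    shape_class_counts = as.list(table(res$shapes$shape_class)),
    aspect_ratio = as.list(summarize_values(res$shapes$aspect_ratio)),
    registration_error_mm = as.list(
      summarize_values(res$registration$results$mean_distance_error_mm))
  )
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(res$cohort, file.path(out_dir, "cohort"))
  readr::write_csv(res$shapes, file.path(out_dir, "shape_metrics.csv"))
  readr::write_csv(res$solutions, file.path(out_dir, "tunnel_solutions.csv"))
  readr::write_csv(res$registration$results, file.path(out_dir, "registration.csv"))
  jsonlite::write_json(report_as_list(res), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(res$log, file.path(out_dir, "run.log"))
  if (res$config$write_figures) {
    try({
      grDevices::pdf(file.path(out_dir, "overlay.pdf"), width = 9, height = 5)
      print(plot_overlay(res$registration, res$solutions))
      grDevices::dev.off()
      grDevices::pdf(file.path(out_dir, "corridors.pdf"), width = 7, height = 4)
      print(ggplot2::autoplot(res$report))
      grDevices::dev.off()
    }, silent = TRUE)
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> n =", x$report$n_subjects, "subjects\n")
  print(x$report)
  invisible(x)
}
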
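test_that("aligning a configuration to itself is the identity", {
  src <- rbind(c(12, 0), c(-11, 0), c(1, 14))
  fit <- procrustes_align(src, src)
  expect_equal(fit$rotation, 0)
  expect_equal(fit$scale, 1)
  expect_equal(unname(fit$translation), c(0, 0))
  expect_equal(fit$mean_distance_error, 0)
  expect_false(fit$reflected)
})

test_that("an exact similarity transform is recovered exactly", {
  src <- rbind(c(12, 0), c(-11, 0), c(1, 14))
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  ref <- sweep(2 * (src %*% t(R)), 2, c(5, -7), `+`)
  fit <- procrustes_align(src, ref)
  expect_equal(fit$rotation, th, tolerance = 1e-12)
  expect_equal(fit$scale, 2, tolerance = 1e-12)
  expect_lt(fit$mean_distance_error, 1e-9)
  # round trip through the inverse restores the source
  back <- apply_transform(invert_transform(fit), fit$fitted)
  expect_lt(max(abs(back - src)), 1e-9)
})

test_that("perturbed fits match an independent least-squares oracle", {
  set.seed(71)
  src <- rbind(c(12, 0), c(-11, 0), c(1, 14))
  for (k in 1:8) {
    ref <- src + matrix(stats::rnorm(6, 0, 0.3), 3)
    fit <- procrustes_align(src, ref)
    oracle <- oracle_procrustes(src, ref)
    expect_lt(abs(fit$mean_distance_error - oracle$mean_distance_error), 1e-9)
    expect_equal(sum(fit$per_landmark_residuals^2), oracle$value,
                 tolerance = 1e-9)
    expect_equal(fit$mean_distance_error, mean(fit$per_landmark_residuals))
  }
})

test_that("collinear landmark configurations are rejected", {
  line <- rbind(c(0, 0), c(5, 5), c(10, 10))
  good <- rbind(c(0, 0), c(10, 0), c(0, 10))
  expect_error(procrustes_align(line, good), "degenerate-configuration")
  expect_error(procrustes_align(good, line), "degenerate-configuration")
})

test_that("registration error is invariant to pre-transforming the source", {
  set.seed(73)
  src <- rbind(c(12, 0), c(-11, 0), c(1, 14))
  ref <- src + matrix(stats::rnorm(6, 0, 0.4), 3)
  base <- procrustes_align(src, ref)$mean_distance_error
  for (k in 1:5) {
    sim <- rand_similarity()
    err <- procrustes_align(apply_sim(sim, src), ref)$mean_distance_error
    expect_equal(err, base, tolerance = 1e-9)
  }
})

test_that("cohorts of similar shapes register with zero error", {
  cs <- tri_section()
  sims <- replicate(5, rand_similarity(), simplify = FALSE)
  sections <- c(list(cs), lapply(sims, function(s) transform_section_raw(cs, s)))
  cohort <- tibble::tibble(
    subject_id = sprintf("c%02d", seq_along(sections)),
    section = sections
  )
  for (pol in list("mean", "first", "c03")) {
    reg <- register_cohort(cohort, reference = pol)
    expect_lt(max(reg$results$mean_distance_error_mm), 1e-8)
  }
})

test_that("signed locations are invariant under section transforms", {
  co <- generate_cohort(cohort_params(n_subjects = 4, seed = 81))
  reg <- register_cohort(co)
  for (i in seq_len(nrow(co))) {
    cs <- co$section[[i]]
    cc0 <- center_center_axis(cs)$value
    cst <- transform_section(cs, reg$transforms[[i]])
    cc1 <- center_center_axis(cst)$value
    expect_equal(cc1, cc0, tolerance = 1e-9)
    expect_equal(aspect_ratio(cst)$aspect_ratio, aspect_ratio(cs)$aspect_ratio,
                 tolerance = 1e-9)
  }
})

test_that("the mean-shape iteration converges and centres the cohort", {
  co <- generate_cohort(cohort_params(n_subjects = 12, seed = 83))
  lms <- lapply(co$section, fibsafe:::as_landmark_matrix)
  ref <- fibsafe:::mean_shape(lms, tol = 1e-8)
  # one more full iteration leaves the mean unchanged
  aligned <- lapply(lms, function(x) procrustes_align(x, ref)$fitted)
  m2 <- Reduce(`+`, aligned) / length(aligned)
  m2 <- scale(m2, scale = FALSE)
  csize <- function(x) sqrt(sum(scale(x, scale = FALSE)^2))
  m2 <- m2 * (mean(vapply(lms, csize, numeric(1))) / csize(m2))
  expect_lt(max(abs(m2 - ref)), 1e-6)
})

test_that("noisy-cohort registration error matches a Monte-Carlo oracle", {
  # identical true shapes, landmark annotation noise only
  p <- cohort_params(n_subjects = 60, aspect_ratio_sd = 0,
                     shape_mixture = c(triangular_convex = 1, triangular = 0,
                                       quadrilateral = 0, irregular = 0),
                     fibula_ap_width_mm = c(mean = 25, sd = 0),
                     fibula_ml_depth_mm = c(mean = 15, sd = 0),
                     landmark_noise_sd_mm = 0.3, anchor_jitter_sd_mm = 0,
                     seed = 85)
  co <- generate_cohort(p)
  reg <- register_cohort(co, reference = "mean")
  got <- mean(reg$results$mean_distance_error_mm)

  # Monte-Carlo with the same annotate-then-project noise process but an
  # independent least-squares solver, aligning to the true shape
  p0 <- cohort_params(n_subjects = 1, aspect_ratio_sd = 0,
                      fibula_ap_width_mm = c(mean = 25, sd = 0),
                      fibula_ml_depth_mm = c(mean = 15, sd = 0),
                      landmark_noise_sd_mm = 0, seed = 86)
  cs0 <- generate_cross_section(p0, "triangular_convex")
  truth <- rbind(cs0$landmarks$anterior_apex, cs0$landmarks$posterior_apex,
                 cs0$landmarks$lateral_apex)
  set.seed(87)
  mc <- replicate(150, {
    noisy <- truth + matrix(stats::rnorm(6, 0, 0.3), 3)
    snapped <- t(apply(noisy, 1, function(q) fibsafe:::poly_snap(cs0$contour, q)$point))
    oracle_procrustes(snapped, truth)$mean_distance_error
  })
  expect_lt(abs(got - mean(mc)) / mean(mc), 0.2)
})
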
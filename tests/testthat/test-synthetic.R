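test_that("parameter validation rejects malformed cohort settings", {
  expect_error(cohort_params(shape_mixture = c(triangular_convex = 1)), "named")
  expect_error(cohort_params(shape_mixture = c(triangular_convex = 0.5,
                                               triangular = 0.1,
                                               quadrilateral = 0.1,
                                               irregular = 0.1)), "sum to 1")
  expect_error(cohort_params(n_subjects = 0), "n_subjects")
  expect_error(cohort_params(aspect_ratio_bounds = c(1.5, 0.7)), "increasing")
  expect_error(cohort_params(aspect_ratio_sd = -1), "deviations")
})

test_that("generation is bit-reproducible under a fixed seed", {
  p <- cohort_params(n_subjects = 6, seed = 123)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  for (i in seq_len(nrow(a))) {
    expect_identical(a$section[[i]]$contour, b$section[[i]]$contour)
    expect_identical(a$section[[i]]$landmarks, b$section[[i]]$landmarks)
  }
  expect_identical(a$patient_height_cm, b$patient_height_cm)
})

test_that("degenerate mixture and forced symmetry behave as declared", {
  p <- cohort_params(n_subjects = 30,
                     shape_mixture = c(triangular_convex = 1, triangular = 0,
                                       quadrilateral = 0, irregular = 0),
                     seed = 9)
  co <- generate_cohort(p)
  expect_true(all(co$shape_class_true == "triangular_convex"))

  # zero spread at ratio 1 gives exactly isosceles lateral edges
  p2 <- cohort_params(n_subjects = 1, aspect_ratio_sd = 0,
                      landmark_noise_sd_mm = 0, seed = 10)
  cs <- generate_cross_section(p2, "triangular")
  pa <- lateral_cortex_paths(cs)
  expect_equal(pa$anterior_length, pa$posterior_length, tolerance = 1e-12)
  expect_equal(aspect_ratio(cs)$aspect_ratio, 1, tolerance = 1e-12)
})

test_that("every generated section satisfies the cross-section invariants", {
  co <- generate_cohort(cohort_params(n_subjects = 40, seed = 77))
  for (i in seq_len(nrow(co))) {
    cs <- co$section[[i]]
    m <- cs$contour
    expect_true(fibsafe:::poly_is_simple(m))
    expect_gt(fibsafe:::poly_signed_area(m), 0)       # counter-clockwise
    # apexes on the contour
    for (nm in c("anterior_apex", "posterior_apex", "lateral_apex")) {
      expect_lt(fibsafe:::poly_snap(m, cs$landmarks[[nm]])$dist, 1e-9)
    }
    # anchors outside and medial (opposite the lateral apex across 7-8)
    for (nm in c("anterior_anchor", "posterior_anchor")) {
      expect_false(fibsafe:::point_in_poly(m, cs$landmarks[[nm]]))
    }
  }
})

test_that("cohort statistics reproduce the configured laws", {
  co <- generate_cohort(cohort_params(n_subjects = 1000, seed = 2024))

  # class counts within 3 sd of the multinomial expectation
  mix <- cohort_params()$shape_mixture
  counts <- table(factor(co$shape_class_true, names(mix)))
  for (cl in names(mix)) {
    expected <- 1000 * mix[[cl]]
    sd3 <- 3 * sqrt(1000 * mix[[cl]] * (1 - mix[[cl]]))
    expect_lt(abs(counts[[cl]] - expected), sd3 + 1e-9)
  }

  # patient-height correlation near the configured 0.42
  r <- stats::cor(co$patient_height_cm, co$height_from_plafond_mm)
  expect_lt(abs(r - 0.42), 0.08)
  r2 <- stats::cor(co$patient_height_cm, co$height_from_tip_mm)
  expect_lt(abs(r2 - 0.42), 0.08)

  # sides roughly 54% left
  expect_lt(abs(mean(co$side == "left") - 0.54), 0.05)
})

test_that("the aspect-ratio law of the dominant class is matched", {
  p <- cohort_params(n_subjects = 1000,
                     shape_mixture = c(triangular_convex = 1, triangular = 0,
                                       quadrilateral = 0, irregular = 0),
                     landmark_noise_sd_mm = 0, seed = 321)
  co <- generate_cohort(p)
  expect_lt(abs(mean(co$aspect_ratio_true) - 1.0), 0.02)
  expect_lt(abs(stats::sd(co$aspect_ratio_true) - 0.2), 0.03)
  expect_true(all(co$aspect_ratio_true >= 0.7 & co$aspect_ratio_true <= 1.5))
})

test_that("noiseless ground truth equals the measured geometry", {
  co <- generate_cohort(cohort_params(n_subjects = 25, landmark_noise_sd_mm = 0,
                                      seed = 55))
  sm <- shape_metrics(co)
  expect_rel_equal(sm$aspect_ratio, co$aspect_ratio_true, 1e-9)
  expect_rel_equal(sm$anterolateral_mm, co$anterolateral_true_mm, 1e-9)
})
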
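# The medial-wedge anchors used here face the apex chord, so both apexes
# are silhouette vertices and the zero-diameter extremes pass exactly
# through them.

test_that("zero-diameter extremes run exactly through the apexes", {
  for (geo in list(tri_section(),
                   tri_section(v7 = c(14, 0), v8 = c(-10, 0), v9 = c(1.5, 13)))) {
    for (who in c("anterior", "posterior")) {
      e0 <- extreme_tunnels(geo, who, d = 0)
      expect_equal(sort(e0$value), c(-100, 100), tolerance = 1e-12)
    }
  }
})

test_that("a symmetric section with an on-axis anchor gives mirrored borders", {
  cs <- tri_section(anchor1 = c(0, -20), anchor4 = c(-10, -20))
  e <- extreme_tunnels(cs, c(0, -20), d = 3.5)
  expect_lt(abs(e$value[1] + e$value[2]), 1e-6)
})

test_that("extreme borders carry a tangency certificate", {
  co <- convex_cohort(3, seed = 23)
  for (i in seq_len(nrow(co))) {
    cs <- co$section[[i]]
    anchor <- as.numeric(cs$landmarks$anterior_anchor)
    e <- extreme_tunnels(cs, anchor, d = 3.5)
    ths <- sort(e$angle_deg) * pi / 180
    mid <- mean(ths)
    for (th in ths) {
      expect_true(strip_within_fibula(cs, tunnel_axis(anchor, c(cos(th), sin(th))), 3.5))
      beyond <- th + sign(th - mid) * 0.1 * pi / 180
      expect_false(strip_within_fibula(
        cs, tunnel_axis(anchor, c(cos(beyond), sin(beyond))), 3.5))
    }
  }
})

test_that("analytic and sweep solvers agree on convex sections", {
  co <- convex_cohort(5, seed = 29)
  for (i in seq_len(nrow(co))) {
    cs <- co$section[[i]]
    for (who in c("anterior", "posterior")) {
      ea <- extreme_tunnels(cs, who, d = 3.5, method = "analytic")
      es <- extreme_tunnels(cs, who, d = 3.5, method = "sweep")
      expect_lt(max(abs(ea$angle_deg - es$angle_deg)), 0.05)
      expect_lt(max(abs(ea$value - es$value)), 0.5)
    }
  }
})

test_that("the ideal axis lies between the extreme borders", {
  co <- generate_cohort(cohort_params(n_subjects = 12, seed = 33))
  sols <- simulate_tunnels(co)
  ang <- sols[sols$orientation != "center_center" & sols$feasible, ]
  expect_true(all(ang$border_anterior_pct >= ang$central_pct - 1e-9))
  expect_true(all(ang$central_pct >= ang$border_posterior_pct - 1e-9))
  # all normalized locations live on the closed [-100, 100] scale
  vals <- c(ang$border_anterior_pct, ang$border_posterior_pct, ang$central_pct)
  expect_true(all(vals >= -100 - 1e-9 & vals <= 100 + 1e-9))
})

test_that("anchor placement drives the sign structure of the exits", {
  co <- generate_cohort(cohort_params(n_subjects = 16, seed = 35))
  sols <- simulate_tunnels(co)
  ant <- sols[sols$orientation == "anterior_angulated" & sols$feasible, ]
  post <- sols[sols$orientation == "posterior_angulated" & sols$feasible, ]
  # anteromedial anchor: tunnels exit on the posterior cortex and vice versa
  expect_gt(mean(ant$central_pct < 0), 0.9)
  expect_gt(mean(post$central_pct > 0), 0.9)
  cc <- sols[sols$orientation == "center_center", ]
  expect_true(all(is.na(cc$border_anterior_pct)))
})

test_that("the feasible interval shrinks with the tunnel diameter", {
  co <- generate_cohort(cohort_params(n_subjects = 8, seed = 39))
  for (i in seq_len(nrow(co))) {
    cs <- co$section[[i]]
    for (who in c("anterior", "posterior")) {
      widths <- vapply(c(0, 1, 2, 3.5, 5), function(d) {
        e <- tryCatch(extreme_tunnels(cs, who, d = d), error = function(x) NULL)
        if (is.null(e)) NA_real_ else diff(range(e$value))
      }, numeric(1))
      w <- widths[!is.na(widths)]
      expect_true(all(diff(w) <= 1e-6))
      # infeasibility only appears beyond feasible diameters
      if (anyNA(widths)) expect_true(all(is.na(widths[which(is.na(widths))[1]:5])))
    }
  }
})

test_that("center-center axis matches a brute-force intersection oracle", {
  co <- generate_cohort(cohort_params(n_subjects = 10, seed = 41))
  for (i in seq_len(nrow(co))) {
    cs <- co$section[[i]]
    cc <- center_center_axis(cs)
    p10 <- cs$landmarks$tibial_center
    p11 <- cs$landmarks$fibular_center
    u <- (p11 - p10) / sqrt(sum((p11 - p10)^2))
    t_all <- oracle_line_crossings(cs$contour, p10, u)
    best <- t_all[which.max(abs(t_all))]
    want <- p10 + best * u
    expect_lt(sqrt(sum((c(cc$x, cc$y) - want)^2)), 1e-6)
  }
  # fully symmetric configuration exits at the lateral apex
  cs <- tri_section(anchor1 = c(10, -20), anchor4 = c(-10, -20))
  expect_lt(abs(center_center_axis(cs)$value), 1e-9)
})

test_that("an oversized drill raises infeasible-tunnel", {
  cs <- tri_section()
  expect_error(extreme_tunnels(cs, "anterior", d = 80), "infeasible-tunnel")
  sol <- solve_subject(cs, d = 80)
  expect_true(all(!sol$feasible[sol$orientation != "center_center"]))
})

test_that("exit location is monotone in the axis angle on the lateral cortex", {
  cs <- tri_section()
  anchor <- c(5, -22)
  e <- extreme_tunnels(cs, anchor, d = 2)
  ths <- seq(min(e$angle_deg) + 0.2, max(e$angle_deg) - 0.2,
             length.out = 40) * pi / 180
  vals <- vapply(ths, function(th) {
    p <- fibsafe:::axis_lateral_exit(cs, tunnel_axis(anchor, c(cos(th), sin(th))))$point
    signed_location(cs, p)$value
  }, numeric(1))
  expect_true(all(diff(vals) < 0) || all(diff(vals) > 0))
})
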
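mk_solutions <- function(ant, post, cc = NULL) {
  rows <- lapply(seq_along(ant), function(i) {
    tibble::tibble(subject_id = sprintf("s%d", i),
                   orientation = "anterior_angulated",
                   border_anterior_pct = ant[[i]][2],
                   border_posterior_pct = ant[[i]][1],
                   central_pct = mean(ant[[i]]), feasible = TRUE)
  })
  sol <- dplyr::bind_rows(rows)
  if (!is.null(post)) {
    sol <- dplyr::bind_rows(sol, dplyr::mutate(sol, orientation = "posterior_angulated"))
  }
  if (!is.null(cc)) {
    sol <- dplyr::bind_rows(sol, tibble::tibble(
      subject_id = sprintf("s%d", seq_along(cc)),
      orientation = "center_center",
      border_anterior_pct = NA_real_, border_posterior_pct = NA_real_,
      central_pct = cc, feasible = TRUE))
  }
  sol
}

test_that("the angulated corridor is the interval intersection", {
  sol <- mk_solutions(list(c(-10, 50), c(-20, 40)), post = NULL)
  cor <- cohort_corridor_angulated(sol, "anterior_angulated")
  expect_equal(c(cor$lower, cor$upper), c(-10, 40))
  expect_false(cor$empty)

  single <- cohort_corridor_angulated(mk_solutions(list(c(-10, 50)), NULL),
                                      "anterior_angulated")
  expect_equal(c(single$lower, single$upper), c(-10, 50))

  disjoint <- cohort_corridor_angulated(
    mk_solutions(list(c(-40, -20), c(0, 30)), NULL), "anterior_angulated")
  expect_true(disjoint$empty)
  expect_gt(disjoint$lower, disjoint$upper)

  expect_error(cohort_corridor_angulated(
    dplyr::mutate(mk_solutions(list(c(-10, 10)), NULL), feasible = FALSE),
    "anterior_angulated"), "no feasible")
})

test_that("the central corridor is the range of center-center locations", {
  sol <- mk_solutions(list(c(-10, 10)), NULL, cc = c(-5, 0, 3))
  cor <- cohort_corridor_central(sol)
  expect_equal(c(cor$lower, cor$upper), c(-5, 3))
  same <- cohort_corridor_central(mk_solutions(list(c(-1, 1)), NULL, cc = rep(2, 4)))
  expect_equal(c(same$lower, same$upper), c(2, 2))
})

test_that("summaries use the sample convention", {
  s <- summarize_values(c(1, 2, 3))
  expect_equal(unlist(s[c("mean", "sd", "min", "max")]),
               c(mean = 2, sd = 1, min = 1, max = 3))
  expect_equal(summarize_values(rep(4, 5))$sd, 0)
  expect_error(summarize_values(7), "at least 2")

  set.seed(91)
  x <- stats::rnorm(1e6, 3, 2)
  s <- summarize_values(x)
  expect_lt(abs(s$mean - 3), 4 * 2 / sqrt(1e6))
  expect_lt(abs(s$sd - 2), 4 * 2 / sqrt(2 * 1e6))
})

test_that("paired tests match direct formula evaluation", {
  x <- c(1, 2, 3); y <- c(2, 4, 5)
  got <- paired_t_and_pearson(x, y)
  d <- x - y
  t_direct <- mean(d) / (stats::sd(d) / sqrt(3))
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p_t_direct <- 2 * stats::pt(-abs(t_direct), df = 2)
  p_r_direct <- 2 * stats::pt(-abs(r_direct * sqrt(1 / (1 - r_direct^2))), df = 1)
  expect_equal(got$t, t_direct)
  expect_equal(got$p_t, p_t_direct)
  expect_equal(got$r, r_direct)
  expect_equal(got$p_r, p_r_direct)

  # degenerate cases are flagged, not fatal
  same <- paired_t_and_pearson(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_t, 1)
  expect_true(same$degenerate)
  lin <- paired_t_and_pearson(x, 2 * x + 1)
  expect_equal(lin$r, 1)
  expect_error(paired_t_and_pearson(1:2, 2:3), "at least 3")
})

test_that("cohort corridors are subsets of every feasible subject interval", {
  co <- generate_cohort(cohort_params(n_subjects = 20, seed = 95))
  sols <- simulate_tunnels(co)
  rep <- corridor_report(sols)
  for (orient in c("anterior_angulated", "posterior_angulated")) {
    cor <- rep$corridors[rep$corridors$orientation == orient, ]
    sub <- sols[sols$orientation == orient & sols$feasible, ]
    expect_true(all(cor$lower >= sub$border_posterior_pct - 1e-9))
    expect_true(all(cor$upper <= sub$border_anterior_pct + 1e-9))
    # direct recomputation
    expect_equal(cor$upper, min(sub$border_anterior_pct))
    expect_equal(cor$lower, max(sub$border_posterior_pct))
  }
  cc <- sols$central_pct[sols$orientation == "center_center"]
  cor <- rep$corridors[rep$corridors$orientation == "center_center", ]
  expect_equal(c(cor$lower, cor$upper), range(cc))
  # order invariance
  rep2 <- corridor_report(sols[sample(nrow(sols)), ])
  expect_equal(rep2$corridors$lower, rep$corridors$lower)
  expect_equal(rep2$corridors$upper, rep$corridors$upper)
})
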
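#' Parameters for a synthetic cross-section cohort
#'
#' Encodes the statistical structure a distal-fibula cross-section cohort
#' is assumed to have at the level of syndesmotic stabilization: a mixture
#' of cross-sectional shape classes dominated by a lateral-based triangle
#' with a medially convex hypotenuse, a lateral-surface aspect ratio of
#' about 1.0 +/- 0.2 (bounded 0.7-1.5), slice heights of ~19 mm above the
#' tibial plafond and ~44 mm above the fibular tip correlated with patient
#' height, and a 3.5 mm drill tunnel.  Scale parameters (anteroposterior
#' width ~25 mm, mediolateral depth ~15 mm, tibial anchor offsets) are
#' plausibility choices and fully configurable.
#'
#' @param n_subjects number of subjects.
#' @param shape_mixture named probabilities over the four shape classes
#'   `triangular_convex`, `triangular`, `quadrilateral`, `irregular`.
#' @param aspect_ratio_mean,aspect_ratio_sd,aspect_ratio_bounds truncated
#'   normal law for the anterolateral / posterolateral edge-length ratio.
#' @param fibula_ap_width_mm,fibula_ml_depth_mm `c(mean, sd)` in mm for the
#'   apex chord 7-8 and the lateral apex height above it.
#' @param sagitta_fraction sagitta of the medial convex arc as a fraction
#'   of the 7-8 chord (triangular_convex class).
#' @param tunnel_diameter_mm drill tunnel diameter (mm).
#' @param landmark_noise_sd_mm isotropic Gaussian jitter applied to the
#'   landmark annotations only (manual-marking noise); apex landmarks are
#'   projected back onto the contour after jittering.
#' @param anterior_anchor_offset_mm,posterior_anchor_offset_mm mean anchor
#'   positions `c(x, y)` in mm relative to the apex-chord midpoint.  The
#'   defaults place the anteromedial anchor ~26 mm anterior / 15 mm medial
#'   (just medial to the anterior tibial tendon) and the posteromedial
#'   anchor ~22 mm posterior / 16 mm medial (just anterior to the
#'   posterior tibial tendon groove), so the angulated axes run obliquely
#'   across the syndesmosis, roughly parallel to their near cortex.
#' @param anchor_jitter_sd_mm per-subject anchor placement spread (mm).
#' @param prop_left proportion of left-sided subjects.
#' @param height_from_plafond_mm,height_from_tip_mm `c(mean, sd)` of the
#'   simulated (uninjured side) slice heights Y and X in mm.
#' @param injured_height_shift_mm `c(mean, sd)` of the additive shift of
#'   the operated-side drill height relative to the simulated height.
#' @param patient_height_cm `c(mean, sd)` of the patient-height covariate.
#' @param height_correlation target Pearson correlation between patient
#'   height and the simulated slice heights.
#' @param contour_step_mm approximate vertex spacing used to densify
#'   straight contour edges.
#' @param irregular_harmonics,irregular_amplitude_range,irregular_smooth_deg
#'   radial Fourier harmonics, per-harmonic relative amplitude range and
#'   corner-smoothing window (degrees) for the irregular class.
#' @param generate_tibia also emit a schematic tibial contour (for
#'   overlay figures).
#' @param seed optional integer seed; generation is bit-reproducible.
#' @return validated list of class `cohort_params`.
#' @export
cohort_params <- function(
    n_subjects = 96,
    shape_mixture = c(triangular_convex = 0.81, triangular = 0.01,
                      quadrilateral = 0.08, irregular = 0.10),
    aspect_ratio_mean = 1.0,
    aspect_ratio_sd = 0.2,
    aspect_ratio_bounds = c(0.7, 1.5),
    fibula_ap_width_mm = c(mean = 25, sd = 2),
    fibula_ml_depth_mm = c(mean = 15, sd = 1.5),
    sagitta_fraction = 0.15,
    tunnel_diameter_mm = 3.5,
    landmark_noise_sd_mm = 0.3,
    anterior_anchor_offset_mm = c(x = 26, y = -15),
    posterior_anchor_offset_mm = c(x = -22, y = -16),
    anchor_jitter_sd_mm = 2,
    prop_left = 0.54,
    height_from_plafond_mm = c(mean = 19, sd = 3),
    height_from_tip_mm = c(mean = 44, sd = 4),
    injured_height_shift_mm = c(mean = 4, sd = 5),
    patient_height_cm = c(mean = 172, sd = 9),
    height_correlation = 0.42,
    contour_step_mm = 1.5,
    irregular_harmonics = 2:3,
    irregular_amplitude_range = c(0.02, 0.07),
    irregular_smooth_deg = 60,
    generate_tibia = TRUE,
    seed = NULL) {
  classes <- c("triangular_convex", "triangular", "quadrilateral", "irregular")
  if (!setequal(names(shape_mixture), classes)) {
    stop("shape_mixture must be named over the four shape classes", call. = FALSE)
  }
  shape_mixture <- shape_mixture[classes]
  if (any(shape_mixture < 0) || abs(sum(shape_mixture) - 1) > 1e-8) {
    stop("shape_mixture must be non-negative and sum to 1", call. = FALSE)
  }
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (aspect_ratio_sd < 0 || landmark_noise_sd_mm < 0 || anchor_jitter_sd_mm < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (diff(aspect_ratio_bounds) <= 0) {
    stop("aspect_ratio_bounds must be an increasing pair", call. = FALSE)
  }
  if (tunnel_diameter_mm < 0) stop("tunnel_diameter_mm must be >= 0", call. = FALSE)
  if (abs(height_correlation) > 1) stop("height_correlation must be in [-1, 1]", call. = FALSE)
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      shape_mixture = shape_mixture,
      aspect_ratio_mean = aspect_ratio_mean,
      aspect_ratio_sd = aspect_ratio_sd,
      aspect_ratio_bounds = aspect_ratio_bounds,
      fibula_ap_width_mm = fibula_ap_width_mm,
      fibula_ml_depth_mm = fibula_ml_depth_mm,
      sagitta_fraction = sagitta_fraction,
      tunnel_diameter_mm = tunnel_diameter_mm,
      landmark_noise_sd_mm = landmark_noise_sd_mm,
      anterior_anchor_offset_mm = anterior_anchor_offset_mm,
      posterior_anchor_offset_mm = posterior_anchor_offset_mm,
      anchor_jitter_sd_mm = anchor_jitter_sd_mm,
      prop_left = prop_left,
      height_from_plafond_mm = height_from_plafond_mm,
      height_from_tip_mm = height_from_tip_mm,
      injured_height_shift_mm = injured_height_shift_mm,
      patient_height_cm = patient_height_cm,
      height_correlation = height_correlation,
      contour_step_mm = contour_step_mm,
      irregular_harmonics = as.integer(irregular_harmonics),
      irregular_amplitude_range = irregular_amplitude_range,
      irregular_smooth_deg = irregular_smooth_deg,
      generate_tibia = isTRUE(generate_tibia),
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "cohort_params"
  )
}

# Truncated normal via inverse-cdf (deterministic under set.seed; sd = 0
# degenerates to the mean).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

trunc_norm_moments <- function(mu, s, lo, hi) {
  a <- (lo - mu) / s; b <- (hi - mu) / s
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + s * (da - db) / Z
  v <- s^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

trunc_cal_cache <- new.env(parent = emptyenv())

# Parameters (mu, s) of the underlying normal such that the *realized*
# truncated law has the requested mean and sd.  Asymmetric truncation
# both shifts the naive mean (by +0.024 for mean 1, sd 0.2, bounds
# 0.7-1.5) and shrinks the sd, so the generating law is solved for the
# targets; if the target sd is not reachable inside the bounds, only the
# mean is matched.
trunc_norm_calibrate <- function(target_mean, target_sd, lo, hi) {
  key <- paste(target_mean, target_sd, lo, hi)
  hit <- trunc_cal_cache[[key]]
  if (!is.null(hit)) return(hit)
  obj <- function(par) {
    mo <- trunc_norm_moments(par[1], exp(par[2]), lo, hi)
    (mo["mean"] - target_mean)^2 + (mo["sd"] - target_sd)^2
  }
  o <- stats::optim(c(target_mean, log(target_sd)), obj,
                    control = list(reltol = 1e-14, maxit = 2000))
  par <- c(mu = o$par[1], s = exp(o$par[2]))
  if (o$value > 1e-8) {
    mu <- stats::uniroot(function(m) {
      trunc_norm_moments(m, target_sd, lo, hi)["mean"] - target_mean
    }, c(lo - 3 * target_sd, hi + 3 * target_sd), tol = 1e-12)$root
    par <- c(mu = mu, s = target_sd)
  }
  trunc_cal_cache[[key]] <- par
  par
}

rtrunc_norm_calibrated <- function(n, target, sd, lo, hi) {
  if (sd == 0) return(rep(target, n))
  par <- trunc_norm_calibrate(target, sd, lo, hi)
  rtrunc_norm(n, par["mu"], par["s"], lo, hi)
}

# Apex placement for a given apex chord width, lateral depth and edge
# ratio r = |9-7| / |9-8|: solve (1-r^2) x^2 - W (1+r^2) x + (1-r^2)(W^2/4 + h^2) = 0
# for the apex abscissa on the Apollonius locus at height h.
apex_for_ratio <- function(W, h, r) {
  if (abs(r - 1) < 1e-12) return(c(0, h))
  a <- 1 - r^2
  b <- -W * (1 + r^2)
  cc <- (1 - r^2) * (W^2 / 4 + h^2)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("infeasible aspect ratio for the given width/depth", call. = FALSE)
  roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
  x <- roots[which.min(abs(roots))]
  c(x, h)
}

densify_edge <- function(a, b, step) {
  len <- vec_norm(b - a)
  k <- max(1L, ceiling(len / step))
  t <- seq(0, 1, length.out = k + 1)
  t <- t[-length(t)]                      # drop b; next edge supplies it
  cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
}

# Medial convex arc from A to B bulging towards negative y; sagitta s.
medial_arc_points <- function(A, B, s, n_min = 24) {
  W <- vec_norm(A - B)
  R <- (W^2 / 4 + s^2) / (2 * s)
  ctr <- c((A[1] + B[1]) / 2, R - s)      # chord assumed on y = 0
  phiA <- atan2(A[2] - ctr[2], A[1] - ctr[1])
  phiB <- atan2(B[2] - ctr[2], B[1] - ctr[1])
  # sweep from B to A through the lowest point (-pi/2)
  if (phiB > phiA) phiB <- phiB - 2 * pi
  n <- max(n_min, 2L)
  phis <- seq(phiB, phiA, length.out = n + 2)
  phis <- phis[-c(1, length(phis))]
  cbind(ctr[1] + R * cos(phis), ctr[2] + R * sin(phis))
}

# Smoothed-triangle radial template for the irregular class: the radial
# function of a triangle about its centroid, circularly smoothed (rounding
# the corners), then modulated by low-frequency Fourier harmonics.  The
# result is star-shaped about the centroid, hence always simple.
irregular_contour <- function(tri, params, n_theta = 180) {
  ctr <- colMeans(tri)
  th_dense <- seq(0, 2 * pi, length.out = 721)[-721]
  r_dense <- vapply(th_dense, function(th) {
    u <- c(cos(th), sin(th))
    cr <- line_poly_crossings(tri, ctr, u)
    max(cr$t[cr$t > 0])
  }, numeric(1))
  w <- round(params$irregular_smooth_deg / (360 / length(th_dense)))
  if (w >= 1) {
    k <- 2L * as.integer(w %/% 2) + 1L
    kern <- rep(1 / k, k)
    r_dense <- stats::filter(c(utils::tail(r_dense, k), r_dense, utils::head(r_dense, k)),
                             kern, circular = FALSE)[(k + 1):(k + length(th_dense))]
    r_dense <- as.numeric(r_dense)
  }
  ks <- params$irregular_harmonics
  amp <- stats::runif(length(ks), params$irregular_amplitude_range[1],
                      params$irregular_amplitude_range[2])
  pha <- stats::runif(length(ks), 0, 2 * pi)
  mod <- rep(1, length(th_dense))
  for (i in seq_along(ks)) mod <- mod + amp[i] * cos(ks[i] * th_dense + pha[i])
  r_dense <- r_dense * mod
  idx <- round(seq(1, length(th_dense), length.out = n_theta + 1))[-(n_theta + 1)]
  th <- th_dense[idx]
  r <- r_dense[idx]
  cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
}

# Schematic tibial contour facing the fibula across the syndesmosis:
# a rounded box spanning both anchors with a shallow concave incisura.
tibia_contour_for <- function(anchor_ant, anchor_post, depth = 22) {
  xr <- range(anchor_ant[1], anchor_post[1])
  ytop <- max(anchor_ant[2], anchor_post[2]) + 12
  x <- seq(xr[1] - 6, xr[2] + 6, length.out = 24)
  mid <- mean(xr)
  topy <- ytop - 3 * exp(-((x - mid) / (diff(xr) / 3))^2)   # incisura dip
  rbind(
    cbind(rev(x), ytop - depth),
    cbind(x, topy)
  )
}

#' Generate one synthetic cross-section
#'
#' Draws a single cross-section of the requested shape class in the
#' canonical right-side frame (+x anterior, +y lateral), with the apex
#' chord on y = 0.  The apex landmarks are placed at the true generating
#' vertices; anchors are placed medially at the configured offsets.
#' Consumes the current RNG stream (use [generate_cohort()] for seeded,
#' reproducible cohorts).
#'
#' @param params a [cohort_params()] object.
#' @param shape_class one of `"triangular_convex"`, `"triangular"`,
#'   `"quadrilateral"`, `"irregular"`.
#' @param subject_id,side identifiers stored on the section.
#' @return a [cross_section()] with a `truth` attribute recording the
#'   generating parameters (true apex coordinates, realized aspect ratio,
#'   drawn aspect ratio, shape class).
#' @export
generate_cross_section <- function(params, shape_class = "triangular_convex",
                                   subject_id = "s1", side = "right") {
  stopifnot(inherits(params, "cohort_params"))
  shape_class <- match.arg(shape_class, names(params$shape_mixture))
  step <- params$contour_step_mm

  W <- rtrunc_norm(1, params$fibula_ap_width_mm["mean"],
                   params$fibula_ap_width_mm["sd"],
                   params$fibula_ap_width_mm["mean"] - 3 * params$fibula_ap_width_mm["sd"],
                   params$fibula_ap_width_mm["mean"] + 3 * params$fibula_ap_width_mm["sd"])
  h <- rtrunc_norm(1, params$fibula_ml_depth_mm["mean"],
                   params$fibula_ml_depth_mm["sd"],
                   params$fibula_ml_depth_mm["mean"] - 3 * params$fibula_ml_depth_mm["sd"],
                   params$fibula_ml_depth_mm["mean"] + 3 * params$fibula_ml_depth_mm["sd"])
  r_drawn <- rtrunc_norm_calibrated(1, params$aspect_ratio_mean,
                                    params$aspect_ratio_sd,
                                    params$aspect_ratio_bounds[1],
                                    params$aspect_ratio_bounds[2])

  A <- c(W / 2, 0)     # anterior apex 7
  B <- c(-W / 2, 0)    # posterior apex 8

  if (shape_class %in% c("triangular", "triangular_convex")) {
    C <- apex_for_ratio(W, h, r_drawn)
    lat_pts <- rbind(densify_edge(A, C, step), densify_edge(C, B, step))
    if (shape_class == "triangular_convex") {
      med <- medial_arc_points(A, B, params$sagitta_fraction * W)
      contour <- rbind(lat_pts, B, med)
    } else {
      contour <- rbind(lat_pts, densify_edge(B, A, step))
    }
    apex7 <- A; apex8 <- B; apex9 <- C
    true_ant <- vec_norm(C - A); true_post <- vec_norm(C - B)
  } else if (shape_class == "quadrilateral") {
    # lateral apex corner La near the top; the fourth corner Lp is an
    # outward kink on the posterior-lateral face, far enough out that all
    # four corners stay dominant under the corner rule
    lam <- stats::runif(1, 0.38, 0.55)
    efrac <- stats::runif(1, 0.20, 0.30)
    corner_lp <- function(La) {
      chord <- B - La
      L <- vec_norm(chord)
      dch <- chord / L
      La + lam * chord + efrac * L * c(dch[2], -dch[1])
    }
    f <- function(xa) {
      La <- c(xa, h)
      Lp <- corner_lp(La)
      vec_norm(La - A) - r_drawn * (vec_norm(Lp - La) + vec_norm(B - Lp))
    }
    lo <- -0.35 * W / 2; hi <- 0.7 * W / 2
    xa <- if (f(lo) <= 0) lo else if (f(hi) >= 0) hi else
      stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    La <- c(xa, h)
    Lp <- corner_lp(La)
    contour <- rbind(densify_edge(A, La, step), densify_edge(La, Lp, step),
                     densify_edge(Lp, B, step), densify_edge(B, A, step))
    apex7 <- A; apex8 <- B; apex9 <- La
    true_ant <- vec_norm(La - A)
    true_post <- vec_norm(Lp - La) + vec_norm(B - Lp)
  } else {
    C <- apex_for_ratio(W, h, r_drawn)
    tri <- poly_ensure_ccw(rbind(A, C, B))
    contour <- irregular_contour(tri, params)
    apex9 <- contour[which.max(contour[, 2]), ]
    apex7 <- contour[which.max(contour[, 1]), ]
    apex8 <- contour[which.min(contour[, 1]), ]
    true_ant <- NA; true_post <- NA   # measured below from the contour
  }
  contour <- poly_ensure_ccw(contour)

  med_mid <- (apex7 + apex8) / 2
  jit <- function() stats::rnorm(2, 0, params$anchor_jitter_sd_mm)
  anchor1 <- med_mid + params$anterior_anchor_offset_mm + jit()
  anchor4 <- med_mid + params$posterior_anchor_offset_mm + jit()

  lm_true <- list(anterior_anchor = anchor1, posterior_anchor = anchor4,
                  anterior_apex = apex7, posterior_apex = apex8,
                  lateral_apex = apex9)

  # manual-marking noise: jitter annotations, project apexes back on bone
  lm_obs <- lm_true
  if (params$landmark_noise_sd_mm > 0) {
    lm_obs <- lapply(lm_true, function(p) p + stats::rnorm(2, 0, params$landmark_noise_sd_mm))
    for (nm in c("anterior_apex", "posterior_apex", "lateral_apex")) {
      lm_obs[[nm]] <- poly_snap(contour, lm_obs[[nm]])$point
    }
  }

  tib <- if (params$generate_tibia) tibia_contour_for(anchor1, anchor4)

  cs <- cross_section(
    fibula_contour = contour,
    landmarks = lm_obs,
    subject_id = subject_id,
    side = side,
    tibia_contour = tib,
    shape_class = shape_class
  )

  if (shape_class == "irregular") {
    # truth from the realized contour paths between the true apexes
    cs_true <- cross_section(contour, lm_true, subject_id = subject_id)
    true_ant <- cs_true$paths$anterior_length
    true_post <- cs_true$paths$posterior_length
  }

  attr(cs, "truth") <- list(
    shape_class = shape_class,
    aspect_ratio = true_ant / true_post,
    aspect_ratio_drawn = r_drawn,
    anterolateral_mm = true_ant,
    posterolateral_mm = true_post,
    ap_width_mm = W,
    ml_depth_mm = h,
    landmarks = lm_true
  )
  cs
}

#' Generate a synthetic cross-section cohort
#'
#' Draws `params$n_subjects` cross-sections with shape classes from the
#' configured mixture, sides assigned with probability `prop_left`, slice
#' heights correlated with a synthetic patient-height covariate, and an
#' operated-side drill height offset from the simulated height.  The
#' per-subject generating parameters are recorded as plain columns so that
#' recovery can be tested against ground truth.
#'
#' @param params a [cohort_params()].
#' @return tibble with one row per subject: identifiers, ground-truth
#'   columns (`shape_class_true`, `aspect_ratio_true`, ...), covariates
#'   (`patient_height_cm`, `height_from_plafond_mm`, `height_from_tip_mm`,
#'   `injured_height_from_plafond_mm`, `injured_height_from_tip_mm`),
#'   `tunnel_diameter_mm`, and the `section` list-column of
#'   [cross_section()] objects.  The params are attached as attribute
#'   `cohort_params`.
#' @examples
#' cohort <- generate_cohort(cohort_params(n_subjects = 5, seed = 1))
#' shape_metrics(cohort)
#' simulate_tunnels(cohort)
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  sides <- ifelse(stats::runif(n) < params$prop_left, "left", "right")
  classes <- sample(names(params$shape_mixture), n, replace = TRUE,
                    prob = params$shape_mixture)

  hgt <- stats::rnorm(n, params$patient_height_cm["mean"], params$patient_height_cm["sd"])
  z <- (hgt - params$patient_height_cm["mean"]) / params$patient_height_cm["sd"]
  rho <- params$height_correlation
  mk_height <- function(mu, sd) {
    mu + sd * (rho * z + sqrt(1 - rho^2) * stats::rnorm(n))
  }
  yc <- mk_height(params$height_from_plafond_mm["mean"], params$height_from_plafond_mm["sd"])
  xc <- mk_height(params$height_from_tip_mm["mean"], params$height_from_tip_mm["sd"])
  yi <- yc + stats::rnorm(n, params$injured_height_shift_mm["mean"],
                          params$injured_height_shift_mm["sd"])
  xi <- xc + stats::rnorm(n, params$injured_height_shift_mm["mean"],
                          params$injured_height_shift_mm["sd"])

  sections <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- generate_cross_section(params, classes[i], subject_id = ids[i],
                                 side = sides[i])
    cs$height_from_plafond <- yc[i]
    cs$height_from_fibular_tip <- xc[i]
    sections[[i]] <- cs
    truths[[i]] <- attr(cs, "truth")
  }

  out <- tibble::tibble(
    subject_id = ids,
    side = sides,
    shape_class_true = classes,
    aspect_ratio_true = vapply(truths, `[[`, numeric(1), "aspect_ratio"),
    aspect_ratio_drawn = vapply(truths, `[[`, numeric(1), "aspect_ratio_drawn"),
    anterolateral_true_mm = vapply(truths, `[[`, numeric(1), "anterolateral_mm"),
    posterolateral_true_mm = vapply(truths, `[[`, numeric(1), "posterolateral_mm"),
    ap_width_mm = vapply(truths, `[[`, numeric(1), "ap_width_mm"),
    ml_depth_mm = vapply(truths, `[[`, numeric(1), "ml_depth_mm"),
    patient_height_cm = hgt,
    height_from_plafond_mm = yc,
    height_from_tip_mm = xc,
    injured_height_from_plafond_mm = yi,
    injured_height_from_tip_mm = xi,
    tunnel_diameter_mm = params$tunnel_diameter_mm,
    section = sections
  )
  attr(out, "cohort_params") <- params
  out
}
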
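#' Parametric curve specification
#'
#' Describes one of four 3D curve families used to build vascular phantoms
#' with known geometry: `straight` (a line of given `length`), `helix`
#' (circular helix with `radius`, `pitch` per turn and `turns`), `sinusoid`
#' (planar sine of `amplitude` and `wavelength` over `span`), and `siphon`
#' (a C1-continuous chain of circular arcs given as `arcs`, a data frame
#' with columns `radius` (mm) and `angle_deg`, optionally torsioned out of
#' plane by `torsion_deg` at each junction — a stand-in for the C-shaped
#' carotid siphon). All lengths are in mm.
#'
#' @param kind One of `"straight"`, `"helix"`, `"sinusoid"`, `"siphon"`.
#' @param ... Kind-specific parameters, see Details.
#' @param sample_count Number of points sampled along the curve (>= 3).
#' @param start Starting point in mm (default origin).
#' @return An object of class `curve_spec`.
#' @examples
#' sp <- curve_spec("helix", radius = 10, pitch = 20, turns = 1,
#'                  sample_count = 1000)
#' p <- make_parametric_curve(sp)
#' curve_length(p)  # close to sqrt((2*pi*10)^2 + 20^2)
#' @export
curve_spec <- function(kind = c("straight", "helix", "sinusoid", "siphon"),
                       ..., sample_count = 1000L, start = c(0, 0, 0)) {
  kind <- match.arg(kind)
  pars <- list(...)
  if (!is.numeric(sample_count) || sample_count < 3)
    vm_stop("sample_count must be >= 3")
  need <- function(name, positive = TRUE) {
    v <- pars[[name]]
    if (is.null(v)) vm_stop("missing parameter '", name, "' for kind ", kind)
    if (positive && any(v <= 0))
      vm_stop("parameter '", name, "' must be positive")
    v
  }
  pars <- switch(kind,
    straight = list(length = need("length")),
    helix = list(radius = need("radius"), pitch = need("pitch"),
                 turns = need("turns")),
    sinusoid = list(amplitude = {
                      a <- pars[["amplitude"]]
                      if (is.null(a)) vm_stop("missing parameter 'amplitude' for kind sinusoid")
                      if (a < 0) vm_stop("parameter 'amplitude' must be nonnegative")
                      a
                    },
                    wavelength = need("wavelength"), span = need("span")),
    siphon = {
      arcs <- pars[["arcs"]]
      if (is.null(arcs) || !is.data.frame(arcs) ||
          !all(c("radius", "angle_deg") %in% names(arcs)))
        vm_stop("siphon needs 'arcs': a data.frame with radius and angle_deg")
      if (any(arcs$radius <= 0)) vm_stop("parameter 'radius' must be positive")
      if (any(arcs$angle_deg <= 0)) vm_stop("parameter 'angle_deg' must be positive")
      list(arcs = arcs, torsion_deg = pars[["torsion_deg"]] %||% 0)
    })
  structure(list(kind = kind, pars = pars,
                 sample_count = as.integer(sample_count),
                 start = .check_num3(start, "start")),
            class = "curve_spec")
}

# rotate vector v about unit axis a by angle (radians), Rodrigues
.rotate_about <- function(v, a, ang) {
  v * cos(ang) + pracma_cross(a, v) * sin(ang) + a * sum(a * v) * (1 - cos(ang))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.siphon_points <- function(pars, n, start) {
  arcs <- pars$arcs
  tors <- pars$torsion_deg * pi / 180
  lens <- arcs$radius * arcs$angle_deg * pi / 180
  total <- sum(lens)
  s_break <- c(0, cumsum(lens))
  svals <- seq(0, total, length.out = n)
  p <- start
  tang <- c(1, 0, 0)
  norm <- c(0, 1, 0)
  out <- matrix(NA_real_, n, 3)
  k <- 1L
  for (a in seq_len(nrow(arcs))) {
    r <- arcs$radius[a]
    while (k <= n && svals[k] <= s_break[a + 1] + 1e-9) {
      s <- svals[k] - s_break[a]
      th <- s / r
      out[k, ] <- p + r * (sin(th) * tang + (1 - cos(th)) * norm)
      k <- k + 1L
    }
    phi <- arcs$angle_deg[a] * pi / 180
    p <- p + r * (sin(phi) * tang + (1 - cos(phi)) * norm)
    t_new <- cos(phi) * tang + sin(phi) * norm
    n_new <- -sin(phi) * tang + cos(phi) * norm
    tang <- t_new
    norm <- n_new
    if (tors != 0) norm <- .rotate_about(norm, tang / sqrt(sum(tang^2)), tors)
  }
  out
}

#' Sample a parametric curve as a 3D polyline
#'
#' Points are sampled at uniform parameter values, which is uniform arc
#' length for straight, helix and siphon curves; use
#' [smooth_resample()]-style resampling (or dense sampling) where uniform
#' spacing matters for the sinusoid.
#'
#' @param spec A [curve_spec()].
#' @param sample_count Optional override of the spec's sample count.
#' @return An n x 3 matrix of points in mm.
#' @export
make_parametric_curve <- function(spec, sample_count = NULL) {
  if (!inherits(spec, "curve_spec")) vm_stop("spec must be a curve_spec")
  n <- as.integer(sample_count %||% spec$sample_count)
  if (n < 3) vm_stop("sample_count must be >= 3")
  pars <- spec$pars
  st <- spec$start
  pts <- switch(spec$kind,
    straight = {
      t <- seq(0, pars$length, length.out = n)
      cbind(st[1] + t, st[2], st[3])
    },
    helix = {
      th <- seq(0, 2 * pi * pars$turns, length.out = n)
      cc <- pars$pitch / (2 * pi)
      cbind(st[1] + pars$radius * cos(th) - pars$radius,
            st[2] + pars$radius * sin(th),
            st[3] + cc * th)
    },
    sinusoid = {
      t <- seq(0, pars$span, length.out = n)
      cbind(st[1] + t,
            st[2] + pars$amplitude * sin(2 * pi * t / pars$wavelength),
            st[3])
    },
    siphon = .siphon_points(pars, n, st))
  unname(pts)
}

# ---------------------------------------------------------------------------
# Independent dense-polyline tortuosity oracle. This deliberately re-derives
# every descriptor with its own arithmetic (direction-vector turning angles
# rather than interior angles, explicit accumulation loops) so agreement with
# the morphometry module is a genuine cross-check.
# ---------------------------------------------------------------------------

#' Dense-polyline tortuosity oracle
#'
#' Computes the six tortuosity descriptors directly from a (densely sampled)
#' polyline with an implementation independent of the morphometry functions.
#' Used as ground truth for phantom curves.
#'
#' @param polyline n x 3 matrix of points in mm.
#' @param pad_definition As in [product_of_angle_distance()].
#' @return Named vector with elements `lc`, `l`, `RL`, `SOAM`, `PAD`, `TI`.
#' @export
oracle_tortuosity <- function(polyline,
                              pad_definition = c("soam_over_rl",
                                                 "soam_times_rl")) {
  pad_definition <- match.arg(pad_definition)
  p <- as.matrix(polyline)
  n <- nrow(p)
  d <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
  seg <- sqrt(d[, 1]^2 + d[, 2]^2 + d[, 3]^2)
  lc <- sum(seg)
  l <- sqrt(sum((p[n, ] - p[1, ])^2))
  u <- d[-(n - 1), , drop = FALSE]
  v <- d[-1, , drop = FALSE]
  dot <- u[, 1] * v[, 1] + u[, 2] * v[, 2] + u[, 3] * v[, 3]
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  turn <- atan2(sqrt(cx^2 + cy^2 + cz^2), dot)  # radians turned per vertex
  soam_val <- sum(turn) * 180 / pi / lc
  chord <- sqrt((p[3:n, 1] - p[1:(n - 2), 1])^2 +
                  (p[3:n, 2] - p[1:(n - 2), 2])^2 +
                  (p[3:n, 3] - p[1:(n - 2), 3])^2)
  ti <- mean((seg[-(n - 1)] + seg[-1]) / chord)
  rl <- l / lc
  pad <- if (pad_definition == "soam_over_rl") soam_val / rl else
    soam_val * rl
  c(lc = lc, l = l, RL = rl, SOAM = soam_val, PAD = pad, TI = ti)
}

#' Closed-form / quadrature tortuosity of a parametric curve
#'
#' Curve and Euclidean lengths come from closed forms (straight, helix) or
#' adaptive quadrature (sinusoid); the angle-based descriptors come from the
#' independent dense-polyline oracle evaluated at `oracle_points` samples.
#' Siphon curves have no closed form here; call [oracle_tortuosity()] on a
#' dense [make_parametric_curve()] sampling explicitly.
#'
#' @param spec A [curve_spec()] of kind straight, helix or sinusoid.
#' @param oracle_points Dense sample count for the oracle (default 1e5).
#' @inheritParams oracle_tortuosity
#' @return Named vector with elements `lc`, `l`, `RL`, `SOAM`, `PAD`, `TI`.
#' @export
analytic_tortuosity <- function(spec, oracle_points = 1e5,
                                pad_definition = c("soam_over_rl",
                                                   "soam_times_rl")) {
  pad_definition <- match.arg(pad_definition)
  if (!inherits(spec, "curve_spec")) vm_stop("spec must be a curve_spec")
  if (spec$kind == "siphon")
    vm_stop("siphon has no closed form; use oracle_tortuosity() on a dense sampling")
  pars <- spec$pars
  if (spec$kind == "straight") {
    return(c(lc = pars$length, l = pars$length, RL = 1, SOAM = 0,
             PAD = 0, TI = 1))
  }
  if (spec$kind == "helix") {
    lc <- pars$turns * sqrt((2 * pi * pars$radius)^2 + pars$pitch^2)
    the <- 2 * pi * pars$turns
    cc <- pars$pitch / (2 * pi)
    endd <- c(pars$radius * cos(the) - pars$radius,
              pars$radius * sin(the), cc * the)
    l <- sqrt(sum(endd^2))
  } else {  # sinusoid
    k <- 2 * pi / pars$wavelength
    lc <- integrate(function(t) sqrt(1 + (pars$amplitude * k * cos(k * t))^2),
                    0, pars$span, rel.tol = 1e-10)$value
    l <- sqrt(pars$span^2 + (pars$amplitude * sin(k * pars$span))^2)
  }
  dense <- oracle_tortuosity(
    make_parametric_curve(spec, sample_count = as.integer(oracle_points)),
    pad_definition = pad_definition)
  rl <- l / lc
  pad <- if (pad_definition == "soam_over_rl") dense[["SOAM"]] / rl else
    dense[["SOAM"]] * rl
  c(lc = lc, l = l, RL = rl, SOAM = dense[["SOAM"]], PAD = pad,
    TI = dense[["TI"]])
}

#' Voxel grid specification
#'
#' @param shape Grid size in voxels, length 3. Default 128^3: desk-scale but
#'   finer than typical TOF-MRA matrices at the chosen spacing.
#' @param spacing Voxel size mm/axis (default 0.5 mm isotropic).
#' @param origin World position of voxel (0,0,0) in mm.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape = c(128, 128, 128), spacing = c(0.5, 0.5, 0.5),
                      origin = c(0, 0, 0)) {
  if (!is.numeric(shape) || length(shape) != 3L || any(shape < 2))
    vm_stop("shape must be 3 positive integers")
  structure(list(shape = as.integer(shape),
                 spacing = .check_num3(spacing, "spacing", positive = TRUE),
                 origin = .check_num3(origin, "origin")),
            class = "grid_spec")
}

#' Rasterize a tube phantom into a volume
#'
#' A voxel belongs to the true mask iff its center lies within the radius
#' (linearly interpolated along arc length between the per-point values) of
#' the polyline. The intensity volume is two-valued plus optional additive
#' Gaussian noise, clipped at 0 — enough to exercise threshold-based region
#' growing, with no MR physics modeled.
#'
#' @param polyline n x 3 matrix of centerline points in mm.
#' @param radius_profile Radius in mm: a scalar or one value per point.
#' @param grid A [grid_spec()].
#' @param vessel_intensity,background_intensity Intensities of tube and
#'   background (vessel must be brighter).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed RNG seed for the noise (same seed, same volume).
#' @return List with elements `volume` (numeric [vol3d()]) and `mask`
#'   (logical [vol3d()]).
#' @export
rasterize_tube <- function(polyline, radius_profile, grid,
                           vessel_intensity = 200, background_intensity = 40,
                           noise_sd = 0, seed = 1L) {
  p <- .as_polyline(polyline)
  if (!inherits(grid, "grid_spec")) vm_stop("grid must be a grid_spec")
  if (vessel_intensity <= background_intensity)
    vm_stop("vessel_intensity must exceed background_intensity")
  r <- rep_len(as.numeric(radius_profile), nrow(p))
  if (any(r <= 0)) vm_stop("radius_profile must be positive")
  margin <- 2 * max(r)
  lo <- grid$origin + margin
  hi <- grid$origin + (grid$shape - 1) * grid$spacing - margin
  bad <- which(apply(p, 1, function(q) any(q < lo) || any(q > hi)))
  if (length(bad))
    vm_stop("polyline point ", bad[1], " (",
            paste(format(p[bad[1], ], digits = 4), collapse = ", "),
            ") violates the 2x max-radius margin of the grid")
  m <- array(.rasterize_mask_cpp(p, r, grid$shape, grid$spacing,
                                 grid$origin), grid$shape)
  vals <- array(background_intensity, grid$shape)
  vals[m] <- vessel_intensity
  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed),
                              rnorm(prod(grid$shape), 0, noise_sd))
    vals <- vals + array(noise, grid$shape)
    vals[vals < 0] <- 0
  }
  list(volume = vol3d(vals, grid$spacing, grid$origin),
       mask = vol3d(m, grid$spacing, grid$origin))
}

# ---------------------------------------------------------------------------
# tabular cohort simulator
# ---------------------------------------------------------------------------

#' Default per-feature sampling distributions
#'
#' Fixture values on the scale of adult intracranial arteries (ICA curve
#' length tens of mm, diameters 2-5 mm, RL well below 1 for the tortuous
#' ICA and near 1 for the straighter basilar artery). These are stated
#' fixtures, not estimates of any cohort.
#'
#' @return Data frame with columns `name`, `mean`, `sd`, `min`, `max`.
#' @export
default_feature_distributions <- function() {
  ica <- data.frame(
    suffix = vm_feature_suffixes(),
    mean = c(72, 38, 0.55, 6, 11, 1.05, 3.4, 2.2, 4.6, 0.5, 3.0, 3.4, 3.8),
    sd = c(12, 8, 0.08, 1.5, 3, 0.02, 0.5, 0.4, 0.6, 0.15, 0.45, 0.5, 0.55),
    min = c(5, 5, 0.05, 0, 0, 1, 0.5, 0.3, 0.5, 0, 0.4, 0.5, 0.5),
    max = c(Inf, Inf, 1, Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf))
  ba <- data.frame(
    suffix = vm_feature_suffixes(),
    mean = c(28, 25, 0.9, 3, 3.5, 1.02, 3.2, 2.4, 4.0, 0.4, 2.9, 3.2, 3.5),
    sd = c(5, 4, 0.05, 1, 1.2, 0.01, 0.4, 0.35, 0.5, 0.12, 0.38, 0.4, 0.45),
    min = c(5, 5, 0.05, 0, 0, 1, 0.5, 0.3, 0.5, 0, 0.4, 0.5, 0.5),
    max = c(Inf, Inf, 1, Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf))
  blocks <- list(`R-ICA` = ica, `L-ICA` = ica, BA = ba)
  out <- do.call(rbind, lapply(names(blocks), function(lb) {
    b <- blocks[[lb]]
    data.frame(name = paste0(lb, "_", b$suffix), mean = b$mean, sd = b$sd,
               min = b$min, max = b$max)
  }))
  rownames(out) <- NULL
  out
}

#' Tabular cohort specification
#'
#' Describes a synthetic cohort in which age is an affine function of the 39
#' features plus Gaussian noise: `age = intercept + sum(coef * feature) +
#' N(0, noise_sd)`. Defaults target a cohort age distribution of mean 49.3
#' and SD about 16.5 years, driven mainly by the mean-diameter features.
#'
#' @param n_subjects Number of subjects (>= 8, so four folds of >= 2 exist).
#' @param coefficients Named numeric vector of linear coefficients over
#'   [vm_feature_names()] (years per feature unit).
#' @param intercept Years; if `NULL`, chosen so the expected mean age is
#'   49.3 years under the default feature means.
#' @param noise_sd SD of the additive age noise, years (>= 0).
#' @param distributions Per-feature sampling distributions, as
#'   [default_feature_distributions()].
#' @param seed RNG seed; the cohort is a pure function of spec + seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 171,
                        coefficients = c("R-ICA_diam_mean" = 18,
                                         "L-ICA_diam_mean" = 12,
                                         "BA_diam_mean" = 8,
                                         "R-ICA_lc" = 0.15),
                        intercept = NULL, noise_sd = 11,
                        distributions = default_feature_distributions(),
                        seed = 1L) {
  if (n_subjects < 8) vm_stop("n_subjects must be >= 8")
  if (noise_sd < 0) vm_stop("noise_sd must be >= 0")
  unknown <- setdiff(names(coefficients), vm_feature_names())
  if (length(unknown))
    vm_stop("unknown feature name(s) in coefficients: ",
            paste(unknown, collapse = ", "))
  if (is.null(intercept)) {
    mu <- setNames(distributions$mean, distributions$name)
    intercept <- 49.3 - sum(coefficients * mu[names(coefficients)])
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 coefficients = coefficients, intercept = intercept,
                 noise_sd = noise_sd, distributions = distributions,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a tabular cohort
#'
#' Features are drawn independently per subject from the spec's truncated
#' normal distributions; age is the spec's affine function plus noise.
#'
#' @param spec A [cohort_spec()].
#' @return A feature table (data frame with `subject_id`, `age` and the 39
#'   feature columns) with attribute `truth` recording the generating
#'   coefficients, intercept and noise SD.
#' @export
simulate_tabular_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) vm_stop("spec must be a cohort_spec")
  d <- spec$distributions
  n <- spec$n_subjects
  out <- withr::with_seed(spec$seed, {
    X <- matrix(NA_real_, n, nrow(d))
    for (j in seq_len(nrow(d)))
      X[, j] <- pmin(pmax(rnorm(n, d$mean[j], d$sd[j]), d$min[j]), d$max[j])
    colnames(X) <- d$name
    beta <- setNames(numeric(nrow(d)), d$name)
    beta[names(spec$coefficients)] <- spec$coefficients
    age <- spec$intercept + as.vector(X %*% beta) +
      rnorm(n, 0, spec$noise_sd)
    list(X = X, age = age)
  })
  tab <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    age = out$age, check.names = FALSE)
  tab <- cbind(tab, as.data.frame(out$X, check.names = FALSE))
  attr(tab, "truth") <- list(coefficients = spec$coefficients,
                             intercept = spec$intercept,
                             noise_sd = spec$noise_sd)
  class(tab) <- c("feature_table", "data.frame")
  tab
}

# ---------------------------------------------------------------------------
# volumetric subject simulator
# ---------------------------------------------------------------------------

.min_polyline_distance <- function(p1, p2) {
  # min pairwise point distance on dense samplings; adequate for the
  # separation check with sub-mm sampling
  best <- Inf
  for (i in seq_len(nrow(p1))) {
    d2 <- (p2[, 1] - p1[i, 1])^2 + (p2[, 2] - p1[i, 2])^2 +
      (p2[, 3] - p1[i, 3])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Simulate one volumetric phantom subject
#'
#' Builds a volume containing three non-overlapping bright tubes emulating
#' the right and left internal carotid arteries (helical, tortuous) and the
#' basilar artery (gently sinusoidal, near-straight), on a darker noisy
#' background. Tube radii increase linearly with the assigned age at
#' `diameter_slope` mm/year around the reference age of 49.3 years, so
#' extracted mean diameters are monotone in age by construction.
#'
#' @param age Assigned age in years; drives the tube radii.
#' @param grid A [grid_spec()]. The default 64 x 64 x 48 at 0.5 mm keeps a
#'   subject under a second of processing; geometry scales with the grid's
#'   physical extent only in so far as the built-in curve layout fits it, so
#'   supply grids of at least 32 x 32 x 24 mm extent.
#' @param seed RNG seed for the intensity noise.
#' @param noise_sd Intensity noise SD (default 10; the vessel/background gap
#'   is 160).
#' @param diameter_slope Radius change in mm per year of age (default 0.008).
#' @param vessel_intensity,background_intensity Tube and background
#'   intensities.
#' @param curve_kind `"helix"` (default) or `"straight"` ICA-like segments.
#' @return List with `volume`, combined `mask`, per-segment `segments`
#'   (label, 0-based voxel `endpoints`, and `ground_truth` holding the dense
#'   polyline, radius profile and true 13 features), `age` and `seed`.
#' @export
simulate_volumetric_subject <- function(age,
                                        grid = grid_spec(c(64, 64, 48),
                                                         c(0.5, 0.5, 0.5)),
                                        seed = 1L, noise_sd = 10,
                                        diameter_slope = 0.008,
                                        vessel_intensity = 200,
                                        background_intensity = 40,
                                        curve_kind = c("helix", "straight")) {
  curve_kind <- match.arg(curve_kind)
  if (!inherits(grid, "grid_spec")) vm_stop("grid must be a grid_spec")
  ext <- (grid$shape - 1) * grid$spacing
  if (any(ext < c(31, 31, 23)))
    vm_stop("grid extent too small for the three-segment layout")
  o <- grid$origin
  rad <- function(base) base + diameter_slope * (age - 49.3)
  radii <- c(`R-ICA` = rad(1.8), `L-ICA` = rad(1.75), BA = rad(1.5))

  th <- seq(0, 2 * pi * 1.4, length.out = 800)
  cc <- 9 / (2 * pi)
  if (curve_kind == "helix") {
    p_rica <- cbind(o[1] + 7.6 + 2.3 * cos(th), o[2] + 16 + 2.3 * sin(th),
                    o[3] + 5.2 + cc * th)
    p_lica <- cbind(o[1] + 23.9 + 2.3 * cos(th), o[2] + 16 - 2.3 * sin(th),
                    o[3] + 5.2 + cc * th)
  } else {
    tt <- seq(0, 12.6, length.out = 800)
    p_rica <- cbind(o[1] + 8.5, o[2] + 16, o[3] + 5.2 + tt)
    p_lica <- cbind(o[1] + 23.5, o[2] + 16, o[3] + 5.2 + tt)
  }
  tt <- seq(0, 14, length.out = 800)
  p_ba <- cbind(o[1] + 15.75 + 0.7 * sin(2 * pi * tt / 12), o[2] + 16,
                o[3] + 4.8 + tt)
  polys <- list(`R-ICA` = p_rica, `L-ICA` = p_lica, BA = p_ba)

  labs <- names(polys)
  for (i in 1:2) for (j in (i + 1):3) {
    gap <- .min_polyline_distance(polys[[i]], polys[[j]])
    if (gap < radii[i] + radii[j] + 0.25)
      vm_stop("tube overlap between ", labs[i], " and ", labs[j])
  }

  masks <- lapply(labs, function(lb) {
    rasterize_tube(polys[[lb]], radii[[lb]], grid,
                   vessel_intensity, background_intensity,
                   noise_sd = 0)$mask
  })
  names(masks) <- labs
  comb <- masks[[1]]$values | masks[[2]]$values | masks[[3]]$values
  vals <- array(background_intensity, grid$shape)
  vals[comb] <- vessel_intensity
  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed),
                              rnorm(prod(grid$shape), 0, noise_sd))
    vals <- vals + array(noise, grid$shape)
    vals[vals < 0] <- 0
  }
  geom <- list(spacing = grid$spacing, origin = grid$origin)
  segments <- lapply(labs, function(lb) {
    p <- polys[[lb]]
    tort <- oracle_tortuosity(p)
    dstats <- diameter_stats(rep(2 * radii[[lb]], 5L))
    truth <- c(tort, dstats)
    names(truth) <- paste0(lb, "_", vm_feature_suffixes())
    ep <- mm_to_voxel(p[c(1, nrow(p)), ], geom)
    list(label = lb,
         endpoints = ep,
         ground_truth = list(polyline = p,
                             radius_profile = rep(radii[[lb]], nrow(p)),
                             true_features = truth))
  })
  names(segments) <- labs
  list(volume = vol3d(vals, grid$spacing, grid$origin),
       mask = vol3d(comb, grid$spacing, grid$origin),
       segment_masks = masks,
       segments = segments, age = age, seed = as.integer(seed))
}
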
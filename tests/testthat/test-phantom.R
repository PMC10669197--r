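pracma_cross_test <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

test_that("parametric curves match their stated geometry", {
  # straight: collinear points spanning the requested length
  p <- make_parametric_curve(curve_spec("straight", length = 60,
                                        sample_count = 121))
  expect_equal(nrow(p), 121)
  expect_equal(euclidean_length(p), 60)
  d <- diff(p)
  crosses <- vapply(seq_len(nrow(d) - 1), function(i)
    sqrt(sum(pracma_cross_test(d[i, ], d[i + 1, ])^2)), numeric(1))
  expect_true(all(crosses < 1e-12))

  # helix: chordal length converges to the closed form
  hx <- curve_spec("helix", radius = 10, pitch = 20, turns = 1)
  truth <- sqrt((2 * pi * 10)^2 + 20^2)
  lc1 <- curve_length(make_parametric_curve(hx, sample_count = 4000))
  lc2 <- curve_length(make_parametric_curve(hx, sample_count = 8000))
  expect_lt(abs(lc1 - truth) / truth, 1e-3)
  expect_lt(abs(lc2 - truth), abs(lc1 - truth))  # doubling improves

  # zero-amplitude sinusoid degenerates to a straight line
  s0 <- make_parametric_curve(curve_spec("sinusoid", amplitude = 0,
                                         wavelength = 10, span = 25,
                                         sample_count = 50))
  st <- make_parametric_curve(curve_spec("straight", length = 25,
                                         sample_count = 50))
  expect_equal(s0, st)
})

test_that("curve specs reject bad parameters by name", {
  expect_error(curve_spec("helix", radius = -1, pitch = 5, turns = 1),
               "radius")
  expect_error(curve_spec("helix", pitch = 5, turns = 1), "radius")
  expect_error(curve_spec("sinusoid", amplitude = -2, wavelength = 5,
                          span = 10), "amplitude")
  expect_error(curve_spec("nonsense", length = 5))
  expect_error(curve_spec("straight", length = 10, sample_count = 2),
               "sample_count")
})

test_that("analytic tortuosity matches closed forms and definitions", {
  at <- analytic_tortuosity(curve_spec("straight", length = 40))
  expect_equal(at[["RL"]], 1)
  expect_equal(at[["SOAM"]], 0)
  expect_equal(at[["TI"]], 1)

  hx <- curve_spec("helix", radius = 10, pitch = 20, turns = 1)
  at <- analytic_tortuosity(hx, oracle_points = 2e5)
  expect_equal(at[["RL"]], 20 / sqrt((2 * pi * 10)^2 + 20^2),
               tolerance = 1e-9)
  # constant-curvature helix: SOAM equals the curvature in deg/mm
  kappa <- 10 / (10^2 + (20 / (2 * pi))^2)
  expect_equal(at[["SOAM"]], kappa * 180 / pi, tolerance = 1e-3)
  # PAD consistency with its definition
  expect_equal(at[["PAD"]], at[["SOAM"]] / at[["RL"]], tolerance = 1e-12)

  sn <- curve_spec("sinusoid", amplitude = 4, wavelength = 20, span = 50)
  at <- analytic_tortuosity(sn, oracle_points = 2e5)
  expect_equal(at[["PAD"]], at[["SOAM"]] / at[["RL"]], tolerance = 1e-12)

  expect_error(analytic_tortuosity(
    curve_spec("siphon", arcs = data.frame(radius = 5, angle_deg = 90))),
    "closed form")
})

test_that("siphon curves are C1 arc chains with oracle ground truth", {
  sp <- curve_spec("siphon",
                   arcs = data.frame(radius = c(6, 4, 6),
                                     angle_deg = c(90, 120, 90)),
                   torsion_deg = 20, sample_count = 4000)
  p <- make_parametric_curve(sp)
  expect_equal(nrow(p), 4000)
  # total curve length equals the sum of arc lengths
  truth_lc <- sum(c(6, 4, 6) * c(90, 120, 90) * pi / 180)
  expect_equal(curve_length(p), truth_lc, tolerance = 1e-4)
  # no kinks: max turning angle per (uniform) step close to max curvature step
  or <- oracle_tortuosity(p)
  step <- truth_lc / (4000 - 1)
  max_turn_deg <- max(180 - vesselmorph:::.interior_angles_deg(p))
  expect_lt(max_turn_deg, 1.5 * step / 4 * 180 / pi)  # r_min = 4
})

test_that("rasterize_tube is deterministic and geometrically faithful", {
  g <- grid_spec(c(32, 32, 40), c(0.5, 0.5, 0.5))
  poly <- cbind(8, 8, seq(7, 13, length.out = 50))
  t1 <- rasterize_tube(poly, 3, g, noise_sd = 0)
  # noise-free volume takes exactly two values
  expect_equal(sort(unique(as.vector(t1$volume$values))), c(40, 200))
  # cross-sections are digital disks of radius 6 voxels within a voxel
  idx <- which(t1$mask$values, arr.ind = TRUE)
  mm <- sweep((idx - 1) * 0.5, 2, g$origin, `+`)
  mid <- mm[abs(mm[, 3] - 10) < 0.26, , drop = FALSE]
  rad <- sqrt((mid[, 1] - 8)^2 + (mid[, 2] - 8)^2)
  expect_lte(max(rad), 3.0 + 1e-9)
  expect_gt(max(rad), 3.0 - 0.5)

  # same seed: identical; different seed: same mask, different noise
  a <- rasterize_tube(poly, 3, g, noise_sd = 5, seed = 7)
  b <- rasterize_tube(poly, 3, g, noise_sd = 5, seed = 7)
  c2 <- rasterize_tube(poly, 3, g, noise_sd = 5, seed = 8)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$mask$values, c2$mask$values)
  expect_false(identical(a$volume$values, c2$volume$values))

  # margin violation names the offending point
  bad <- cbind(2, 8, seq(7, 13, length.out = 10))
  expect_error(rasterize_tube(bad, 3, g), "point 1")
})

test_that("tabular cohorts are reproducible affine worlds", {
  # noiseless single-coefficient cohort: age is exactly affine in the feature
  cs <- cohort_spec(n_subjects = 20, coefficients = c("BA_diam_mean" = 7),
                    intercept = 30, noise_sd = 0, seed = 11)
  tab <- simulate_tabular_cohort(cs)
  expect_equal(tab$age, 30 + 7 * tab[["BA_diam_mean"]], tolerance = 1e-12)

  # byte-identical rerun under the same spec
  expect_identical(tab, simulate_tabular_cohort(cs))

  # unknown coefficient names are rejected with the offending names
  expect_error(cohort_spec(coefficients = c("R-ICA_bogus" = 1, "huh" = 2)),
               "R-ICA_bogus.*huh")
  expect_error(cohort_spec(n_subjects = 5), "n_subjects")

  # default world targets the stated cohort age distribution
  tab <- simulate_tabular_cohort(cohort_spec(n_subjects = 2000, seed = 3))
  expect_equal(mean(tab$age), 49.3, tolerance = 0.05)
  expect_equal(sd(tab$age), 16.5, tolerance = 0.15)
})

test_that("volumetric subjects are deterministic with 13-value truth", {
  s1 <- simulate_volumetric_subject(55, seed = 4)
  s2 <- simulate_volumetric_subject(55, seed = 4)
  expect_identical(s1$volume$values, s2$volume$values)
  expect_identical(names(s1$segments), c("R-ICA", "L-ICA", "BA"))
  for (seg in s1$segments) {
    expect_length(seg$ground_truth$true_features, 13L)
    expect_true(all(is.finite(seg$ground_truth$true_features)))
    expect_equal(dim(seg$endpoints), c(2, 3))
  }
  # radii (hence true mean diameters) increase with age
  s3 <- simulate_volumetric_subject(75, seed = 4)
  expect_gt(s3$segments[["BA"]]$ground_truth$true_features[["BA_diam_mean"]],
            s1$segments[["BA"]]$ground_truth$true_features[["BA_diam_mean"]])
})

test_that("halving the voxel size changes extracted lc and diameter < 2%", {
  run_extract <- function(spacing) {
    g <- grid_spec(round(c(24, 20, 40) / spacing), rep(spacing, 3))
    poly <- cbind(12 + 1.5 * sin(2 * pi * seq(0, 20, length.out = 300) / 15),
                  10, 9 + seq(0, 20, length.out = 300))
    tube <- rasterize_tube(poly, 2, g, noise_sd = 0)
    ep <- mm_to_voxel(poly[c(1, 300), ], list(spacing = g$spacing,
                                              origin = g$origin))
    sk <- skeletonize(tube$mask, anchors = ep)
    gr <- build_skeleton_graph(sk)
    path <- shortest_centerline_path(gr, snap_endpoint(ep[1, ], gr)$node,
                                     snap_endpoint(ep[2, ], gr)$node)
    pl <- smooth_resample(path, step = 0.5)
    c(lc = curve_length(pl),
      dm = mean(diameters_along(pl, tube$mask)))
  }
  coarse <- run_extract(0.5)
  fine <- run_extract(0.25)
  expect_lt(abs(coarse["lc"] - fine["lc"]) / fine["lc"], 0.02)
  expect_lt(abs(coarse["dm"] - fine["dm"]) / fine["dm"], 0.02)
})
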
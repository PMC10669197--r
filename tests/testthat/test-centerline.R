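test_that("thinning reduces a straight tube to a unit-wide axial skeleton", {
  tube <- straight_tube(radius = 3, length_mm = 20)
  sk <- skeletonize(tube$mask, anchors = tube$endpoints)
  vox <- sk$voxels
  # skeleton stays within the mask and near the true axis
  axis_vox <- tube$endpoints[1, 1:2]
  expect_true(all(abs(vox[, 1] - axis_vox[1]) <= 1))
  expect_true(all(abs(vox[, 2] - axis_vox[2]) <= 1))
  # one voxel thick: no voxel has a full 3x3x3 object neighborhood
  occ <- new.env()
  for (i in seq_len(nrow(vox)))
    assign(paste(vox[i, ], collapse = ","), TRUE, envir = occ)
  full <- vapply(seq_len(nrow(vox)), function(i) {
    all(vapply(1:27, function(c0) {
      d <- c((c0 - 1) %% 3, ((c0 - 1) %/% 3) %% 3, (c0 - 1) %/% 9) - 1
      exists(paste(vox[i, ] + d, collapse = ","), envir = occ)
    }, logical(1)))
  }, logical(1))
  expect_false(any(full))
  # homotopy: still a single component
  g <- build_skeleton_graph(sk)
  expect_equal(igraph::components(g$graph)$no, 1)
  expect_error(skeletonize(vol3d(array(FALSE, c(8, 8, 8)), c(1, 1, 1))),
               "empty")
})

test_that("an isolated voxel is its own skeleton and a torus keeps its cycle", {
  vals <- array(FALSE, c(9, 9, 9))
  vals[5, 5, 5] <- TRUE
  sk <- skeletonize(vol3d(vals, c(1, 1, 1)))
  expect_equal(sk$voxels, cbind(4L, 4L, 4L))

  # torus: ring of radius 6 mm, tube radius 1.5 mm
  g <- grid_spec(c(40, 40, 16), c(0.5, 0.5, 0.5))
  th <- seq(0, 2 * pi, length.out = 400)
  ring <- cbind(10 + 6 * cos(th), 10 + 6 * sin(th), 4)
  torus <- rasterize_tube(ring, 1.5, g, noise_sd = 0)
  sk <- skeletonize(torus$mask)
  gr <- build_skeleton_graph(sk)
  comp <- igraph::components(gr$graph)
  expect_equal(comp$no, 1)
  # independent topology count: a connected graph retains a cycle iff E >= V
  expect_gte(igraph::ecount(gr$graph), igraph::vcount(gr$graph))
})

test_that("skeleton graph weights are anisotropy-aware", {
  mk <- function(vox) {
    structure(list(voxels = vox, dim = c(10L, 10L, 10L),
                   spacing = c(0.5, 0.5, 0.8), origin = c(0, 0, 0)),
              class = "skeleton3d")
  }
  g1 <- build_skeleton_graph(mk(rbind(c(1, 1, 1), c(2, 1, 1))))
  expect_equal(igraph::E(g1$graph)$weight, 0.5)
  g2 <- build_skeleton_graph(mk(rbind(c(1, 1, 1), c(2, 2, 2))))
  expect_equal(igraph::E(g2$graph)$weight, sqrt(0.25 + 0.25 + 0.64))
  g3 <- build_skeleton_graph(mk(rbind(c(1, 1, 1), c(5, 5, 5))))
  expect_equal(igraph::degree(g3$graph), c(0, 0))
})

voxel_to_mm_test <- function(idx, geom) {
  sweep(sweep(idx, 2, geom$spacing, `*`), 2, geom$origin, `+`)
}

test_that("endpoint snapping matches the brute-force oracle with stated ties", {
  tube <- straight_tube(radius = 2.5, length_mm = 18)
  sk <- skeletonize(tube$mask, anchors = tube$endpoints)
  # a point already on the skeleton snaps to itself at distance 0
  v0 <- sk$voxels[3, ]
  sn <- snap_endpoint(v0, sk)
  expect_equal(sn$voxel, v0)
  expect_equal(sn$distance_mm, 0)
  # arbitrary points match an exhaustive scan
  geom <- list(spacing = sk$spacing, origin = sk$origin)
  for (k in 1:10) {
    p <- withr::with_seed(k, runif(3, 0, 10))
    sn <- snap_endpoint(p, sk, type = "mm")
    ctr <- voxel_to_mm_test(sk$voxels, geom)
    d <- sqrt(colSums((t(ctr) - p)^2))
    expect_equal(sn$distance_mm, min(d))
  }
  # equidistant tie: lexicographically smallest voxel index wins
  skm <- structure(list(voxels = rbind(c(2, 0, 0), c(0, 0, 2)),
                        dim = c(5L, 5L, 5L), spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)),
                   class = "skeleton3d")
  tie <- snap_endpoint(c(1, 0, 1), skm)
  expect_equal(tie$voxel, c(0, 0, 2))  # smaller first coordinate
})

test_that("Dijkstra paths are optimal, symmetric and error-typed", {
  # trivial: a = b
  g <- random_weighted_graph(6, 0.6, rng_seed = 1)
  p <- shortest_centerline_path(g, 3, 3)
  expect_equal(p$weight_mm, 0)
  expect_equal(p$nodes, 3L)

  # oracle agreement + symmetry on small random graphs
  for (k in 1:50) {
    n <- withr::with_seed(k, sample(2:8, 1))
    g <- random_weighted_graph(n, 0.5, rng_seed = 1000 + k)
    ab <- withr::with_seed(2000 + k, sample(n, 2))
    truth <- brute_force_shortest(g, ab[1], ab[2])
    if (is.finite(truth)) {
      p1 <- shortest_centerline_path(g, ab[1], ab[2])
      p2 <- shortest_centerline_path(g, ab[2], ab[1])
      expect_equal(p1$weight_mm, truth, tolerance = 1e-12)
      expect_equal(p2$weight_mm, truth, tolerance = 1e-12)
    } else {
      expect_error(shortest_centerline_path(g, ab[1], ab[2]),
                   class = "vm_no_path")
    }
  }

  # invalid-node error is distinct from no-path error
  g <- random_weighted_graph(4, 0.9, rng_seed = 3)
  expect_error(shortest_centerline_path(g, 1, 99),
               class = "vm_invalid_node")
})

test_that("a shortcut branch wins, the documented tortuous-vessel failure mode", {
  # skeleton shaped like a theta: direct chord vs long detour between A and B
  detour <- cbind(0:10, pmin(0:10, 10 - (0:10)), 0L)    # diagonal diamond arc
  vox <- unique(rbind(cbind(0:10, 0L, 0L), detour))
  sk <- structure(list(voxels = vox, dim = c(12L, 12L, 3L),
                       spacing = c(1, 1, 1), origin = c(0, 0, 0)),
                  class = "skeleton3d")
  g <- build_skeleton_graph(sk)
  a <- snap_endpoint(c(0, 0, 0), g)$node
  b <- snap_endpoint(c(10, 0, 0), g)$node
  p <- shortest_centerline_path(g, a, b)
  expect_equal(p$weight_mm, 10)            # the straight shortcut
  expect_true(all(p$voxels[, 2] == 0))     # not the detour
})

test_that("smoothing preserves straight paths and deflates jagged ones", {
  # collinear path: length preserved within 0.5%, output collinear
  tube <- straight_tube(radius = 2.5, length_mm = 20)
  sk <- skeletonize(tube$mask, anchors = tube$endpoints)
  g <- build_skeleton_graph(sk)
  a <- snap_endpoint(tube$endpoints[1, ], g)$node
  b <- snap_endpoint(tube$endpoints[2, ], g)$node
  path <- shortest_centerline_path(g, a, b)
  poly <- smooth_resample(path, step = 0.5)
  expect_lt(abs(curve_length(poly) - path$weight_mm) / path$weight_mm,
            0.005)
  expect_lt(soam(poly), 1e-6)

  # step arithmetic: 0.5 mm step on a 20 mm path -> 41 +/- 1 points
  expect_lt(abs(nrow(poly) - 41), 1.5)
  # consecutive spacing within 1% of the step (except final point)
  seg <- sqrt(rowSums(diff(unclass(poly))^2))
  expect_true(all(abs(head(seg, -1) - 0.5) < 0.005))

  # voxel-jagged diagonal: smoothing shortens the chordal length
  stair <- cbind(rep(0:14, each = 2)[-1], rep(0:14, each = 2)[-30], 0) * 0.5
  raw_lc <- curve_length(stair)
  sm <- smooth_resample(stair, step = 0.25)
  expect_lt(curve_length(sm), raw_lc)

  # halving the step changes lc by < 0.5%
  half <- smooth_resample(path, step = 0.25)
  expect_lt(abs(curve_length(half) - curve_length(poly)) /
              curve_length(poly), 0.005)

  expect_error(smooth_resample(cbind(0:2, 0, 0)), "4")
})

test_that("path QC flags by ratio ceiling and snap bound", {
  tube <- straight_tube(radius = 2.5, length_mm = 20)
  sk <- skeletonize(tube$mask, anchors = tube$endpoints)
  g <- build_skeleton_graph(sk)
  a <- snap_endpoint(tube$endpoints[1, ], g)
  b <- snap_endpoint(tube$endpoints[2, ], g)
  path <- shortest_centerline_path(g, a$node, b$node)
  qc <- path_qc(path, c(a$distance_mm, b$distance_mm))
  expect_equal(qc$flag, "accepted")
  expect_gt(qc$ratio, 0.99)
  # a straight path is "too straight" under a 0.99 ceiling
  expect_equal(path_qc(path, 0, max_ratio = 0.99)$flag, "suspect")
  # snap distance beyond the bound
  expect_equal(path_qc(path, c(20, 0), max_snap_mm = 5)$flag, "suspect")
})

test_that("end-to-end straight phantom recovers the true length within 2%", {
  tube <- straight_tube(radius = 3, length_mm = 26, noise_sd = 10, seed = 4)
  mask <- region_growing(tube$volume,
                         seed_spec(tube$endpoints[1, ], threshold = 120))
  sk <- skeletonize(mask, anchors = tube$endpoints)
  g <- build_skeleton_graph(sk)
  a <- snap_endpoint(tube$endpoints[1, ], g)$node
  b <- snap_endpoint(tube$endpoints[2, ], g)$node
  poly <- smooth_resample(shortest_centerline_path(g, a, b), step = 0.5)
  expect_lt(abs(curve_length(poly) - 26) / 26, 0.02)
})

test_that("annotations and polylines round-trip through JSON", {
  tmp <- withr::local_tempdir()
  ann <- list(`R-ICA` = list(label = "R-ICA", endpoint_a = c(1L, 2L, 3L),
                             endpoint_b = c(9L, 8L, 7L)),
              BA = list(label = "BA", endpoint_a = c(0L, 0L, 0L),
                        endpoint_b = c(4L, 4L, 4L)))
  path <- file.path(tmp, "ann.json")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_identical(back, ann)
  write_polylines(list(BA = cbind(1:3, 0, 0)), file.path(tmp, "poly.json"))
  expect_true(file.size(file.path(tmp, "poly.json")) > 0)
})
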
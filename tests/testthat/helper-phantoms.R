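# shared in-code fixtures: no data files, everything built at test time

# straight axial tube phantom with known geometry
straight_tube <- function(radius = 3, length_mm = 26, spacing = 0.5,
                          noise_sd = 0, seed = 1) {
  margin <- 2 * radius + 2
  nxy <- ceiling(2 * margin / spacing) + 1
  nz <- ceiling((length_mm + 2 * margin) / spacing) + 1
  g <- grid_spec(c(nxy, nxy, nz), rep(spacing, 3))
  ctr <- (nxy - 1) * spacing / 2
  z0 <- margin
  poly <- cbind(ctr, ctr, seq(z0, z0 + length_mm, length.out = 200))
  tube <- rasterize_tube(poly, radius, g, vessel_intensity = 200,
                         background_intensity = 40, noise_sd = noise_sd,
                         seed = seed)
  ep <- mm_to_voxel(poly[c(1, nrow(poly)), ], list(spacing = g$spacing,
                                                   origin = g$origin))
  list(volume = tube$volume, mask = tube$mask, grid = g, poly = poly,
       endpoints = ep, true_length = length_mm, radius = radius,
       axis_xy_mm = c(ctr, ctr))
}

# smooth random space curve via a low-order random Fourier series,
# resampled to near-uniform arc length
random_smooth_polyline <- function(n_pts = 80, scale = 30, rng_seed = 1) {
  withr::with_seed(rng_seed, {
    t <- seq(0, 1, length.out = 400)
    coords <- vapply(1:3, function(j) {
      a <- rnorm(3, sd = c(1, 0.5, 0.25))
      b <- rnorm(3, sd = c(1, 0.5, 0.25))
      drift <- rnorm(1, sd = 2)
      drift * t + a[1] * sin(2 * pi * t) + b[1] * cos(2 * pi * t) +
        a[2] * sin(4 * pi * t) + b[2] * cos(4 * pi * t) +
        a[3] * sin(6 * pi * t) + b[3] * cos(6 * pi * t)
    }, numeric(length(t)))
    p <- coords * scale / 4
    vesselmorph:::.resample_polyline(p, n = n_pts)
  })
}

random_rotation <- function(rng_seed = 1) {
  withr::with_seed(rng_seed, {
    qr_dec <- qr(matrix(rnorm(9), 3))
    Q <- qr.Q(qr_dec)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}

six_features <- function(p) {
  c(lc = curve_length(p), l = euclidean_length(p), RL = relative_length(p),
    SOAM = soam(p), PAD = product_of_angle_distance(p),
    TI = triangular_index(p))
}

# weighted random graph as a skeleton_graph-compatible object, with dummy
# voxel coordinates (the path tests only use edge weights)
random_weighted_graph <- function(n, p_edge = 0.4, rng_seed = 1) {
  withr::with_seed(rng_seed, {
    em <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(em)) < p_edge
    em <- em[keep, , drop = FALSE]
    w <- runif(nrow(em), 0.1, 1)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(em))
      g <- igraph::add_edges(g, as.vector(t(em)), weight = w)
    structure(list(graph = g, voxels = cbind(seq_len(n), 0L, 0L),
                   spacing = c(1, 1, 1), origin = c(0, 0, 0)),
              class = "skeleton_graph")
  })
}

# exhaustive simple-path shortest distance (branch and bound), the
# independent oracle for Dijkstra
brute_force_shortest <- function(graph, from, to) {
  g <- graph$graph
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(v) {
    es <- igraph::incident(g, v)
    ends <- igraph::ends(g, es)
    nbr <- ifelse(ends[, 1] == v, ends[, 2], ends[, 1])
    list(nbr = as.integer(nbr), w = igraph::E(g)$weight[as.integer(es)])
  })
  best <- Inf
  visited <- rep(FALSE, n)
  dfs <- function(v, acc) {
    if (acc >= best) return()
    if (v == to) {
      best <<- acc
      return()
    }
    visited[v] <<- TRUE
    a <- adj[[v]]
    for (i in seq_along(a$nbr)) {
      u <- a$nbr[i]
      if (!visited[u]) dfs(u, acc + a$w[i])
    }
    visited[v] <<- FALSE
  }
  dfs(from, 0)
  best
}

# independent sort-based percentile oracle (linear interpolation between
# order statistics)
percentile_oracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
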
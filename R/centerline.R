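#' Skeletonize a vessel mask by 3D topological thinning
#'
#' Iteratively deletes simple (topology-preserving, for the 26/6
#' connectivity pair) border voxels in six directional subiterations until
#' stable, keeping curve endpoints, so a tubular mask reduces to a one-voxel
#' -wide centerline with the same number of connected components and the
#' same holes. `anchors` marks voxels that may never be deleted; passing the
#' annotated vessel endpoints here prevents the erosion of tube ends that
#' plain thinning causes, so the skeleton spans the full annotated length.
#'
#' @param mask A nonempty logical [vol3d()].
#' @param anchors Optional n x 3 matrix of 0-based voxel indices to protect;
#'   anchors outside the mask are ignored.
#' @return An object of class `skeleton3d`: 0-based voxel matrix plus
#'   geometry.
#' @export
skeletonize <- function(mask, anchors = NULL) {
  if (!.is_mask(mask)) vm_stop("mask must be a logical vol3d")
  if (!any(mask$values)) vm_stop("mask is empty; nothing to skeletonize")
  d <- dim(mask$values)
  anc <- matrix(integer(), 0, 3)
  if (!is.null(anchors)) {
    anchors <- rbind(anchors)
    keep <- vapply(seq_len(nrow(anchors)), function(i) {
      v <- anchors[i, ]
      all(v >= 0) && all(v < d) && mask$values[v[1] + 1, v[2] + 1, v[3] + 1]
    }, logical(1))
    anc <- matrix(as.integer(anchors[keep, , drop = FALSE]), ncol = 3)
  }
  sk <- array(.thin_cpp(as.vector(mask$values), d, anc), d)
  idx <- which(sk) - 1L
  vox <- cbind(idx %% d[1],
               (idx %/% d[1]) %% d[2],
               idx %/% (d[1] * d[2]))
  structure(list(voxels = vox, dim = d, spacing = mask$spacing,
                 origin = mask$origin),
            class = "skeleton3d")
}

#' @export
print.skeleton3d <- function(x, ...) {
  cat(sprintf("<skeleton3d> %d voxels in a %s grid\n", nrow(x$voxels),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

#' Build the weighted adjacency graph of a skeleton
#'
#' Nodes are skeleton voxels; undirected edges join 26-adjacent voxels with
#' weight equal to the spacing-aware Euclidean distance between voxel
#' centers in mm.
#'
#' @param skeleton A [skeletonize()] result.
#' @return An object of class `skeleton_graph` wrapping an igraph graph plus
#'   the voxel table and geometry.
#' @export
build_skeleton_graph <- function(skeleton) {
  if (!inherits(skeleton, "skeleton3d")) vm_stop("skeleton3d required")
  if (nrow(skeleton$voxels) == 0L) vm_stop("skeleton is empty")
  ed <- .skeleton_edges_cpp(skeleton$voxels, skeleton$dim, skeleton$spacing)
  g <- igraph::make_empty_graph(n = nrow(skeleton$voxels), directed = FALSE)
  if (length(ed$from))
    g <- igraph::add_edges(g, as.vector(rbind(ed$from, ed$to)),
                           weight = ed$weight)
  structure(list(graph = g, voxels = skeleton$voxels,
                 spacing = skeleton$spacing, origin = skeleton$origin),
            class = "skeleton_graph")
}

#' Snap a point to the nearest skeleton voxel
#'
#' Manually annotated endpoints land near, but rarely exactly on, the
#' skeleton; this returns the skeleton voxel minimizing the Euclidean mm
#' distance, ties broken by lexicographically smallest voxel index.
#'
#' @param point Length-3 point: 0-based voxel indices (`type = "voxel"`) or
#'   mm (`type = "mm"`).
#' @param skeleton A [skeletonize()] result or a [build_skeleton_graph()]
#'   result.
#' @param type Interpretation of `point`.
#' @return List with `node` (row index into the skeleton voxel table),
#'   `voxel` (0-based triple) and `distance_mm`.
#' @export
snap_endpoint <- function(point, skeleton, type = c("voxel", "mm")) {
  type <- match.arg(type)
  vox <- skeleton$voxels
  if (is.null(vox) || nrow(vox) == 0L) vm_stop("skeleton is empty")
  geom <- list(spacing = skeleton$spacing, origin = skeleton$origin)
  pmm <- if (type == "voxel") as.vector(voxel_to_mm(point, geom)) else
    as.numeric(point)
  ctr <- voxel_to_mm(vox, geom)
  d2 <- (ctr[, 1] - pmm[1])^2 + (ctr[, 2] - pmm[2])^2 + (ctr[, 3] - pmm[3])^2
  ord <- order(d2, vox[, 1], vox[, 2], vox[, 3])
  best <- ord[1]
  list(node = best, voxel = vox[best, ], distance_mm = sqrt(d2[best]))
}

#' Shortest centerline path between two skeleton nodes
#'
#' Dijkstra's algorithm on the skeleton graph. With several annotated
#' endpoints on a tortuous vessel, note that shortcut branches produce
#' shortest paths shorter than the anatomically correct one — the failure
#' mode that motivates downstream QC.
#'
#' @param graph A [build_skeleton_graph()] result.
#' @param from,to Node indices (rows of the voxel table), e.g. from
#'   [snap_endpoint()].
#' @return An object of class `centerline_path`: node sequence, 0-based
#'   voxels, mm points and total weight in mm.
#' @export
shortest_centerline_path <- function(graph, from, to) {
  if (!inherits(graph, "skeleton_graph")) vm_stop("skeleton_graph required")
  n <- nrow(graph$voxels)
  if (!(from %in% seq_len(n)) || !(to %in% seq_len(n)))
    vm_stop("invalid node index", class = "vm_invalid_node")
  if (from == to) {
    nodes <- from
  } else {
    sp <- suppressWarnings(
      igraph::shortest_paths(graph$graph, from = from, to = to,
                             weights = igraph::E(graph$graph)$weight,
                             algorithm = "dijkstra"))
    nodes <- as.integer(sp$vpath[[1]])
    if (length(nodes) == 0L)
      vm_stop("no path between nodes ", from, " and ", to,
              " (different components)", class = "vm_no_path")
  }
  geom <- list(spacing = graph$spacing, origin = graph$origin)
  vox <- graph$voxels[nodes, , drop = FALSE]
  pts <- voxel_to_mm(vox, geom)
  w <- if (length(nodes) > 1)
    sum(igraph::E(graph$graph, path = nodes)$weight) else 0
  structure(list(nodes = nodes, voxels = vox, points_mm = pts,
                 weight_mm = w),
            class = "centerline_path")
}

#' @export
print.centerline_path <- function(x, ...) {
  cat(sprintf("<centerline_path> %d nodes, %.2f mm\n", length(x$nodes),
              x$weight_mm))
  invisible(x)
}

#' Smooth and uniformly resample a centerline
#'
#' Fits one cubic smoothing spline per coordinate against cumulative chordal
#' arc length (suppressing the voxel-quantization jaggedness that inflates
#' curve length), then resamples the smoothed curve at a uniform arc-length
#' step. All angle-based tortuosity descriptors are computed on this uniform
#' sampling.
#'
#' @param path A [shortest_centerline_path()] result (or an n x 3 mm point
#'   matrix), n >= 4.
#' @param step Resampling step in mm (default 0.5, sub-voxel for typical
#'   TOF spacing).
#' @param df_frac Smoothing-spline degrees of freedom as a fraction of the
#'   input point count (default 0.5); higher follows the raw path more
#'   closely.
#' @return An object of class `polyline_mm`: an n x 3 matrix with attribute
#'   `step`.
#' @export
smooth_resample <- function(path, step = 0.5, df_frac = 0.5) {
  pts <- if (inherits(path, "centerline_path")) path$points_mm else
    .as_polyline(path)
  n <- nrow(pts)
  if (n < 4L) vm_stop("need at least 4 path points to smooth")
  if (step <= 0) vm_stop("step must be positive")
  seg <- sqrt(rowSums(diff(pts)^2))
  if (any(seg == 0)) {
    keep <- c(TRUE, seg > 0)
    pts <- pts[keep, , drop = FALSE]
    n <- nrow(pts)
    if (n < 4L) vm_stop("need at least 4 distinct path points to smooth")
    seg <- sqrt(rowSums(diff(pts)^2))
  }
  s <- c(0, cumsum(seg))
  df <- min(n, max(4, round(df_frac * n)))
  fine_n <- max(10L * n, 200L)
  sf <- seq(0, s[n], length.out = fine_n)
  sm <- vapply(1:3, function(j) {
    fit <- smooth.spline(s, pts[, j], df = df)
    predict(fit, sf)$y
  }, numeric(fine_n))
  out <- .resample_polyline(sm, step = step)
  structure(out, step = step, class = c("polyline_mm", class(out)))
}

#' Path quality control
#'
#' Numeric surrogate for the visual exclusion of incorrect path-finding:
#' computes the chord/path length ratio and the endpoint snap distances and
#' flags the path `"suspect"` when the ratio exceeds `max_ratio` (a path
#' straighter than the vessel plausibly is — the shortcut failure mode) or
#' when an annotation had to travel more than `max_snap_mm` to reach the
#' skeleton. The defaults (`max_ratio = 1`, i.e. disabled, and
#' `max_snap_mm = 5`) accept straight phantoms; tighten `max_ratio` for
#' tortuous vessels.
#'
#' @param path A [shortest_centerline_path()] result.
#' @param snap_distances_mm Numeric vector of endpoint snap distances.
#' @param max_ratio Chord/path ratio ceiling in (0, 1].
#' @param max_snap_mm Largest acceptable snap distance in mm.
#' @return An object of class `path_qc`: list with `ratio`,
#'   `snap_distances_mm`, `flag` (`"accepted"` or `"suspect"`) and `reason`.
#' @export
path_qc <- function(path, snap_distances_mm = numeric(),
                    max_ratio = 1, max_snap_mm = 5) {
  if (!inherits(path, "centerline_path")) vm_stop("centerline_path required")
  chord <- sqrt(sum((path$points_mm[nrow(path$points_mm), ] -
                       path$points_mm[1, ])^2))
  ratio <- if (path$weight_mm > 0) chord / path$weight_mm else 1
  reason <- character()
  if (ratio > max_ratio)
    reason <- c(reason, sprintf("chord/path ratio %.3f > %.3f", ratio,
                                max_ratio))
  if (length(snap_distances_mm) && max(snap_distances_mm) > max_snap_mm)
    reason <- c(reason, sprintf("snap distance %.1f mm > %.1f mm",
                                max(snap_distances_mm), max_snap_mm))
  structure(list(ratio = ratio, snap_distances_mm = snap_distances_mm,
                 flag = if (length(reason)) "suspect" else "accepted",
                 reason = reason),
            class = "path_qc")
}

# ---------------------------------------------------------------------------
# annotation and polyline JSON I/O
# ---------------------------------------------------------------------------

#' Read or write endpoint annotations
#'
#' Annotations are JSON arrays of objects
#' `{label, endpoint_a: [i,j,k], endpoint_b: [i,j,k]}` with 0-based voxel
#' indices.
#'
#' @param path JSON file path.
#' @return For reading, a named list of annotations.
#' @export
read_annotations <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(x)) x <- split(x, seq_len(nrow(x)))
  ann <- lapply(x, function(a) {
    if (is.null(a$label) || length(unlist(a$endpoint_a)) != 3 ||
        length(unlist(a$endpoint_b)) != 3)
      vm_stop("malformed annotation entry in ", path)
    list(label = as.character(a$label),
         endpoint_a = as.integer(unlist(a$endpoint_a)),
         endpoint_b = as.integer(unlist(a$endpoint_b)))
  })
  names(ann) <- vapply(ann, `[[`, character(1), "label")
  ann
}

#' @rdname read_annotations
#' @param annotations Named list of `list(label, endpoint_a, endpoint_b)`.
#' @export
write_annotations <- function(annotations, path) {
  jsonlite::write_json(unname(annotations), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Export centerline polylines as JSON
#'
#' @param polylines Named list of n x 3 mm point matrices.
#' @param path JSON file path.
#' @export
write_polylines <- function(polylines, path) {
  out <- lapply(names(polylines), function(lb) {
    list(label = lb, points_mm = unclass(polylines[[lb]]))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
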
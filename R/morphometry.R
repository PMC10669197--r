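#' Feature naming
#'
#' Thirteen per-segment features: six tortuosity descriptors and seven
#' diameter statistics, keyed `"{label}_{suffix}"` (for example
#' `"R-ICA_diam_mean"`). The modeling table uses three segments (R-ICA,
#' L-ICA, BA), giving 3 x 13 = 39 feature columns.
#'
#' @return Character vector of feature names.
#' @export
vm_feature_suffixes <- function() {
  c("lc", "l", "RL", "SOAM", "PAD", "TI",
    "diam_mean", "diam_min", "diam_max", "diam_std",
    "diam_p25", "diam_p50", "diam_p75")
}

#' @rdname vm_feature_suffixes
#' @export
vm_segment_labels <- function() c("R-ICA", "L-ICA", "BA")

#' @rdname vm_feature_suffixes
#' @export
vm_feature_names <- function() {
  as.vector(t(outer(vm_segment_labels(), vm_feature_suffixes(), paste,
                    sep = "_")))
}

.as_polyline <- function(p) {
  p <- as.matrix(p)
  if (!is.numeric(p) || ncol(p) != 3L) vm_stop("polyline must be an n x 3 numeric matrix")
  p
}

#' Tortuosity descriptors of a 3D polyline
#'
#' `curve_length` is the summed chordal length lc; `euclidean_length` is the
#' endpoint distance l; `relative_length` is RL = l / lc (1 for a straight
#' segment); `soam` is the sum over interior points of the angular deviation
#' from straightness, `sum(180 - phi_i) / lc`, in degrees per mm, where phi_i
#' is the interior angle at point i between the chords to its neighbors;
#' `product_of_angle_distance` combines SOAM with RL; `triangular_index` is
#' the mean over interior points of `(a_i + b_i) / c_i` with a, b the
#' adjacent chord lengths and c the spanning chord (1 for a straight
#' segment, larger when winding).
#'
#' Angle-based descriptors assume a (near-)uniform arc-length sampling of the
#' centerline, which [smooth_resample()] provides.
#'
#' @param polyline n x 3 numeric matrix of points in mm.
#' @return A length in mm, a dimensionless ratio, or degrees/mm.
#' @examples
#' p <- cbind(seq(0, 10, 0.5), 0, 0)
#' curve_length(p)      # 10
#' relative_length(p)   # 1
#' soam(p)              # 0
#' @export
curve_length <- function(polyline) {
  p <- .as_polyline(polyline)
  if (nrow(p) < 2L) vm_stop("polyline needs at least 2 points")
  sum(sqrt(rowSums(diff(p)^2)))
}

#' @rdname curve_length
#' @export
euclidean_length <- function(polyline) {
  p <- .as_polyline(polyline)
  if (nrow(p) < 2L) vm_stop("polyline needs at least 2 points")
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
}

#' @rdname curve_length
#' @export
relative_length <- function(polyline) {
  lc <- curve_length(polyline)
  l <- euclidean_length(polyline)
  if (l == 0) vm_stop("euclidean length is zero (closed curve); RL undefined")
  if (lc == 0) vm_stop("curve length is zero; RL undefined")
  l / lc
}

# interior angles phi_i in degrees at points 2..(n-1), computed stably with
# atan2 of the cross/dot products of the chords to both neighbors
.interior_angles_deg <- function(p) {
  n <- nrow(p)
  u <- p[1:(n - 2), , drop = FALSE] - p[2:(n - 1), , drop = FALSE]
  w <- p[3:n, , drop = FALSE] - p[2:(n - 1), , drop = FALSE]
  nu <- sqrt(rowSums(u^2))
  nw <- sqrt(rowSums(w^2))
  if (any(nu == 0) || any(nw == 0))
    vm_stop("repeated consecutive points at index ",
            which(nu == 0 | nw == 0)[1] + 1, "; angle undefined")
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  atan2(sqrt(rowSums(cr^2)), rowSums(u * w)) * 180 / pi
}

#' @rdname curve_length
#' @export
soam <- function(polyline) {
  p <- .as_polyline(polyline)
  if (nrow(p) < 3L) vm_stop("polyline needs at least 3 points")
  phi <- .interior_angles_deg(p)
  sum(180 - phi) / curve_length(p)
}

#' @rdname curve_length
#' @param pad_definition How SOAM and RL are combined. The descriptor's flat
#'   rendering is ambiguous between a quotient and a product; the quotient
#'   `SOAM / RL` (default) penalizes winding segments twice and reduces to
#'   SOAM when RL = 1. The product reading is available as
#'   `"soam_times_rl"`.
#' @export
product_of_angle_distance <- function(polyline,
                                      pad_definition = c("soam_over_rl",
                                                         "soam_times_rl")) {
  pad_definition <- match.arg(pad_definition)
  s <- soam(polyline)
  rl <- relative_length(polyline)
  if (pad_definition == "soam_over_rl") s / rl else s * rl
}

#' @rdname curve_length
#' @export
triangular_index <- function(polyline) {
  p <- .as_polyline(polyline)
  n <- nrow(p)
  if (n < 3L) vm_stop("polyline needs at least 3 points")
  a <- sqrt(rowSums((p[2:(n - 1), , drop = FALSE] -
                       p[1:(n - 2), , drop = FALSE])^2))
  b <- sqrt(rowSums((p[3:n, , drop = FALSE] -
                       p[2:(n - 1), , drop = FALSE])^2))
  cc <- sqrt(rowSums((p[3:n, , drop = FALSE] -
                        p[1:(n - 2), , drop = FALSE])^2))
  if (any(cc == 0))
    vm_stop("spanning chord is zero at interior point ",
            which(cc == 0)[1] + 1, " (fold-back); TI undefined")
  mean((a + b) / cc)
}

#' Diameters along a centerline from the mask distance transform
#'
#' The local diameter at a centerline point is twice the exact anisotropic
#' Euclidean distance from the containing voxel's center to the nearest
#' background voxel center, computed on the binary vessel mask. With
#' `interpolate = TRUE` the distance field is instead sampled trilinearly at
#' the point itself.
#'
#' @param polyline n x 3 matrix of centerline points in mm.
#' @param mask A logical [vol3d()] vessel mask.
#' @param interpolate Trilinear interpolation of the distance field
#'   (default `FALSE`: value at the containing voxel).
#' @return Numeric vector of diameters in mm, one per point.
#' @export
diameters_along <- function(polyline, mask, interpolate = FALSE) {
  p <- .as_polyline(polyline)
  if (!.is_mask(mask)) vm_stop("mask must be a logical vol3d")
  d <- dim(mask$values)
  edt <- array(.edt_cpp(as.vector(mask$values), d, mask$spacing), d)
  vox <- mm_to_voxel(p, mask)
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    v <- vox[i, ]
    if (any(v < 0) || any(v >= d))
      vm_stop("centerline point ", i, " maps outside the volume")
    if (!mask$values[v[1] + 1, v[2] + 1, v[3] + 1])
      vm_stop("centerline point ", i, " lies outside the mask")
    if (interpolate) {
      f <- (p[i, ] - mask$origin) / mask$spacing
      f0 <- pmin(pmax(floor(f), 0), d - 2)
      w <- f - f0
      acc <- 0
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        wt <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
        acc <- acc + wt * edt[f0[1] + dx + 1, f0[2] + dy + 1, f0[3] + dz + 1]
      }
      out[i] <- 2 * acc
    } else {
      out[i] <- 2 * edt[v[1] + 1, v[2] + 1, v[3] + 1]
    }
  }
  out
}

#' Summary statistics of a diameter sequence
#'
#' Mean, minimum, maximum, standard deviation (population form), and the
#' 25th/50th/75th percentiles (linear interpolation between order
#' statistics).
#'
#' @param diameters Nonempty numeric vector of diameters in mm.
#' @return Named numeric vector with elements `diam_mean`, `diam_min`,
#'   `diam_max`, `diam_std`, `diam_p25`, `diam_p50`, `diam_p75`.
#' @export
diameter_stats <- function(diameters) {
  if (length(diameters) == 0L || anyNA(diameters))
    vm_stop("diameters must be a nonempty numeric vector without NAs")
  q <- quantile(diameters, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(diam_mean = mean(diameters),
    diam_min = min(diameters),
    diam_max = max(diameters),
    diam_std = sqrt(mean((diameters - mean(diameters))^2)),
    diam_p25 = q[1], diam_p50 = q[2], diam_p75 = q[3])
}

#' All 13 features of a vessel segment
#'
#' @inheritParams diameters_along
#' @inheritParams product_of_angle_distance
#' @param label Segment label used as the key prefix (for example `"R-ICA"`).
#' @return Named numeric vector of length 13 with class `segment_features`
#'   and a `label` attribute.
#' @export
segment_features <- function(polyline, mask, label,
                             pad_definition = c("soam_over_rl",
                                                "soam_times_rl"),
                             interpolate = FALSE) {
  pad_definition <- match.arg(pad_definition)
  diam <- diameters_along(polyline, mask, interpolate = interpolate)
  vals <- c(lc = curve_length(polyline),
            l = euclidean_length(polyline),
            RL = relative_length(polyline),
            SOAM = soam(polyline),
            PAD = product_of_angle_distance(polyline, pad_definition),
            TI = triangular_index(polyline),
            diameter_stats(diam))
  names(vals) <- paste0(label, "_", vm_feature_suffixes())
  structure(vals, label = label, class = c("segment_features", "numeric"))
}

#' @export
print.segment_features <- function(x, ...) {
  cat(sprintf("<segment_features> %s\n", attr(x, "label")))
  print(round(unclass(x), 4))
  invisible(x)
}
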
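#' 3D scalar volume with voxel geometry
#'
#' The basic image container: a 3D array of intensities (or logicals, for
#' masks) with per-axis voxel spacing in mm and a world origin in mm. Voxel
#' indices in the public interface are 0-based (as in the annotation files the
#' pipeline consumes); the mm position of voxel `(i, j, k)` is
#' `origin + c(i, j, k) * spacing`. No orientation matrix is applied beyond
#' spacing and origin.
#'
#' @param values 3D numeric or logical array.
#' @param spacing Voxel size in mm per axis, length 3, positive.
#' @param origin World position of voxel (0,0,0) in mm, length 3.
#' @return An object of class `vol3d`.
#' @examples
#' v <- vol3d(array(0, c(16, 16, 16)), spacing = c(0.5, 0.5, 0.5))
#' dim(v$values)
#' @export
vol3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    vm_stop("values must be a 3D array")
  if (any(dim(values) < 8L) && !is.logical(values))
    warning("volume has fewer than 8 voxels along some axis")
  structure(list(values = values,
                 spacing = .check_num3(spacing, "spacing", positive = TRUE),
                 origin = .check_num3(origin, "origin")),
            class = "vol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<vol3d> %s voxels, spacing %s mm, %s\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              if (is.logical(x$values)) sprintf("mask (%d on)",
                                                sum(x$values)) else
                sprintf("range [%.3g, %.3g]", min(x$values), max(x$values))))
  invisible(x)
}

.as_mask <- function(values, like) {
  vol3d(array(as.logical(values), dim(like$values)), like$spacing,
        like$origin)
}

.is_mask <- function(x) inherits(x, "vol3d") && is.logical(x$values)

# mm coordinates of 0-based voxel indices (matrix or vector)
voxel_to_mm <- function(idx, geom) {
  idx <- rbind(idx)
  sweep(sweep(idx, 2, geom$spacing, `*`), 2, geom$origin, `+`)
}

mm_to_voxel <- function(pts, geom) {
  pts <- rbind(pts)
  round(sweep(sweep(pts, 2, geom$origin, `-`), 2, geom$spacing, `/`))
}

# ---------------------------------------------------------------------------
# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package is available in the supported dependency set, so the
# single-file uncompressed/gzipped .nii subset the pipeline needs is
# implemented here: 3D volumes, datatypes uint8/int16/int32/float32/float64,
# spacing from pixdim, origin from the sform translation. This is not a
# general NIfTI implementation (no qform rotation, no extensions).
# ---------------------------------------------------------------------------

.nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a volume as NIfTI-1
#'
#' Logical (mask) volumes are stored as uint8, numeric volumes as float32.
#' A diagonal sform carries spacing and origin.
#'
#' @param vol A [vol3d()] object.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  if (!inherits(vol, "vol3d")) vm_stop("vol must be a vol3d")
  d <- dim(vol$values)
  is_mask <- is.logical(vol$values)
  con <- .nii_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    r <- charToRaw(s)
    writeBin(c(r, raw(len - length(r))), con)
  }
  wi(348L, 4)                                   # sizeof_hdr
  wc("", 10); wc("", 18)                        # data_type, db_name
  wi(0L, 4); wi(0L, 2); wc("r", 1); wc("", 1)   # extents..dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)               # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent_p, intent_code
  wi(if (is_mask) 2L else 16L, 2)               # datatype
  wi(if (is_mask) 8L else 32L, 2)               # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, vol$spacing, 1, 1, 1, 1))             # pixdim[8]
  wf(352); wf(1); wf(0)                         # vox_offset, scl
  wi(0L, 2); wc("", 1); wc(rawToChar(as.raw(2L)), 1)  # slice_end/code, units=mm
  wf(c(0, 0, 0, 0))                             # cal_max..toffset
  wi(0L, 4); wi(0L, 4)                          # glmax, glmin
  wc("vesselmorph", 80); wc("", 24)             # descrip, aux_file
  wi(0L, 2); wi(1L, 2)                          # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))                       # quatern, qoffset
  wf(c(vol$spacing[1], 0, 0, vol$origin[1]))    # srow_x
  wf(c(0, vol$spacing[2], 0, vol$origin[2]))    # srow_y
  wf(c(0, 0, vol$spacing[3], vol$origin[3]))    # srow_z
  wc("", 16); wc("n+1", 4)                      # intent_name, magic
  writeBin(raw(4), con)                         # extension flag
  if (is_mask) {
    writeBin(as.integer(vol$values), con, size = 1, endian = "little")
  } else {
    writeBin(as.numeric(vol$values), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param mask Logical; if `TRUE` the data are returned as a logical mask.
#' @return A [vol3d()] object.
#' @export
read_nifti <- function(path, mask = FALSE) {
  if (!file.exists(path)) vm_stop("file not found: ", path)
  con <- .nii_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352)
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = "little")
  }
  if (rd(0, "integer", 1, 4) != 348L)
    vm_stop("not a little-endian NIfTI-1 file: ", path)
  dims <- rd(40, "integer", 8, 2)
  if (dims[1] < 3) vm_stop("expected a 3D volume in ", path)
  d <- dims[2:4]
  datatype <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "numeric", 8, 4)
  vox_offset <- rd(108, "numeric", 1, 4)
  scl_slope <- rd(112, "numeric", 1, 4)
  scl_inter <- rd(116, "numeric", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  origin <- c(0, 0, 0)
  if (sform_code > 0) {
    origin <- c(rd(280 + 12, "numeric", 1, 4), rd(296 + 12, "numeric", 1, 4),
                rd(312 + 12, "numeric", 1, 4))
  }
  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(d)
  vals <- switch(as.character(datatype),
    "2" = readBin(con, "integer", n = n, size = 1, signed = FALSE,
                  endian = "little"),
    "4" = readBin(con, "integer", n = n, size = 2, endian = "little"),
    "8" = readBin(con, "integer", n = n, size = 4, endian = "little"),
    "16" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n = n, size = 8, endian = "little"),
    vm_stop("unsupported NIfTI datatype code: ", datatype))
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  a <- array(if (mask) as.logical(vals) else as.numeric(vals), d)
  vol3d(a, spacing = abs(pixdim[2:4]), origin = origin)
}
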
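#' Time-ordered sequence of 3D image volumes
#'
#' Container for a cine acquisition: a list of 3D intensity arrays of one
#' common shape, the voxel spacing in millimetres, and the indices of the
#' reference (end-diastolic, default first) and end-systolic frames.
#' Frame indices are 1-based throughout the R interface; voxel coordinates
#' are 0-based, matching the half-open block convention used by the matcher.
#'
#' @param frames list of 3D numeric arrays with identical dimensions.
#' @param voxel_spacing numeric length-3 (or scalar) spacing in mm per voxel.
#' @param end_systolic_index 1-based index of the end-systolic frame.
#' @param reference_index 1-based index of the reference frame (default 1).
#' @return An object of class `volume_sequence`.
#' @export
volume_sequence <- function(frames, voxel_spacing = 0.96,
                            end_systolic_index = 1L,
                            reference_index = 1L) {
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- dim(frames[[1]])
  if (length(dims) != 3) stop("frames must be 3D arrays")
  for (f in frames) {
    if (!identical(dim(f), dims)) stop("all frames must share one shape")
  }
  voxel_spacing <- rep_len(as.numeric(voxel_spacing), 3L)
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  end_systolic_index <- as.integer(end_systolic_index)
  reference_index <- as.integer(reference_index)
  if (end_systolic_index < 1 || end_systolic_index > length(frames)) {
    stop("end_systolic_index out of range")
  }
  if (reference_index < 1 || reference_index > length(frames)) {
    stop("reference_index out of range")
  }
  structure(
    list(frames = frames, voxel_spacing = voxel_spacing,
         end_systolic_index = end_systolic_index,
         reference_index = reference_index),
    class = "volume_sequence")
}

#' @export
print.volume_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<volume_sequence> %d frames of %dx%dx%d voxels, spacing %s mm\n",
    length(x$frames), d[1], d[2], d[3],
    paste(signif(x$voxel_spacing, 4), collapse = "x")))
  cat(sprintf("  reference frame %d, end-systolic frame %d\n",
              x$reference_index, x$end_systolic_index))
  invisible(x)
}

#' @export
length.volume_sequence <- function(x) length(x$frames)

#' Convert between voxel and millimetre coordinates
#'
#' Geometry (meshes, landmarks, strain) is carried in millimetres; image
#' operations use 0-based voxel coordinates. The image origin sits at voxel
#' (0, 0, 0), so the conversion is a pure per-axis scaling that round-trips
#' exactly for integer voxel indices.
#'
#' @param pts numeric matrix (n x 3) or length-3 vector of coordinates.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @return matrix (n x 3) in the target unit.
#' @export
voxel_to_mm <- function(pts, spacing) {
  pts <- as_points(pts)
  spacing <- rep_len(as.numeric(spacing), 3L)
  sweep(pts, 2, spacing, `*`)
}

#' @rdname voxel_to_mm
#' @export
mm_to_voxel <- function(pts, spacing) {
  pts <- as_points(pts)
  spacing <- rep_len(as.numeric(spacing), 3L)
  sweep(pts, 2, spacing, `/`)
}

as_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3, byrow = TRUE)
  pts <- as.matrix(pts)
  if (ncol(pts) != 3) stop("points must have 3 columns")
  storage.mode(pts) <- "double"
  dimnames(pts) <- NULL
  pts
}
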
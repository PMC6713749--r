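#' Read a time series of 3D volumes from NIfTI
#'
#' Accepts either a single 4D NIfTI file (time on the 4th dimension) or a
#' character vector of per-frame 3D files (ordered as given). Voxel
#' spacing comes from the header; frames with mismatched shapes or
#' spacings are an error.
#'
#' @param paths one 4D NIfTI path or a vector of 3D NIfTI paths.
#' @param end_systolic_index,reference_index 1-based frame indices.
#' @return a [volume_sequence()].
#' @export
read_volume_sequence <- function(paths, end_systolic_index = 1L,
                                 reference_index = 1L) {
  imgs <- lapply(paths, RNifti::readNifti)
  frames <- list()
  spacing <- NULL
  for (img in imgs) {
    px <- RNifti::pixdim(img)[1:3]
    if (is.null(spacing)) {
      spacing <- px
    } else if (max(abs(px - spacing)) > 1e-6) {
      stop("frames have mismatched voxel spacing")
    }
    d <- dim(img)
    if (length(d) == 4) {
      for (t in seq_len(d[4])) {
        frames[[length(frames) + 1]] <- array(img[, , , t], d[1:3])
      }
    } else if (length(d) == 3) {
      frames[[length(frames) + 1]] <- array(as.numeric(img), d)
    } else {
      stop("NIfTI volumes must be 3D or 4D")
    }
  }
  volume_sequence(frames, spacing, end_systolic_index, reference_index)
}

#' Write a volume sequence as one 4D NIfTI file
#'
#' @param vols a [volume_sequence()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume_sequence <- function(vols, path) {
  stopifnot(inherits(vols, "volume_sequence"))
  d <- dim(vols$frames[[1]])
  arr <- array(NA_real_, c(d, length(vols$frames)))
  for (t in seq_along(vols$frames)) arr[, , , t] <- vols$frames[[t]]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vols$voxel_spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# CSV writers carry a unit/index-base declaration as a leading comment
# line; the readers skip comments.
write_csv_commented <- function(df, path, comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write / read control points as CSV
#'
#' Columns `frame, mx, my, mz, rx, ry, rz, cc, valid` in 0-based voxel
#' units; the unit declaration is kept in a leading comment line.
#'
#' @param cps a `control_points` tibble (a `frame` column is added when
#'   missing).
#' @param path file path.
#' @param frame frame index recorded in the file when `cps` lacks one.
#' @export
write_control_points <- function(cps, path, frame = NA_integer_) {
  df <- as.data.frame(cps)
  if (!"frame" %in% names(df)) df <- cbind(frame = frame, df)
  df <- df[, c("frame", "mx", "my", "mz", "rx", "ry", "rz", "cc", "valid")]
  write_csv_commented(df, path, "units: voxel (0-based indices)")
}

#' @rdname write_control_points
#' @export
read_control_points <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  out <- tibble::as_tibble(df)
  class(out) <- c("control_points", class(out))
  out
}

#' Write / read landmark trajectories as CSV
#'
#' Columns `landmark, frame, x, y, z` in millimetres (reference-image
#' space).
#'
#' @param lm a [landmark_trajectories()] tibble.
#' @param path file path.
#' @export
write_landmarks <- function(lm, path) {
  df <- as.data.frame(lm)[, c("landmark", "frame", "x", "y", "z")]
  write_csv_commented(df, path, "units: mm (reference-image space)")
}

#' @rdname write_landmarks
#' @param observer_id observer label attached on read.
#' @export
read_landmarks <- function(path, observer_id = NA_character_) {
  df <- utils::read.csv(path, comment.char = "#")
  landmark_trajectories(df, observer_id)
}

#' Write strain curves as CSV
#'
#' Per-frame aggregate directional strains and median eigenvalue series
#' (unitless strain).
#'
#' @param curves a [strain_curves()] tibble.
#' @param path file path.
#' @export
write_strain_curves <- function(curves, path) {
  write_csv_commented(as.data.frame(curves), path,
                      "units: unitless strain; frame indices 1-based")
}

#' Write per-node strain tensors as CSV
#'
#' One row per node and frame: the six independent tensor components, the
#' directional strains and the sorted eigenvalues.
#'
#' @param fields per-frame `strain_field` list from [strain_fields()].
#' @param dirs a [local_directions()].
#' @param path file path.
#' @export
write_strain_tensors <- function(fields, dirs, path) {
  rows <- lapply(fields, function(f) {
    m <- dim(f$E)[3]
    ev <- eigen_analysis(f)$values
    el <- project_strain(f$E, matrix(dirs$L, m, 3, byrow = TRUE))
    ec <- project_strain(f$E, dirs$C)
    er <- project_strain(f$E, dirs$R_dir)
    tibble::tibble(
      frame = f$frame, node = seq_len(m),
      Exx = f$E[1, 1, ], Eyy = f$E[2, 2, ], Ezz = f$E[3, 3, ],
      Exy = f$E[1, 2, ], Exz = f$E[1, 3, ], Eyz = f$E[2, 3, ],
      E_L = el, E_C = ec, E_R = er,
      eig1 = ev[, 1], eig2 = ev[, 2], eig3 = ev[, 3])
  })
  write_csv_commented(as.data.frame(dplyr::bind_rows(rows)), path,
                      "units: unitless strain; frame/node indices 1-based")
}
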
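#' Track a volume sequence and fit per-frame LWM transforms
#'
#' For each non-reference frame, runs [hierarchical_match()] of the frame
#' (moving) against the reference frame and fits two LWM transforms from
#' the same correspondences: current-to-reference (used for the strain
#' gradient) and reference-to-current (used for forward tracking). By
#' default only pyramid-validated correspondences enter the fit;
#' non-displaced sentinel pairs mark failed matches and carry no
#' displacement information. Frames yielding fewer usable points than the
#' polynomial basis fall back to identity transforms with a warning.
#'
#' @param vols a [volume_sequence()].
#' @param params a [hierarchy_params()].
#' @param n LWM local neighbourhood size (default 100; capped at the
#'   number of available control points with a warning).
#' @param include_invalid also fit on non-displaced (failed) pairs.
#' @return list of class `tracking_result`: per-frame `control_points`
#'   tibbles, `inverse` (current-to-reference) and `forward`
#'   (reference-to-current) transform lists, and the input metadata.
#' @export
track_sequence <- function(vols, params = hierarchy_params(), n = 100L,
                           include_invalid = FALSE) {
  stopifnot(inherits(vols, "volume_sequence"))
  refi <- vols$reference_index
  ref <- vols$frames[[refi]]
  n_frames <- length(vols$frames)
  cps <- vector("list", n_frames)
  inv <- vector("list", n_frames)
  fwd <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    if (t == refi) {
      inv[[t]] <- lwm_identity("moving_to_reference")
      fwd[[t]] <- lwm_identity("reference_to_moving")
      next
    }
    cp <- hierarchical_match(vols$frames[[t]], ref, params)
    cps[[t]] <- cp
    use <- if (include_invalid) cp else cp[cp$valid, , drop = FALSE]
    n_use <- nrow(dplyr::distinct(use[, c("mx", "my", "mz")]))
    if (n_use < 10L) {
      warning(sprintf(
        "frame %d: only %d usable control points; identity transform",
        t, n_use))
      inv[[t]] <- lwm_identity("moving_to_reference")
      fwd[[t]] <- lwm_identity("reference_to_moving")
      next
    }
    n_t <- n
    if (n_use < n) {
      warning(sprintf(
        "frame %d: %d control points < n = %d; shrinking neighbourhood",
        t, n_use, n))
      n_t <- n_use
    }
    inv[[t]] <- lwm_fit(use, n = n_t, direction = "moving_to_reference")
    fwd[[t]] <- lwm_fit(use, n = n_t, direction = "reference_to_moving")
  }
  structure(list(control_points = cps, inverse = inv, forward = fwd,
                 params = params, n = n,
                 spacing = vols$voxel_spacing,
                 end_systolic_index = vols$end_systolic_index,
                 reference_index = refi),
            class = "tracking_result")
}

#' Full strain pipeline over a tracked sequence
#'
#' Tracks the mesh forward through every frame, evaluates per-node strain
#' tensors from the current-to-reference transforms, and aggregates the
#' directional strain and eigenvalue curves.
#'
#' @param tracking a [track_sequence()] result.
#' @param mesh the reference-frame [surface_mesh()] (mm).
#' @param h finite-difference step in voxels.
#' @param aggregation curve aggregation, `"median"` or `"mean"`.
#' @return list of class `strain_result`: `tracked` ([track_mesh()]),
#'   `fields` (per-frame strain tensors), `dirs`, `curves`
#'   ([strain_curves()]).
#' @export
strain_pipeline <- function(tracking, mesh, h = 2,
                            aggregation = "median") {
  stopifnot(inherits(tracking, "tracking_result"))
  tracked <- track_mesh(mesh, tracking$forward, tracking$spacing)
  fields <- strain_fields(tracked, tracking$inverse, h)
  dirs <- local_directions(mesh)
  curves <- strain_curves(fields, dirs, aggregation)
  structure(list(tracked = tracked, fields = fields, dirs = dirs,
                 curves = curves), class = "strain_result")
}

#' Track landmark points through the fitted transforms
#'
#' Maps reference-frame landmark positions through each frame's forward
#' transform, producing trajectories in mm in the pipeline's CSV schema.
#'
#' @param tracking a [track_sequence()] result.
#' @param points reference landmark positions in voxel coordinates
#'   (m x 3).
#' @return a [landmark_trajectories()] tibble (mm).
#' @export
track_landmarks <- function(tracking, points) {
  stopifnot(inherits(tracking, "tracking_result"))
  points <- as_points(points)
  sp <- tracking$spacing
  rows <- lapply(seq_along(tracking$forward), function(t) {
    tr <- tracking$forward[[t]]
    p <- if (inherits(tr, "lwm_identity")) points else lwm_evaluate(tr, points)
    p <- voxel_to_mm(p, sp)
    tibble::tibble(landmark = seq_len(nrow(points)), frame = t,
                   x = p[, 1], y = p[, 2], z = p[, 3])
  })
  landmark_trajectories(dplyr::bind_rows(rows), observer_id = "tracked")
}
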
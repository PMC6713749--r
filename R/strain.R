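#' Track mesh nodes through the cardiac cycle
#'
#' Forward tracking from the reference (end-diastolic) mesh: the node
#' position at frame t is the reference position mapped through that
#' frame's reference-to-current LWM transform. The reference frame itself
#' uses the identity. Transforms operate in voxel coordinates; mesh
#' geometry is millimetres, so positions are converted with the voxel
#' spacing on the way in and out.
#'
#' @param mesh a [surface_mesh()] (reference frame, mm).
#' @param forward_transforms list of per-frame transforms
#'   (`lwm_transform` with direction `reference_to_moving`, or
#'   `lwm_identity`); one entry per frame, reference frame included.
#' @param spacing voxel spacing in mm.
#' @return object of class `tracked_mesh`: `positions` array
#'   (nodes x 3 x frames) in mm, plus the input mesh.
#' @export
track_mesh <- function(mesh, forward_transforms, spacing = 0.96) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n_frames <- length(forward_transforms)
  n <- nrow(mesh$nodes)
  pos <- array(NA_real_, c(n, 3, n_frames))
  ref_vox <- mm_to_voxel(mesh$nodes, spacing)
  for (t in seq_len(n_frames)) {
    tr <- forward_transforms[[t]]
    if (inherits(tr, "lwm_identity")) {
      pos[, , t] <- mesh$nodes
      next
    }
    stopifnot(inherits(tr, "lwm_transform"))
    if (tr$direction != "reference_to_moving") {
      stop("forward tracking needs reference_to_moving transforms")
    }
    pos[, , t] <- voxel_to_mm(lwm_evaluate(tr, ref_vox), spacing)
  }
  structure(list(positions = pos, mesh = mesh, spacing = spacing),
            class = "tracked_mesh")
}

#' Displacement gradient of the motion at current-frame points
#'
#' The displacement of a current-frame point x is u(x) = x - X(x), where
#' X(x) is its reference position under the current-to-reference
#' (inverse) transform. U = du/dx is evaluated by central finite
#' differences of the smooth LWM map, taken with respect to the deformed
#' (current-frame) coordinates - the reading under which F = (I - U)^-1
#' recovers the true deformation gradient.
#'
#' The default step h = 2 voxels equals the control-point pitch of the
#' matching hierarchy: displacement models fitted to integer-voxel matches
#' carry sub-pitch quantization ripple, and a step of one pitch averages
#' across it, while the O(h^2) truncation error stays negligible for
#' fields that are smooth at the scale of the ventricular wall.
#'
#' @param inverse_transform `lwm_transform` with direction
#'   `moving_to_reference` (current frame -> reference), in voxel
#'   coordinates, or `lwm_identity`.
#' @param points current-frame points, mm (m x 3).
#' @param spacing voxel spacing in mm.
#' @param h finite-difference step in voxels (default 2).
#' @return array (3 x 3 x m) of displacement gradients (unitless).
#' @export
displacement_gradient <- function(inverse_transform, points,
                                  spacing = 0.96, h = 2) {
  points <- as_points(points)
  m <- nrow(points)
  if (inherits(inverse_transform, "lwm_identity")) {
    return(array(0, c(3, 3, m)))
  }
  stopifnot(inherits(inverse_transform, "lwm_transform"))
  if (inverse_transform$direction != "moving_to_reference") {
    stop("displacement gradient needs a moving_to_reference transform")
  }
  spacing <- rep_len(as.numeric(spacing), 3L)
  # map mm query -> voxel -> reference voxel -> reference mm
  map_mm <- function(q) {
    voxel_to_mm(lwm_evaluate(inverse_transform, mm_to_voxel(q, spacing)),
                spacing)
  }
  U <- array(0, c(3, 3, m))
  for (j in 1:3) {
    step <- rep(0, 3); step[j] <- h * spacing[j]
    plus <- sweep(points, 2, step, `+`)
    minus <- sweep(points, 2, step, `-`)
    # u = x - X(x); dU/dx_j per component
    dudx <- ((plus - map_mm(plus)) - (minus - map_mm(minus))) /
      (2 * h * spacing[j])
    U[, j, ] <- t(dudx)
  }
  U
}

#' Deformation gradient from the displacement gradient
#'
#' `F = (I - U)^-1`, mapping reference line elements to the deformed
#' configuration.
#'
#' @param U 3x3 matrix, or 3x3xm array.
#' @return matching 3x3 matrix or array.
#' @export
deformation_gradient <- function(U) {
  one <- function(u, k) {
    a <- diag(3) - u
    rc <- rcond(a)
    if (!is.finite(rc) || rc < 1e-12) {
      stop(sprintf(
        "singular (I - U) at node %d (reciprocal condition %.3g)", k, rc))
    }
    solve(a)
  }
  if (length(dim(U)) == 3) {
    out <- array(NA_real_, dim(U))
    for (k in seq_len(dim(U)[3])) out[, , k] <- one(U[, , k], k)
    out
  } else {
    one(U, 1L)
  }
}

#' Lagrange (Green-Lagrange) strain tensor
#'
#' `E = (F^T F - I) / 2`; zero exactly when F is a rotation (rigid motion).
#' The result is symmetrised against rounding.
#'
#' @param F 3x3 deformation gradient, or 3x3xm array.
#' @return matching 3x3 matrix or array.
#' @export
lagrange_strain <- function(F) {
  one <- function(f) {
    e <- (t(f) %*% f - diag(3)) / 2
    (e + t(e)) / 2
  }
  if (length(dim(F)) == 3) {
    out <- array(NA_real_, dim(F))
    for (k in seq_len(dim(F)[3])) out[, , k] <- one(F[, , k])
    out
  } else {
    one(F)
  }
}

#' Local anatomical direction frame of an LV mesh
#'
#' The longitudinal direction L is the unit vector from the apex to the
#' mitral-valve centre (one global vector). Per node, the radial direction
#' is the outward node normal with its longitudinal component removed,
#' `R = M - (M . L) L`, normalised; the circumferential direction is
#' `C = L x R`. Nodes whose normal is (numerically) parallel to L have no
#' defined radial direction and are flagged for exclusion from aggregates.
#'
#' @param mesh a [surface_mesh()].
#' @return list of class `local_directions`: `L` (length 3), `R_dir` and
#'   `C` (n x 3), `defined` (logical n).
#' @export
local_directions <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  L <- mesh$mitral_center - mesh$apex
  L <- L / sqrt(sum(L^2))
  M <- mesh$normals
  proj <- as.numeric(M %*% L)
  R_dir <- M - outer(proj, L)
  len <- sqrt(rowSums(R_dir^2))
  defined <- len >= 1e-9
  R_dir <- R_dir / pmax(len, 1e-12)
  Lm <- matrix(L, nrow(M), 3, byrow = TRUE)
  C <- cross3(Lm, R_dir)
  clen <- sqrt(rowSums(C^2))
  C <- C / pmax(clen, 1e-12)
  R_dir[!defined, ] <- NA_real_
  C[!defined, ] <- NA_real_
  structure(list(L = L, R_dir = R_dir, C = C, defined = defined),
            class = "local_directions")
}

#' Project a strain tensor on a direction
#'
#' `E_p = p^T E p` for a unit direction p: the normal strain along p.
#'
#' @param E 3x3 symmetric strain tensor, or 3x3xm array.
#' @param p unit direction, length 3 (or m x 3, one direction per tensor).
#' @return scalar or numeric vector of projected strains.
#' @export
project_strain <- function(E, p) {
  if (length(dim(E)) == 3) {
    m <- dim(E)[3]
    p <- if (is.null(dim(p))) {
      matrix(p, m, 3, byrow = TRUE)
    } else {
      as_points(p)
    }
    out <- numeric(m)
    for (k in seq_len(m)) out[k] <- project_strain(E[, , k], p[k, ])
    return(out)
  }
  p <- as.numeric(p)
  if (anyNA(p)) return(NA_real_)
  if (abs(sqrt(sum(p^2)) - 1) > 1e-9) stop("direction p must be unit length")
  as.numeric(t(p) %*% E %*% p)
}

#' Per-frame strain tensors at tracked mesh nodes
#'
#' Evaluates U, F and E at every node's current-frame position for each
#' frame, from that frame's current-to-reference transform.
#'
#' @param tracked a [track_mesh()] result.
#' @param inverse_transforms list of per-frame `moving_to_reference`
#'   transforms (reference frame entry may be `lwm_identity`).
#' @param h finite-difference step in voxels.
#' @return list of per-frame `strain_field` objects (fields `U`, `F`, `E`:
#'   3x3xn arrays; `frame`).
#' @export
strain_fields <- function(tracked, inverse_transforms, h = 2) {
  stopifnot(inherits(tracked, "tracked_mesh"))
  n_frames <- dim(tracked$positions)[3]
  stopifnot(length(inverse_transforms) == n_frames)
  lapply(seq_len(n_frames), function(t) {
    x <- tracked$positions[, , t]
    U <- displacement_gradient(inverse_transforms[[t]], x,
                               tracked$spacing, h)
    F <- deformation_gradient(U)
    E <- lagrange_strain(F)
    structure(list(U = U, F = F, E = E, frame = t), class = "strain_field")
  })
}

#' Sorted eigenvalues of a strain field
#'
#' Each node's symmetric strain tensor yields three real eigenvalues
#' (principal strains), sorted ascending; medians are taken per sorted
#' position across nodes.
#'
#' @param field a `strain_field` (or bare 3x3xm array of symmetric
#'   tensors).
#' @param tol asymmetry tolerance.
#' @return list with `values` (m x 3, ascending) and `medians` (length 3).
#' @export
eigen_analysis <- function(field, tol = 1e-8) {
  E <- if (inherits(field, "strain_field")) field$E else field
  if (length(dim(E)) == 2) E <- array(E, c(3, 3, 1))
  m <- dim(E)[3]
  vals <- matrix(NA_real_, m, 3)
  for (k in seq_len(m)) {
    e <- E[, , k]
    if (anyNA(e)) next
    if (max(abs(e - t(e))) > tol) {
      stop(sprintf("strain tensor %d is not symmetric", k))
    }
    vals[k, ] <- sort(eigen(e, symmetric = TRUE, only.values = TRUE)$values)
  }
  list(values = vals,
       medians = apply(vals, 2, stats::median, na.rm = TRUE))
}

#' Aggregate strain curves over the cardiac cycle
#'
#' Per frame, the longitudinal / circumferential / radial strains are the
#' aggregate (median by default) over mesh nodes of the strain tensor
#' projected on the local direction frame; the eigenvalue series are the
#' per-sorted-position medians of the nodal principal strains. Nodes with
#' an undefined radial direction are excluded from the directional
#' aggregates.
#'
#' @param fields list of per-frame `strain_field`s from [strain_fields()].
#' @param dirs a [local_directions()] for the reference mesh.
#' @param aggregation `"median"` (default) or `"mean"`.
#' @return tibble of class `strain_curves`: `frame`, `E_L`, `E_C`, `E_R`,
#'   `eig1`..`eig3`, `aggregation`.
#' @export
strain_curves <- function(fields, dirs, aggregation = c("median", "mean")) {
  aggregation <- match.arg(aggregation)
  aggfun <- if (aggregation == "median") {
    function(x) stats::median(x, na.rm = TRUE)
  } else {
    function(x) mean(x, na.rm = TRUE)
  }
  stopifnot(inherits(dirs, "local_directions"))
  ok <- dirs$defined
  if (!any(ok)) stop("no nodes with a defined direction frame")
  n_nodes <- length(ok)
  rows <- lapply(fields, function(f) {
    stopifnot(dim(f$E)[3] == n_nodes)
    Eok <- f$E[, , ok, drop = FALSE]
    el <- project_strain(Eok, matrix(dirs$L, sum(ok), 3, byrow = TRUE))
    ec <- project_strain(Eok, dirs$C[ok, , drop = FALSE])
    er <- project_strain(Eok, dirs$R_dir[ok, , drop = FALSE])
    ev <- eigen_analysis(f)
    tibble::tibble(frame = f$frame, E_L = aggfun(el), E_C = aggfun(ec),
                   E_R = aggfun(er), eig1 = ev$medians[1],
                   eig2 = ev$medians[2], eig3 = ev$medians[3])
  })
  out <- dplyr::bind_rows(rows)
  out$aggregation <- aggregation
  class(out) <- c("strain_curves", class(out))
  out
}
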
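#' Specification of a synthetic tagged-LV phantom
#'
#' A half-ellipsoidal left-ventricle-like shell carrying a 3D tag-grid
#' intensity pattern, deformed over the cardiac cycle by an analytic,
#' invertible motion that peaks at the end-systolic frame. The motion
#' composes, in shell-centred cylindrical coordinates about the long axis:
#' a twist scaled linearly from apex to base, a radial contraction graded
#' across the wall (inner wall contracts more, so the wall thickens), and
#' a longitudinal shortening towards the base. The amplitude profile a(t)
#' rises as sin^2 to 1 at end-systole and decays symmetrically to 0.1 at
#' the final frame.
#'
#' All geometry is in 0-based voxel coordinates; `voxel_spacing` converts
#' to millimetres. Frame indices are 1-based.
#'
#' @param grid_shape volume extents in voxels (default 64^3).
#' @param voxel_spacing mm per voxel (default 0.96, isotropic).
#' @param center base-plane centre of the shell (voxel coords); the long
#'   axis is +z, the apex sits at `center - c(0, 0, outer_semiaxes[3])`.
#' @param outer_semiaxes outer shell semi-axes in voxels.
#' @param inner_fraction inner-to-outer radius ratio of the wall.
#' @param tag_period tag-grid period in voxels (default 7).
#' @param tag_period_minor period of a secondary tag harmonic (default 5).
#'   A single cosine-product grid is exactly invariant under simultaneous
#'   half-period shifts along two axes; the incommensurate second harmonic
#'   removes that translation degeneracy so block matches are unambiguous.
#' @param tag_minor_weight weight of the secondary harmonic in the tag
#'   pattern (0 disables it, leaving a pure single-period grid).
#' @param tag_contrast,background_level intensity units.
#' @param n_frames,end_systolic_index frames in the cycle (1-based index
#'   of end-systole).
#' @param twist_deg apex-to-base twist at peak amplitude, degrees.
#' @param shortening longitudinal shortening factor at peak amplitude.
#' @param radial_contraction inner-wall radial contraction at peak
#'   amplitude.
#' @param thickening transmural grading of the radial contraction in
#'   [0, 1]: the outer wall contracts by `(1 - thickening)` times the
#'   inner-wall amount, so the wall thickens during systole.
#' @param fade_rate per-frame geometric decay of tag contrast (0 = off).
#' @param noise_sd additive Gaussian noise, intensity units.
#' @param seed integer seed controlling the noise.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_spacing = 0.96,
                         center = c(32, 32, 40),
                         outer_semiaxes = c(24, 24, 26),
                         inner_fraction = 0.58,
                         tag_period = 7,
                         tag_period_minor = 5,
                         tag_minor_weight = 0.35,
                         tag_contrast = 40,
                         background_level = 60,
                         n_frames = 10L,
                         end_systolic_index = 6L,
                         twist_deg = 8,
                         shortening = 0.10,
                         radial_contraction = 0.10,
                         thickening = 0.5,
                         fade_rate = 0,
                         noise_sd = 1,
                         seed = 1L) {
  stopifnot(inner_fraction > 0, inner_fraction < 1,
            n_frames >= 2, end_systolic_index >= 1,
            end_systolic_index <= n_frames,
            fade_rate >= 0, fade_rate < 1, tag_period > 0)
  structure(
    list(grid_shape = as.integer(grid_shape),
         voxel_spacing = voxel_spacing, center = as.numeric(center),
         outer_semiaxes = as.numeric(outer_semiaxes),
         inner_fraction = inner_fraction, tag_period = tag_period,
         tag_period_minor = tag_period_minor,
         tag_minor_weight = tag_minor_weight,
         tag_contrast = tag_contrast,
         background_level = background_level,
         n_frames = as.integer(n_frames),
         end_systolic_index = as.integer(end_systolic_index),
         twist_deg = twist_deg, shortening = shortening,
         radial_contraction = radial_contraction,
         thickening = thickening, fade_rate = fade_rate,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec")
}

# amplitude profile: 0 at the reference, 1 at end-systole, 0.1 at the end
phantom_amplitude <- function(spec) {
  tau <- seq_len(spec$n_frames) - 1
  es <- spec$end_systolic_index - 1
  tend <- spec$n_frames - 1
  a <- numeric(spec$n_frames)
  rising <- tau <= es
  a[rising] <- sin(pi * tau[rising] / (2 * max(es, 1)))^2
  if (any(!rising)) {
    a[!rising] <- 0.1 + 0.9 *
      sin(pi * (tend - tau[!rising]) / (2 * max(tend - es, 1)))^2
  }
  a
}

#' Analytic phantom deformation with exact oracles
#'
#' Builds the forward map (reference to frame t), its inverse, and the
#' analytic deformation gradient and Lagrange strain for the phantom
#' motion. Besides the cardiac motion family, rigid, pure-scaling and
#' pure-translation families are available for validation fixtures.
#'
#' @param spec a [phantom_spec()].
#' @param type motion family: `"cardiac"` (default), `"rigid"`, `"scale"`,
#'   `"translation"`.
#' @param rotation_deg,translation,scale_factors parameters of the rigid /
#'   scale / translation families; the rigid rotation is about the long
#'   axis through the shell centre, translation is in voxels.
#' @return object of class `phantom_truth` with functions
#'   `forward(X, t)`, `inverse(x, t)`, `F(X, t)` (3x3xn array),
#'   `E(X, t)`, predicate `in_shell(X)`, and the amplitude profile.
#' @export
make_deformation <- function(spec, type = c("cardiac", "rigid", "scale",
                                            "translation"),
                             rotation_deg = 10,
                             translation = c(2.3, -1.7, 3.1),
                             scale_factors = c(0.9, 0.9, 0.9)) {
  type <- match.arg(type)
  a <- phantom_amplitude(spec)
  ctr <- spec$center
  Rz <- spec$outer_semiaxes[3]
  r_out <- spec$outer_semiaxes[1]
  r_in <- r_out * spec$inner_fraction
  twist <- spec$twist_deg * pi / 180
  cr <- spec$radial_contraction
  kap <- spec$thickening
  if (cr >= 1 || cr < 0 || kap < 0 || kap > 1) {
    stop("radial map parameters make the deformation non-invertible")
  }

  if (type == "cardiac") {
    fwd <- function(X, t) {
      X <- as_points(X)
      at <- a[t]
      dx <- X[, 1] - ctr[1]; dy <- X[, 2] - ctr[2]
      zrel <- X[, 3] - ctr[3]
      r <- sqrt(dx^2 + dy^2)
      th <- atan2(dy, dx)
      g <- pmin(pmax(1 + zrel / Rz, 0), 1)
      w <- pmin(pmax((r - r_in) / (r_out - r_in), 0), 1)
      th2 <- th + at * twist * g
      r2 <- r * (1 - at * cr * (1 - kap * w))
      z2 <- zrel * (1 - at * spec$shortening)
      cbind(ctr[1] + r2 * cos(th2), ctr[2] + r2 * sin(th2),
            ctr[3] + z2)
    }
    inv <- function(x, t) {
      x <- as_points(x)
      at <- a[t]
      dx <- x[, 1] - ctr[1]; dy <- x[, 2] - ctr[2]
      zrel <- (x[, 3] - ctr[3]) / (1 - at * spec$shortening)
      r2 <- sqrt(dx^2 + dy^2)
      th2 <- atan2(dy, dx)
      # fixed-point inversion of the graded radial scaling
      r <- r2
      for (k in seq_len(50)) {
        w <- pmin(pmax((r - r_in) / (r_out - r_in), 0), 1)
        rn <- r2 / (1 - at * cr * (1 - kap * w))
        if (max(abs(rn - r)) < 1e-10) { r <- rn; break }
        r <- rn
      }
      g <- pmin(pmax(1 + zrel / Rz, 0), 1)
      th <- th2 - at * twist * g
      cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th), ctr[3] + zrel)
    }
  } else if (type == "rigid") {
    ang <- rotation_deg * pi / 180
    R <- matrix(c(cos(ang), sin(ang), 0,
                  -sin(ang), cos(ang), 0,
                  0, 0, 1), 3, 3)
    d <- as.numeric(translation)
    fwd <- function(X, t) {
      X <- as_points(X)
      at <- a[t]
      Rt <- matrix(c(cos(ang * at), sin(ang * at), 0,
                     -sin(ang * at), cos(ang * at), 0, 0, 0, 1), 3, 3)
      sweep(sweep(X, 2, ctr) %*% t(Rt), 2, ctr + at * d, `+`)
    }
    inv <- function(x, t) {
      x <- as_points(x)
      at <- a[t]
      Rt <- matrix(c(cos(ang * at), sin(ang * at), 0,
                     -sin(ang * at), cos(ang * at), 0, 0, 0, 1), 3, 3)
      sweep(sweep(x, 2, ctr + at * d) %*% Rt, 2, ctr, `+`)
    }
  } else if (type == "scale") {
    s <- as.numeric(scale_factors)
    fwd <- function(X, t) {
      X <- as_points(X)
      lam <- 1 + a[t] * (s - 1)
      sweep(sweep(sweep(X, 2, ctr), 2, lam, `*`), 2, ctr, `+`)
    }
    inv <- function(x, t) {
      x <- as_points(x)
      lam <- 1 + a[t] * (s - 1)
      sweep(sweep(sweep(x, 2, ctr), 2, lam, `/`), 2, ctr, `+`)
    }
  } else {
    d <- as.numeric(translation)
    fwd <- function(X, t) sweep(as_points(X), 2, a[t] * d, `+`)
    inv <- function(x, t) sweep(as_points(x), 2, a[t] * d, `-`)
  }

  Ffun <- function(X, t, h = 1e-4) {
    # central differences of the forward map; O(h^2) truncation
    X <- as_points(X)
    n <- nrow(X)
    Fa <- array(0, c(3, 3, n))
    for (j in 1:3) {
      step <- rep(0, 3); step[j] <- h
      plus <- fwd(sweep(X, 2, step, `+`), t)
      minus <- fwd(sweep(X, 2, step, `-`), t)
      Fa[, j, ] <- t((plus - minus) / (2 * h))
    }
    Fa
  }
  Efun <- function(X, t, h = 1e-4) lagrange_strain(Ffun(X, t, h))

  in_shell <- function(X) {
    X <- as_points(X)
    dx <- sweep(X, 2, ctr)
    qo <- sqrt((dx[, 1] / spec$outer_semiaxes[1])^2 +
               (dx[, 2] / spec$outer_semiaxes[2])^2 +
               (dx[, 3] / spec$outer_semiaxes[3])^2)
    fi <- spec$inner_fraction
    qo <= 1 & qo >= fi & dx[, 3] <= 0
  }

  structure(list(spec = spec, type = type, forward = fwd, inverse = inv,
                 F = Ffun, E = Efun, in_shell = in_shell, amplitude = a),
            class = "phantom_truth")
}

#' Render the phantom image frames
#'
#' The reference frame samples `background + contrast * prod(cos(2 pi
#' X_axis / period))` inside the shell (uniform background outside). Each
#' later frame is rendered by backward mapping: the reference volume is
#' sampled with trilinear interpolation at the inverse-mapped voxel
#' positions, the tag deviation from background is attenuated by the fade
#' factor, and seeded Gaussian noise is added last.
#'
#' @param spec a [phantom_spec()].
#' @param truth a [make_deformation()] result for the same spec.
#' @return a [volume_sequence()].
#' @export
render_frames <- function(spec, truth) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(truth, "phantom_truth"))
  d <- spec$grid_shape
  gx <- seq_len(d[1]) - 1; gy <- seq_len(d[2]) - 1; gz <- seq_len(d[3]) - 1
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  grid_at <- function(period) {
    cos(2 * pi * pts[, 1] / period) *
      cos(2 * pi * pts[, 2] / period) *
      cos(2 * pi * pts[, 3] / period)
  }
  w2 <- spec$tag_minor_weight %||% 0
  tag <- spec$tag_contrast * ((1 - w2) * grid_at(spec$tag_period) +
    if (w2 > 0) w2 * grid_at(spec$tag_period_minor) else 0)
  mask <- truth$in_shell(pts)
  ref <- rep(spec$background_level, nrow(pts))
  ref[mask] <- ref[mask] + tag[mask]
  ref_arr <- array(ref, d)

  frames <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    if (t == 1) {
      img <- ref
    } else {
      src <- truth$inverse(pts, t)
      img <- cpp_trilinear(as.double(ref_arr), d, src,
                           spec$background_level)
      fade <- (1 - spec$fade_rate)^(t - 1)
      img <- spec$background_level + fade * (img - spec$background_level)
    }
    if (spec$noise_sd > 0) {
      img <- img + withr::with_seed(
        spec$seed + t,
        stats::rnorm(length(img), sd = spec$noise_sd))
    }
    frames[[t]] <- array(img, d)
  }
  volume_sequence(frames, spec$voxel_spacing,
                  end_systolic_index = spec$end_systolic_index,
                  reference_index = 1L)
}

#' Reference mid-wall mesh of the phantom
#'
#' Triangulated mid-wall half-ellipsoid (between the inner and outer shell
#' surfaces) in millimetres, with apex and mitral-centre anchors.
#'
#' @param spec a [phantom_spec()].
#' @param n_theta,n_psi angular / long-axis resolution of the node grid.
#' @param base_margin distance (voxels) by which the basal node ring stays
#'   below the open base plane. Nodes on the rim itself sit at the edge of
#'   the imaged shell, where any image-derived displacement model is
#'   extrapolating; a real segmented LV mesh is likewise clipped inside
#'   the imaged volume.
#' @return a [surface_mesh()].
#' @export
phantom_mesh <- function(spec, n_theta = 40L, n_psi = 12L,
                         base_margin = 2.5) {
  mid <- spec$outer_semiaxes * (1 + spec$inner_fraction) / 2
  ctr <- spec$center
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ps_max <- acos(min(1, base_margin / mid[3]))
  ps <- seq(pi / (n_psi + 1), ps_max, length.out = n_psi)
  grid <- expand.grid(th = th, ps = ps)
  nodes <- cbind(
    ctr[1] + mid[1] * sin(grid$ps) * cos(grid$th),
    ctr[2] + mid[2] * sin(grid$ps) * sin(grid$th),
    ctr[3] - mid[3] * cos(grid$ps))
  apex_node <- c(ctr[1], ctr[2], ctr[3] - mid[3])
  nodes <- rbind(nodes, apex_node)
  n_apex <- nrow(nodes)
  idx <- function(i, j) (j - 1) * n_theta + i  # i in theta, j in psi
  tris <- list()
  for (j in seq_len(n_psi - 1)) {
    for (i in seq_len(n_theta)) {
      i2 <- if (i == n_theta) 1L else i + 1L
      tris[[length(tris) + 1]] <- c(idx(i, j), idx(i2, j), idx(i, j + 1))
      tris[[length(tris) + 1]] <- c(idx(i2, j), idx(i2, j + 1), idx(i, j + 1))
    }
  }
  for (i in seq_len(n_theta)) {  # apex fan on the first ring
    i2 <- if (i == n_theta) 1L else i + 1L
    tris[[length(tris) + 1]] <- c(n_apex, idx(i2, 1), idx(i, 1))
  }
  tris <- do.call(rbind, tris)
  sp <- spec$voxel_spacing
  surface_mesh(voxel_to_mm(nodes, sp), tris,
               apex = voxel_to_mm(ctr - c(0, 0, spec$outer_semiaxes[3]),
                                  sp)[1, ],
               mitral_center = voxel_to_mm(ctr, sp)[1, ])
}

#' Mid-wall landmark set of the phantom
#'
#' Twelve landmarks: one per anterior / lateral / posterior / septal wall
#' position at basal, mid-ventricular and apical levels, placed on the
#' mid-wall surface (the layout used for manual landmarking of LV walls).
#'
#' @param spec a [phantom_spec()].
#' @return matrix (12 x 3) of reference positions in voxel coordinates.
#' @export
phantom_landmarks <- function(spec) {
  mid <- spec$outer_semiaxes * (1 + spec$inner_fraction) / 2
  ctr <- spec$center
  ps_levels <- c(apical = 0.30, mid = 0.55, basal = 0.80) * pi / 2
  th_levels <- c(0, 0.5, 1, 1.5) * pi
  g <- expand.grid(th = th_levels, ps = ps_levels)
  cbind(ctr[1] + mid[1] * sin(g$ps) * cos(g$th),
        ctr[2] + mid[2] * sin(g$ps) * sin(g$th),
        ctr[3] - mid[3] * cos(g$ps))
}

#' Export exact trajectories and strain oracles
#'
#' Evaluates the analytic deformation at requested reference points for
#' every frame: exact trajectories (in mm) in the same schema the tracking
#' pipeline emits, and exact Lagrange strain tensors. Points outside the
#' shell are flagged.
#'
#' @param truth a [make_deformation()] result.
#' @param points reference points in voxel coordinates (m x 3); defaults
#'   to [phantom_landmarks()].
#' @return list with `trajectories` (tibble: landmark, frame, x, y, z in
#'   mm, `in_shell`) and `strain` (list of 3x3xm arrays per frame).
#' @export
export_truth <- function(truth, points = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  if (is.null(points)) points <- phantom_landmarks(spec)
  points <- as_points(points)
  inside <- truth$in_shell(points)
  if (!all(inside)) {
    warning(sprintf("%d point(s) outside the phantom shell",
                    sum(!inside)))
  }
  sp <- spec$voxel_spacing
  traj <- lapply(seq_len(spec$n_frames), function(t) {
    p <- voxel_to_mm(truth$forward(points, t), sp)
    tibble::tibble(landmark = seq_len(nrow(points)), frame = t,
                   x = p[, 1], y = p[, 2], z = p[, 3],
                   in_shell = inside)
  })
  strain <- lapply(seq_len(spec$n_frames),
                   function(t) truth$E(points, t))
  list(trajectories = dplyr::bind_rows(traj), strain = strain)
}
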
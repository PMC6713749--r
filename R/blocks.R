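#' Parameters of the matching hierarchy
#'
#' The matcher decomposes the moving image into nested cubic blocks:
#' templates of edge `t`, segments of `t/2`, chunks of `t/4` and windows of
#' `t/8` voxels. `t` must be divisible by 8. Templates are searched over the
#' reference within `search_radius` voxels of their original position
#' (`Inf` sweeps the whole image); each child level is searched strictly
#' inside its parent's matched block. Pyramid validation accepts a segment
#' or chunk match only when every overlapping screen block agrees with its
#' displacement within `pyramid_agreement_tol` voxels.
#'
#' @param t template edge length in voxels, divisible by 8 (default 16).
#' @param search_radius template-level search half-width in voxels.
#' @param pyramid_agreement_tol displacement agreement tolerance in voxels
#'   (per axis, Chebyshev); `Inf` disables validation.
#' @param cc_tolerance minimum correlation for a match to count as valid;
#'   sub-threshold matches are demoted to non-displaced points. In
#'   textureless regions the matcher sees only noise, and because nested
#'   blocks share content their spurious maxima are mutually consistent,
#'   so the overlap pyramid alone cannot reject them; a correlation floor
#'   can. The default 0.5 was calibrated on the tagged phantom (where the
#'   true displacement field is known) as the level that rejects
#'   noise-driven matches while retaining genuine matches at peak
#'   deformation; set `-Inf` to disable.
#' @param search_margin symmetric margin, in voxels, by which each child
#'   level's search region extends beyond its parent's matched block;
#'   scalar or length 3 (segment, chunk, window levels). `NULL` (default)
#'   uses `c(t/8, t/8, 0)`: without a margin a corner child can only
#'   deviate one-sidedly from the parent displacement, which breaks
#'   matching in smoothly deforming regions, while at window size (8
#'   voxels of content) the NCC optimum over a smooth texture is too flat
#'   for the extra freedom to be informative, so windows stay confined to
#'   their matched chunk.
#' @param refine_radius per-level bound (segment, chunk, window), in
#'   voxels, on how far a child's match may deviate from the position its
#'   parent's displacement predicts for it; scalar or length 3, `Inf`
#'   allows the whole parent block. The default `c(t/8, t/8, 0)` encodes
#'   motion-field coherence across scales: the true child displacement
#'   differs from the parent's by at most a couple of voxels, while
#'   periodic tag textures offer spurious matches a full tag period away
#'   that a free within-parent search would sometimes prefer. The window
#'   entry defaults to 0 (windows subdivide their matched chunk): a window
#'   holds 8 voxels of a smooth texture, too few for its own correlation
#'   optimum to beat the chunk-level estimate; set it to 1 or more to
#'   re-match windows freely inside their chunk.
#' @return list of class `hierarchy_params`.
#' @export
hierarchy_params <- function(t = 16L, search_radius = 20L,
                             pyramid_agreement_tol = 2,
                             cc_tolerance = 0.5,
                             search_margin = NULL,
                             refine_radius = NULL) {
  t <- as.integer(t)
  if (t <= 0 || t %% 8L != 0L) stop("template size t must be divisible by 8")
  if (search_radius < 0) stop("search_radius must be >= 0")
  if (is.null(search_margin)) {
    search_margin <- c(t %/% 8L, t %/% 8L, 0L)
  }
  search_margin <- rep_len(as.integer(search_margin), 3L)
  if (any(search_margin < 0)) stop("search_margin must be >= 0")
  if (is.null(refine_radius)) {
    refine_radius <- c(t %/% 8L, t %/% 8L, 0L)
  }
  refine_radius <- rep_len(refine_radius, 3L)
  if (any(refine_radius < 0)) stop("refine_radius must be >= 0")
  structure(list(t = t, search_radius = search_radius,
                 pyramid_agreement_tol = pyramid_agreement_tol,
                 cc_tolerance = cc_tolerance,
                 search_margin = as.integer(search_margin),
                 refine_radius = refine_radius),
            class = "hierarchy_params")
}

#' Decompose an image grid into the template/segment/chunk/window hierarchy
#'
#' Templates of edge `t` tile the largest sub-grid of the image divisible by
#' `t`, starting at the 0-based origin; trailing voxels that do not fill a
#' template belong to no block. Each block splits into 8 children of half
#' the edge (half-open intervals, exact tiling). Every window's
#' representative point is its minimum corner.
#'
#' @param image_shape integer length-3 image extents in voxels.
#' @param params a [hierarchy_params()] object (or template edge `t`).
#' @return A tibble with one row per block: 0-based `origin_*`, `size`,
#'   `level` (template/segment/chunk/window), `id` and `parent` indices.
#' @export
decompose_blocks <- function(image_shape, params = hierarchy_params()) {
  if (inherits(params, "hierarchy_params")) t <- params$t else
    t <- as.integer(params)
  if (t %% 8L != 0L) stop("template size t must be divisible by 8")
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 3)
  if (any(image_shape < t)) stop("image smaller than one template")
  nt <- image_shape %/% t

  level_names <- c("template", "segment", "chunk", "window")
  sizes <- t %/% c(1L, 2L, 4L, 8L)

  # template origins
  orig <- as.matrix(expand.grid(x = seq_len(nt[1]) - 1L,
                                y = seq_len(nt[2]) - 1L,
                                z = seq_len(nt[3]) - 1L)) * t
  rows <- list(tibble::tibble(
    id = seq_len(nrow(orig)), parent = NA_integer_, level = "template",
    origin_x = orig[, 1], origin_y = orig[, 2], origin_z = orig[, 3],
    size = t))
  offs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  next_id <- nrow(orig)
  for (lev in 2:4) {
    parent_tbl <- rows[[lev - 1]]
    half <- sizes[lev]
    n_par <- nrow(parent_tbl)
    # 8 children per parent
    par_idx <- rep(seq_len(n_par), each = 8L)
    off <- offs[rep(seq_len(8L), times = n_par), , drop = FALSE] * half
    rows[[lev]] <- tibble::tibble(
      id = next_id + seq_len(8L * n_par),
      parent = parent_tbl$id[par_idx],
      level = level_names[lev],
      origin_x = parent_tbl$origin_x[par_idx] + off[, 1],
      origin_y = parent_tbl$origin_y[par_idx] + off[, 2],
      origin_z = parent_tbl$origin_z[par_idx] + off[, 3],
      size = half)
    next_id <- next_id + 8L * n_par
  }
  dplyr::bind_rows(rows)
}
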
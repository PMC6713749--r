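#' Normalized cross-correlation of a block against a reference region
#'
#' Correlation coefficient between a moving-image block `b` and the
#' equally-sized patch of `region` whose minimum corner sits at `lag`
#' (0-based voxel offset). The score is the covariance of the two patches
#' divided by the product of their root sums of squared deviations, so it is
#' invariant to positive affine intensity changes and ranges over [-1, 1].
#' If either patch has zero variance the coefficient is defined as 0.
#'
#' @param block 3D numeric array (the moving block).
#' @param region 3D numeric array (the reference region).
#' @param lag integer length-3 offset of the patch inside `region`.
#' @return scalar correlation coefficient.
#' @export
ncc <- function(block, region, lag = c(0L, 0L, 0L)) {
  bd <- dim(block); rd <- dim(region)
  if (length(bd) != 3 || length(rd) != 3) stop("block and region must be 3D")
  lag <- as.integer(rep_len(lag, 3L))
  if (any(bd > rd)) stop("block larger than region")
  if (any(lag < 0) || any(lag + bd > rd)) {
    stop("block does not fit inside region at the given lag")
  }
  cpp_ncc(as.double(block), as.integer(bd), as.double(region),
          as.integer(rd), lag)
}

#' Match one block into a reference search region
#'
#' Exhaustively scores every admissible placement of the block inside the
#' reference image with [ncc()] and returns the placement with the maximum
#' correlation. Ties (within 1e-12) are broken by the smallest Euclidean
#' displacement from the block's original position, then by lexicographic
#' (z, y, x) order. A zero-variance (textureless) moving block cannot be
#' matched: it is returned as non-displaced with `valid = FALSE`.
#'
#' @param moving,reference 3D numeric arrays of the two images.
#' @param origin 0-based minimum corner of the block in `moving`.
#' @param size block edge length in voxels (scalar or length 3).
#' @param lo,hi inclusive 0-based bounds for the candidate block origin in
#'   `reference`.
#' @return list with `origin` (matched 0-based origin), `cc`, `valid`.
#' @export
match_block <- function(moving, reference, origin, size, lo, hi) {
  origin <- as.integer(rep_len(origin, 3L))
  size <- as.integer(rep_len(size, 3L))
  lo <- as.integer(rep_len(lo, 3L)); hi <- as.integer(rep_len(hi, 3L))
  if (any(hi < lo)) stop("empty search region")
  res <- cpp_match_block(as.double(moving), as.integer(dim(moving)),
                         as.double(reference), as.integer(dim(reference)),
                         origin, size, lo, hi, origin)
  list(origin = as.integer(res$origin), cc = res$cc,
       valid = !res$zerovar)
}

# Clip a search range so the block [origin, origin+size) stays inside the
# image; returns NULL when empty.
clip_range <- function(lo, hi, size, image_shape) {
  lo <- pmax(lo, 0L)
  hi <- pmin(hi, image_shape - size)
  if (any(hi < lo)) NULL else list(lo = as.integer(lo), hi = as.integer(hi))
}

# Overlap screen blocks for pyramid validation: edges t*{5,6,7}/8 around a
# segment, t*3/8 around a chunk, centred on the block.
overlap_sizes <- function(t, level) {
  if (level == "segment") (t * c(5L, 6L, 7L)) %/% 8L else (t * 3L) %/% 8L
}

#' Hierarchical block matching between two frames
#'
#' Decomposes the moving image into templates, segments, chunks and windows
#' and matches each level into the reference image by exhaustive NCC search:
#' templates within `search_radius` of their original position, each child
#' level only inside its parent's matched block. Segment and chunk matches
#' are screened by a pyramid of overlapping blocks centred on them; when any
#' screen block disagrees with the match by more than
#' `pyramid_agreement_tol` voxels the subtree is demoted to non-displaced
#' control points (reference position = moving position, `valid = FALSE`).
#'
#' @param moving,reference 3D numeric arrays of identical shape.
#' @param params a [hierarchy_params()] object.
#' @return A tibble (one row per window) with 0-based voxel coordinates of
#'   the window representative point in the moving image (`mx`, `my`, `mz`),
#'   its matched reference position (`rx`, `ry`, `rz`), the window-level
#'   correlation `cc`, and `valid`.
#' @export
hierarchical_match <- function(moving, reference,
                               params = hierarchy_params()) {
  if (!identical(dim(moving), dim(reference))) {
    stop("moving and reference frames must have the same shape")
  }
  shape <- as.integer(dim(moving))
  t <- params$t
  sr <- params$search_radius
  mar <- rep_len(params$search_margin %||% c(t %/% 8L, t %/% 8L, 0L), 3L)
  rfn <- rep_len(params$refine_radius %||% c(t %/% 8L, t %/% 8L, 0L), 3L)
  tol <- params$pyramid_agreement_tol
  mov <- as.double(moving); ref <- as.double(reference)
  mdim <- shape

  match1 <- function(origin, size, lo, hi) {
    cpp_match_block(mov, mdim, ref, mdim, as.integer(origin),
                    as.integer(rep_len(size, 3L)), as.integer(lo),
                    as.integer(hi), as.integer(origin))
  }

  # Child search region: a bounded refinement window around the position
  # the parent's displacement predicts, intersected with the parent's
  # matched block (expanded by the level margin), clipped to the image.
  child_range <- function(child_orig, child_size, parent_match,
                          parent_size, parent_disp, level) {
    pred <- child_orig + parent_disp
    lo <- pmax(pred - rfn[level], parent_match - mar[level])
    hi <- pmin(pred + rfn[level],
               parent_match + (parent_size - child_size) + mar[level])
    clip_range(lo, hi, child_size, shape)
  }

  # screen a block match with centred overlap blocks; TRUE = agrees
  screen <- function(block_origin, block_size, disp, parent_disp, sizes,
                     margin) {
    if (!is.finite(tol)) return(TRUE)
    for (s in sizes) {
      ov_orig <- block_origin + (block_size - s) %/% 2L
      if (any(ov_orig < 0L) || any(ov_orig + s > shape)) next  # clipped
      expected <- ov_orig + parent_disp
      rng <- clip_range(expected - margin, expected + margin, s, shape)
      if (is.null(rng)) next
      res <- match1(ov_orig, s, rng$lo, rng$hi)
      if (res$zerovar) next
      ov_disp <- as.integer(res$origin) - ov_orig
      if (any(abs(ov_disp - disp) > tol)) return(FALSE)
    }
    TRUE
  }

  offs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  nt <- shape %/% t
  if (any(nt < 1L)) stop("image smaller than one template")

  out <- vector("list", prod(nt))
  ti <- 0L

  window_grid <- function(origin, size, wsize) {
    k <- size %/% wsize
    g <- as.matrix(expand.grid(seq_len(k) - 1L, seq_len(k) - 1L,
                               seq_len(k) - 1L)) * wsize
    sweep(g, 2, as.integer(origin), `+`)
  }

  wsize <- t %/% 8L
  for (tz in seq_len(nt[3])) for (ty in seq_len(nt[2])) {
    for (tx in seq_len(nt[1])) {
      ti <- ti + 1L
      torig <- c(tx - 1L, ty - 1L, tz - 1L) * t
      rows_m <- window_grid(torig, t, wsize)
      res_tbl <- list(m = rows_m, r = rows_m,
                      cc = rep(0, nrow(rows_m)),
                      valid = rep(FALSE, nrow(rows_m)))

      rng <- if (is.finite(sr)) {
        clip_range(torig - as.integer(sr), torig + as.integer(sr), t, shape)
      } else {
        list(lo = c(0L, 0L, 0L), hi = shape - t)
      }
      tres <- match1(torig, t, rng$lo, rng$hi)
      if (!tres$zerovar) {
        tmatch <- as.integer(tres$origin)
        tdisp <- tmatch - torig
        seg <- t %/% 2L
        row_at <- function(pt) {
          # index of a window representative point within rows_m
          rel <- (pt - torig) %/% wsize
          1L + rel[1] + 8L * (rel[2] + 8L * rel[3])
        }
        for (si in seq_len(8L)) {
          sorig <- torig + offs[si, ] * seg
          srng <- child_range(sorig, seg, tmatch, t, tdisp, 1L)
          if (is.null(srng)) next
          sres <- match1(sorig, seg, srng$lo, srng$hi)
          if (sres$zerovar) next
          smatch <- as.integer(sres$origin)
          sdisp <- smatch - sorig
          if (sres$cc < params$cc_tolerance) next
          if (!screen(sorig, seg, sdisp, tdisp,
                      overlap_sizes(t, "segment"), t %/% 4L)) next
          chk <- t %/% 4L
          for (ci in seq_len(8L)) {
            corig <- sorig + offs[ci, ] * chk
            crng <- child_range(corig, chk, smatch, seg, sdisp, 2L)
            if (is.null(crng)) next
            cres <- match1(corig, chk, crng$lo, crng$hi)
            if (cres$zerovar) next
            cmatch <- as.integer(cres$origin)
            cdisp <- cmatch - corig
            if (cres$cc < params$cc_tolerance) next
            if (!screen(corig, chk, cdisp, sdisp,
                        overlap_sizes(t, "chunk"), t %/% 8L)) next
            for (wi in seq_len(8L)) {
              worig <- corig + offs[wi, ] * wsize
              wrng <- child_range(worig, wsize, cmatch, chk, cdisp, 3L)
              if (is.null(wrng)) next
              wres <- match1(worig, wsize, wrng$lo, wrng$hi)
              if (wres$zerovar) next
              if (wres$cc < params$cc_tolerance) next
              k <- row_at(worig)
              res_tbl$r[k, ] <- as.integer(wres$origin)
              res_tbl$cc[k] <- wres$cc
              res_tbl$valid[k] <- TRUE
            }
          }
        }
      }
      out[[ti]] <- tibble::tibble(
        mx = res_tbl$m[, 1], my = res_tbl$m[, 2], mz = res_tbl$m[, 3],
        rx = res_tbl$r[, 1], ry = res_tbl$r[, 2], rz = res_tbl$r[, 3],
        cc = res_tbl$cc, valid = res_tbl$valid)
    }
  }
  cps <- dplyr::bind_rows(out)
  class(cps) <- c("control_points", class(cps))
  cps
}

#' Validate a block match against its overlap screen blocks
#'
#' A segment or chunk match is accepted only if every overlapping screen
#' block's matched displacement agrees with the block's displacement within
#' `tol` voxels per axis. Screen blocks clipped at the image border are
#' skipped; with no usable screen block the match is accepted vacuously.
#' `tol = Inf` disables validation.
#'
#' @param block_disp integer length-3 displacement of the block match.
#' @param overlap_disps list (or matrix rows) of screen-block displacements;
#'   `NULL` entries (clipped blocks) are skipped.
#' @param tol agreement tolerance in voxels.
#' @return logical: does the pyramid agree?
#' @export
pyramid_validate <- function(block_disp, overlap_disps, tol = 2) {
  if (!is.finite(tol)) return(TRUE)
  if (is.matrix(overlap_disps)) {
    overlap_disps <- split(overlap_disps, seq_len(nrow(overlap_disps)))
  }
  for (d in overlap_disps) {
    if (is.null(d)) next
    if (any(abs(as.numeric(d) - as.numeric(block_disp)) > tol)) return(FALSE)
  }
  TRUE
}
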
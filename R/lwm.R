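#' Local Weighted Mean weight kernel
#'
#' The tricubic blending kernel `W(R) = 1 - 3R^2 + 2R^3` for normalized
#' distances `R` in [0, 1] and 0 beyond. `W(0) = 1`, `W(1) = 0`, and the
#' first derivative vanishes at both ends, which is what makes the weighted
#' mean of local polynomials C1-smooth across influence boundaries.
#'
#' @param R numeric vector of normalized distances, must be non-negative.
#' @return numeric vector of weights.
#' @export
lwm_weight <- function(R) {
  R <- as.numeric(R)
  if (any(R < 0)) stop("normalized distance R must be non-negative")
  ifelse(R >= 1, 0, 1 - 3 * R^2 + 2 * R^3)
}

#' Fit a 3D Local Weighted Mean transformation
#'
#' For every control point, a second-order polynomial with ten coefficients
#' (monomial basis 1, x, y, z, x2, y2, z2, xy, xz, yz, centred on the
#' control point for conditioning) is least-squares fitted to the mapped
#' coordinates over the point and its `n - 1` nearest source-side
#' neighbours. The stored influence radius of control point i is its
#' distance to the (n-1)-th nearest control point, so each polynomial only
#' ever influences queries closer than that radius.
#'
#' @param source numeric matrix (N x 3) of source-side control points, or a
#'   `control_points` tibble from [hierarchical_match()] together with
#'   `direction`.
#' @param target numeric matrix (N x 3) of mapped points (ignored when
#'   `source` is a `control_points` tibble).
#' @param n local neighbourhood size (default 100; must satisfy
#'   10 <= n <= N after deduplication).
#' @param direction for a `control_points` input: `"moving_to_reference"`
#'   (source = moving points) or `"reference_to_moving"`.
#' @return object of class `lwm_transform`.
#' @export
lwm_fit <- function(source, target = NULL, n = 100L,
                    direction = c("moving_to_reference",
                                  "reference_to_moving")) {
  direction <- match.arg(direction)
  if (inherits(source, "control_points") ||
      (is.data.frame(source) && all(c("mx", "rx") %in% names(source)))) {
    cps <- source
    m <- cbind(cps$mx, cps$my, cps$mz)
    r <- cbind(cps$rx, cps$ry, cps$rz)
    if (direction == "moving_to_reference") {
      source <- m; target <- r
    } else {
      source <- r; target <- m
    }
  }
  source <- as_points(source); target <- as_points(target)
  if (nrow(source) != nrow(target)) stop("source/target length mismatch")

  # collapse exact-duplicate source positions (keeps the first pair)
  dup <- duplicated(source)
  if (any(dup)) {
    source <- source[!dup, , drop = FALSE]
    target <- target[!dup, , drop = FALSE]
  }
  N <- nrow(source)
  n <- as.integer(n)
  if (n < 10L) stop("neighbourhood size n must be at least 10")
  if (N < n) stop(sprintf("N = %d control points but n = %d required", N, n))

  nn <- cpp_knn(source, n)
  coef <- cpp_lwm_fit(source, target, nn$idx)
  structure(
    list(source = source, target = target, n = n,
         coef = coef, radii = as.numeric(nn$radius),
         direction = direction, radius_mode = "control",
         centering = "per_control_point"),
    class = "lwm_transform")
}

#' Evaluate a Local Weighted Mean transformation
#'
#' Maps 3D points through the fitted transform: each component is the
#' weighted mean over control points of their local polynomial evaluated at
#' the query, with weights `W(d_i / R_i)` from [lwm_weight()]. A query
#' beyond every influence radius falls back to the polynomial of its
#' nearest control point. With `radius_mode = "evaluation"` the normalized
#' distance instead uses the query's own distance to its (n-1)-th nearest
#' control point (the alternative radius convention).
#'
#' @param transform an `lwm_transform`.
#' @param points numeric matrix (m x 3) or length-3 vector.
#' @param radius_mode `"control"` (default, per-control-point radii) or
#'   `"evaluation"`.
#' @return numeric matrix (m x 3) of mapped points.
#' @export
lwm_evaluate <- function(transform, points, radius_mode = NULL) {
  stopifnot(inherits(transform, "lwm_transform"))
  points <- as_points(points)
  mode <- radius_mode %||% transform$radius_mode
  mode_i <- match(mode, c("control", "evaluation")) - 1L
  if (is.na(mode_i)) stop("radius_mode must be 'control' or 'evaluation'")
  cpp_lwm_eval(transform$source, transform$coef, transform$radii,
               points, mode_i, transform$n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numeric Jacobian of an LWM transformation
#'
#' Central finite differences of [lwm_evaluate()] componentwise; exact (to
#' rounding) on globally affine transforms, O(h^2) otherwise.
#'
#' @param transform an `lwm_transform`.
#' @param points query points (m x 3).
#' @param h finite-difference step (same unit as the control points,
#'   default 0.25).
#' @return array (3 x 3 x m); entry (i, j, k) is d map_i / d x_j at point k.
#' @export
lwm_jacobian <- function(transform, points, h = 0.25) {
  stopifnot(h > 0)
  points <- as_points(points)
  m <- nrow(points)
  # batch the 6 shifted evaluations into one call
  shifts <- rbind(c(h, 0, 0), c(-h, 0, 0), c(0, h, 0), c(0, -h, 0),
                  c(0, 0, h), c(0, 0, -h))
  q <- points[rep(seq_len(m), times = 6), , drop = FALSE] +
    shifts[rep(seq_len(6), each = m), , drop = FALSE]
  v <- lwm_evaluate(transform, q)
  J <- array(0, c(3, 3, m))
  for (j in 1:3) {
    plus <- v[(2 * j - 2) * m + seq_len(m), , drop = FALSE]
    minus <- v[(2 * j - 1) * m + seq_len(m), , drop = FALSE]
    J[, j, ] <- t((plus - minus) / (2 * h))
  }
  J
}

#' Identity LWM stand-in
#'
#' Used when a frame yields no usable correspondences; evaluates to the
#' input points.
#' @param direction transform direction label.
#' @return object of class `lwm_identity`.
#' @export
lwm_identity <- function(direction = "moving_to_reference") {
  structure(list(direction = direction), class = "lwm_identity")
}

#' @export
print.lwm_transform <- function(x, ...) {
  cat(sprintf(
    "<lwm_transform> %d control points, n = %d, direction = %s\n",
    nrow(x$source), x$n, x$direction))
  cat(sprintf("  influence radii: %.3g .. %.3g\n",
              min(x$radii), max(x$radii)))
  invisible(x)
}

#' Tidy an LWM transform into a tibble of control points
#'
#' @param x an `lwm_transform`.
#' @param ... unused.
#' @return tibble with source/target coordinates, influence radius and
#'   the per-point fit residual (Euclidean, at the control point itself).
#' @export
tidy.lwm_transform <- function(x, ...) {
  fitted <- lwm_evaluate(x, x$source)
  res <- sqrt(rowSums((fitted - x$target)^2))
  tibble::tibble(
    sx = x$source[, 1], sy = x$source[, 2], sz = x$source[, 3],
    tx = x$target[, 1], ty = x$target[, 2], tz = x$target[, 3],
    radius = x$radii, residual = res)
}

#' One-row summary of an LWM transform
#' @param x an `lwm_transform`.
#' @param ... unused.
#' @export
glance.lwm_transform <- function(x, ...) {
  fitted <- lwm_evaluate(x, x$source)
  res <- sqrt(rowSums((fitted - x$target)^2))
  tibble::tibble(
    n_control = nrow(x$source), n_local = x$n, direction = x$direction,
    median_residual = stats::median(res), max_residual = max(res))
}

#' Serialize an LWM transform to JSON
#'
#' Round-trips the full state: control points, targets, centred polynomial
#' coefficients, influence radii, neighbourhood size, direction and radius
#' convention.
#'
#' @param transform an `lwm_transform`.
#' @param path optional file path; when `NULL`, the JSON string is returned.
#' @export
lwm_to_json <- function(transform, path = NULL) {
  stopifnot(inherits(transform, "lwm_transform"))
  obj <- list(
    type = "lwm_transform",
    n = transform$n,
    direction = transform$direction,
    radius_mode = transform$radius_mode,
    centering = transform$centering,
    basis = c("1", "x", "y", "z", "x2", "y2", "z2", "xy", "xz", "yz"),
    source = transform$source,
    target = transform$target,
    coef = transform$coef,
    radii = transform$radii)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname lwm_to_json
#' @param json a JSON string or file path produced by [lwm_to_json()].
#' @export
lwm_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  if (!identical(obj$type, "lwm_transform")) stop("not an LWM transform")
  structure(
    list(source = as_points(obj$source), target = as_points(obj$target),
         n = as.integer(obj$n), coef = as.matrix(obj$coef),
         radii = as.numeric(obj$radii), direction = obj$direction,
         radius_mode = obj$radius_mode, centering = obj$centering),
    class = "lwm_transform")
}
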
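#' Landmark trajectories container
#'
#' Per-landmark, per-frame 3D positions in millimetres, as a tidy tibble.
#'
#' @param df data frame with columns `landmark`, `frame`, `x`, `y`, `z`.
#' @param observer_id optional observer label.
#' @return tibble of class `landmark_trajectories`.
#' @export
landmark_trajectories <- function(df, observer_id = NA_character_) {
  need <- c("landmark", "frame", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("landmark trajectories need columns landmark, frame, x, y, z")
  }
  out <- tibble::as_tibble(df[, need])
  out$observer <- observer_id
  class(out) <- c("landmark_trajectories", class(out))
  out
}

#' Landmark tracking error summary
#'
#' Per-landmark, per-frame Euclidean error (mm) between predicted and
#' ground-truth trajectories, with medians and maxima over all frames, the
#' end-systolic frame and the final frame.
#'
#' @param predicted,truth `landmark_trajectories` (or data frames) sharing
#'   landmark ids and frames.
#' @param end_systolic_index,final_index 1-based frame indices.
#' @return list of class `error_summary`: `errors` tibble (landmark,
#'   frame, error_mm) and `summary` tibble (category, median_mm, max_mm).
#' @export
landmark_error <- function(predicted, truth, end_systolic_index,
                           final_index = max(truth$frame)) {
  key <- function(d) paste(d$landmark, d$frame)
  predicted <- predicted[order(predicted$landmark, predicted$frame), ]
  truth <- truth[order(truth$landmark, truth$frame), ]
  if (!identical(key(predicted), key(truth))) {
    stop("predicted and truth trajectories have mismatched landmarks/frames")
  }
  err <- sqrt((predicted$x - truth$x)^2 + (predicted$y - truth$y)^2 +
              (predicted$z - truth$z)^2)
  errors <- tibble::tibble(landmark = truth$landmark, frame = truth$frame,
                           error_mm = err)
  cat_rows <- function(label, sel) {
    tibble::tibble(category = label,
                   median_mm = stats::median(errors$error_mm[sel]),
                   max_mm = max(errors$error_mm[sel]))
  }
  summary <- dplyr::bind_rows(
    cat_rows("all_frames", rep(TRUE, nrow(errors))),
    cat_rows("end_systolic", errors$frame == end_systolic_index),
    cat_rows("final", errors$frame == final_index))
  structure(list(errors = errors, summary = summary),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat("<error_summary>\n")
  print(x$summary)
  invisible(x)
}

# nearest-rank percentile: smallest value with at least p of the mass
percentile_nearest_rank <- function(x, p) {
  x <- sort(x)
  x[max(1L, ceiling(p * length(x)))]
}

#' Consensus ground-truth landmark selection between two observers
#'
#' Computes, per landmark: the distance between its final and initial
#' position for each observer, and the distance between the two observers'
#' final positions. All measured distances are pooled; a landmark counts as
#' ground truth only if all three of its distances fall strictly below the
#' pooled 75th percentile (nearest-rank convention). When every distance is
#' identical (e.g. perfectly static landmarks) the strict rule admits
#' nothing and a warning flags the degenerate input.
#'
#' @param obs1,obs2 `landmark_trajectories` for the two observers.
#' @param percentile pooled percentile defining "relatively close".
#' @return integer vector of consensus landmark ids.
#' @export
consensus_landmarks <- function(obs1, obs2, percentile = 0.75) {
  ids <- sort(unique(obs1$landmark))
  if (!identical(ids, sort(unique(obs2$landmark)))) {
    stop("observers annotate different landmark sets")
  }
  if (length(ids) < 2) stop("need at least 2 landmarks")
  frames <- sort(unique(obs1$frame))
  if (!identical(frames, sort(unique(obs2$frame)))) {
    stop("observers annotate different frame sets")
  }
  f0 <- min(frames); f1 <- max(frames)
  pos <- function(obs, id, fr) {
    r <- obs[obs$landmark == id & obs$frame == fr, ]
    c(r$x[1], r$y[1], r$z[1])
  }
  d <- function(p, q) sqrt(sum((p - q)^2))
  per_lm <- lapply(ids, function(id) {
    c(intra1 = d(pos(obs1, id, f1), pos(obs1, id, f0)),
      intra2 = d(pos(obs2, id, f1), pos(obs2, id, f0)),
      inter = d(pos(obs1, id, f1), pos(obs2, id, f1)))
  })
  pooled <- unlist(per_lm)
  thr <- percentile_nearest_rank(pooled, percentile)
  keep <- vapply(per_lm, function(v) all(v < thr), logical(1))
  if (!any(keep) && all(pooled == pooled[1])) {
    warning("degenerate input: all measured distances identical; ",
            "the strict percentile rule admits no landmark")
  }
  ids[keep]
}
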
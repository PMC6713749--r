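#' Triangulated surface mesh with anatomical anchors
#'
#' Nodes are 3D coordinates in millimetres in the reference-frame space;
#' triangles index into the nodes (1-based). Outward unit normals per node
#' are computed on construction when not supplied (area-weighted average of
#' incident triangle normals, oriented so they point away from the mesh
#' centroid on average). The apex and mitral-valve centre anchor the
#' longitudinal direction; when missing they are derived as the extreme
#' nodes along the mesh's first principal axis.
#'
#' @param nodes numeric matrix (n x 3), mm.
#' @param triangles integer matrix (m x 3) of 1-based node indices.
#' @param normals optional numeric matrix (n x 3) of unit node normals.
#' @param apex,mitral_center optional length-3 points (mm).
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(nodes, triangles, normals = NULL, apex = NULL,
                         mitral_center = NULL) {
  nodes <- as_points(nodes)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(triangles) != 3) stop("triangles must have 3 columns")
  if (nrow(triangles) >= 1 &&
      (min(triangles) < 1 || max(triangles) > nrow(nodes))) {
    stop("triangle indices out of range")
  }
  if (is.null(normals)) {
    normals <- vertex_normals(nodes, triangles)
  } else {
    normals <- as_points(normals)
    nrm <- sqrt(rowSums(normals^2))
    normals <- normals / pmax(nrm, 1e-12)
  }
  if (is.null(apex) || is.null(mitral_center)) {
    pc <- principal_axis_extremes(nodes)
    if (is.null(apex)) apex <- pc$lo
    if (is.null(mitral_center)) mitral_center <- pc$hi
  }
  apex <- as.numeric(apex); mitral_center <- as.numeric(mitral_center)
  if (sqrt(sum((apex - mitral_center)^2)) < 1e-9) {
    stop("apex and mitral_center must differ")
  }
  structure(list(nodes = nodes, triangles = triangles, normals = normals,
                 apex = apex, mitral_center = mitral_center),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d nodes, %d triangles\n",
              nrow(x$nodes), nrow(x$triangles)))
  invisible(x)
}

# area-weighted vertex normals, oriented outward from the centroid
vertex_normals <- function(nodes, triangles) {
  nrm <- matrix(0, nrow(nodes), 3)
  if (nrow(triangles) == 0) return(nrm)
  a <- nodes[triangles[, 1], , drop = FALSE]
  b <- nodes[triangles[, 2], , drop = FALSE]
  c_ <- nodes[triangles[, 3], , drop = FALSE]
  fn <- cross3(b - a, c_ - a)  # magnitude = 2 * area
  for (k in 1:3) {
    idx <- triangles[, k]
    for (j in 1:3) {
      nrm[, j] <- nrm[, j] + unname(tapply(
        fn[, j], factor(idx, levels = seq_len(nrow(nodes))), sum,
        default = 0))
    }
  }
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, 1e-12)
  centroid <- colMeans(nodes)
  outward <- sweep(nodes, 2, centroid)
  if (mean(rowSums(nrm * outward)) < 0) nrm <- -nrm
  nrm
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

principal_axis_extremes <- function(nodes) {
  ctr <- colMeans(nodes)
  x <- sweep(nodes, 2, ctr)
  ax <- svd(x, nu = 0, nv = 1)$v[, 1]
  proj <- x %*% ax
  list(lo = nodes[which.min(proj), ], hi = nodes[which.max(proj), ])
}

#' Minimum distance from points to a triangulated surface
#'
#' Exact point-to-triangle distances (closest point on each triangle's
#' face, edges or vertices), minimised over all triangles.
#'
#' @param points numeric matrix (n x 3), mm.
#' @param mesh a [surface_mesh()].
#' @return numeric vector of distances (mm).
#' @export
point_to_surface <- function(points, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$triangles) < 1) stop("mesh has no triangles")
  points <- as_points(points)
  a <- mesh$nodes[mesh$triangles[, 1], , drop = FALSE]
  b <- mesh$nodes[mesh$triangles[, 2], , drop = FALSE]
  c_ <- mesh$nodes[mesh$triangles[, 3], , drop = FALSE]
  ab <- b - a; ac <- c_ - a
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    ap <- sweep(-a, 2, p, `+`)  # p - a per triangle
    d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
    bp <- sweep(-b, 2, p, `+`)
    d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
    cp <- sweep(-c_, 2, p, `+`)
    d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
    va <- d3 * d6 - d5 * d4
    vb <- d5 * d2 - d1 * d6
    vc <- d1 * d4 - d3 * d2
    # Voronoi-region classification of the closest point, vectorised over
    # triangles: start from the face-interior solution and overwrite in
    # reverse priority so the highest-priority region wins.
    denom <- va + vb + vc
    denom[abs(denom) < 1e-300] <- 1e-300
    v <- vb / denom
    w <- vc / denom
    reg_bc <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
    t_bc <- (d4 - d3) / pmax((d4 - d3) + (d5 - d6), 1e-300)
    v[reg_bc] <- (1 - t_bc)[reg_bc]; w[reg_bc] <- t_bc[reg_bc]
    reg_ac <- vb <= 0 & d2 >= 0 & d6 <= 0
    t_ac <- d2 / pmax(d2 - d6, 1e-300)
    v[reg_ac] <- 0; w[reg_ac] <- t_ac[reg_ac]
    reg_c <- d6 >= 0 & d5 <= d6
    v[reg_c] <- 0; w[reg_c] <- 1
    reg_ab <- vc <= 0 & d1 >= 0 & d3 <= 0
    t_ab <- d1 / pmax(d1 - d3, 1e-300)
    v[reg_ab] <- t_ab[reg_ab]; w[reg_ab] <- 0
    reg_b <- d3 >= 0 & d4 <= d3
    v[reg_b] <- 1; w[reg_b] <- 0
    reg_a <- d1 <= 0 & d2 <= 0
    v[reg_a] <- 0; w[reg_a] <- 0
    closest <- a + ab * v + ac * w
    d2p <- rowSums(sweep(closest, 2, p)^2)
    out[i] <- sqrt(min(d2p))
  }
  out
}

#' Read / write a triangulated mesh as Wavefront OBJ
#'
#' Plain-text `v`/`f` records; the apex and mitral-valve anchors are carried
#' in comment lines (`# anchor apex x y z`). Coordinates are millimetres.
#'
#' @param path file path.
#' @return a [surface_mesh()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_obj_mesh <- function(path) {
  lines <- readLines(path)
  vs <- grep("^v ", lines, value = TRUE)
  fs <- grep("^f ", lines, value = TRUE)
  nodes <- do.call(rbind, lapply(strsplit(vs, "\\s+"), function(tok) {
    as.numeric(tok[2:4])
  }))
  tris <- do.call(rbind, lapply(strsplit(fs, "\\s+"), function(tok) {
    as.integer(sub("/.*", "", tok[2:4]))
  }))
  anchor <- function(name) {
    ln <- grep(paste0("^# anchor ", name), lines, value = TRUE)
    if (length(ln) == 0) return(NULL)
    as.numeric(strsplit(ln[1], "\\s+")[[1]][4:6])
  }
  surface_mesh(nodes, tris, apex = anchor("apex"),
               mitral_center = anchor("mitral"))
}

#' @rdname read_obj_mesh
#' @param mesh a [surface_mesh()].
#' @export
write_obj_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# triangulated surface, coordinates in mm",
    sprintf("# anchor apex %.10g %.10g %.10g", mesh$apex[1], mesh$apex[2],
            mesh$apex[3]),
    sprintf("# anchor mitral %.10g %.10g %.10g", mesh$mitral_center[1],
            mesh$mitral_center[2], mesh$mitral_center[3])), con)
  writeLines(sprintf("v %.10g %.10g %.10g", mesh$nodes[, 1],
                     mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 3]), con)
  invisible(path)
}
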
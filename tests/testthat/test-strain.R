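grid_pairs <- function(map, k = 8, pitch = 2) {
  src <- as.matrix(expand.grid(seq_len(k) - 1, seq_len(k) - 1,
                               seq_len(k) - 1)) * pitch
  list(src = src, dst = map(src))
}

test_that("closed-form strains from elementary deformation gradients", {
  # uniaxial stretch
  E <- lagrange_strain(diag(c(1.2, 1, 1)))
  expect_equal(E[1, 1], 0.22, tolerance = 1e-12)
  expect_equal(E[2, 2], 0)
  # longitudinal shortening
  expect_equal(lagrange_strain(diag(c(1, 1, 0.9)))[3, 3], -0.095,
               tolerance = 1e-12)
  # simple shear
  Fm <- diag(3); Fm[1, 2] <- 0.1
  E <- lagrange_strain(Fm)
  expect_equal(E[1, 2], 0.05, tolerance = 1e-12)
  expect_equal(E[2, 2], 0.005, tolerance = 1e-12)
  # rotations produce no strain
  th <- 0.3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_lt(max(abs(lagrange_strain(R))), 1e-14)
})

test_that("deformation gradient inverts (I - U) with singularity guard", {
  expect_equal(deformation_gradient(matrix(0, 3, 3)), diag(3))
  expect_equal(deformation_gradient(diag(c(0.5, 0, 0))),
               diag(c(2, 1, 1)))
  # U from a rigid rotation gives F = R (no strain)
  th <- 0.25
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  U <- diag(3) - t(R)  # inverse map Jacobian is R^T
  Fm <- deformation_gradient(U)
  expect_lt(max(abs(t(Fm) %*% Fm - diag(3))), 1e-12)
  expect_error(deformation_gradient(diag(c(1, 0, 0))), "singular")
})

test_that("displacement gradient from LWM matches closed forms", {
  # uniform stretch x = 2X: inverse map X = x/2 -> U = diag(0.5)
  pr <- grid_pairs(function(p) p / 2, k = 8, pitch = 2)
  inv <- lwm_fit(pr$src, pr$dst, n = 40, direction = "moving_to_reference")
  U <- displacement_gradient(inv, matrix(c(6, 6, 6), 1, 3), spacing = 1,
                             h = 0.25)
  expect_equal(U[, , 1], diag(c(0.5, 0.5, 0.5)), tolerance = 1e-7)
  E <- lagrange_strain(deformation_gradient(U))
  expect_equal(E[1, 1, 1], 1.5, tolerance = 1e-6)  # (lambda^2 - 1)/2, l=2

  # rigid rotation: U = I - R^T, E = 0
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  pr <- grid_pairs(function(p) p %*% R)  # inverse map: rotate by -th
  inv <- lwm_fit(pr$src, pr$dst, n = 40, direction = "moving_to_reference")
  U <- displacement_gradient(inv, matrix(c(7, 5, 6), 1, 3), spacing = 1,
                             h = 0.25)
  # row-vector map p %*% R has column-convention Jacobian t(R)
  expect_lt(max(abs(U[, , 1] - (diag(3) - t(R)))), 1e-7)
  E <- lagrange_strain(deformation_gradient(U))
  expect_lt(max(abs(E)), 1e-7)
})

test_that("Eulerian gradient composition matches the forward Jacobian", {
  # on affine fields, F = (I-U)^{-1} from the inverse map must equal the
  # forward map's Jacobian
  A <- matrix(c(1.1, 0.04, 0, -0.03, 0.95, 0.02, 0.01, 0, 1.05), 3, 3)
  fwd_map <- function(p) p %*% A
  inv_map <- function(p) p %*% solve(A)
  pr_f <- grid_pairs(fwd_map)
  pr_i <- grid_pairs(inv_map)
  fwd <- lwm_fit(pr_f$src, pr_f$dst, n = 40,
                 direction = "reference_to_moving")
  inv <- lwm_fit(pr_i$src, pr_i$dst, n = 40,
                 direction = "moving_to_reference")
  x <- matrix(c(6, 7, 5), 1, 3)
  U <- displacement_gradient(inv, x, spacing = 1, h = 0.25)
  F_from_U <- deformation_gradient(U[, , 1])
  J_fwd <- lwm_jacobian(fwd, inv_map(x), h = 0.25)[, , 1]
  expect_lt(max(abs(F_from_U - J_fwd)), 1e-6)
})

test_that("direction frames follow the anatomy", {
  # cylinder-like mesh: axis +z, apex below
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  nodes <- do.call(rbind, lapply(c(0, 2, 4), function(z) {
    cbind(10 * cos(th), 10 * sin(th), z)
  }))
  tri <- cbind(1:14, 2:15, 17:30)  # connectivity irrelevant here
  normals <- cbind(cos(rep(th, 3)), sin(rep(th, 3)), 0)
  mesh <- surface_mesh(nodes, tri, normals = normals,
                       apex = c(0, 0, -10), mitral_center = c(0, 0, 4))
  dirs <- local_directions(mesh)
  expect_equal(dirs$L, c(0, 0, 1))
  expect_true(all(dirs$defined))
  # radial equals the normal (already orthogonal to L)
  expect_lt(max(abs(dirs$R_dir - normals)), 1e-9)
  # node with normal (1,0,0): C = L x R = (0,1,0)
  i <- which(abs(normals[, 1] - 1) < 1e-12)[1]
  expect_equal(dirs$C[i, ], c(0, 1, 0), tolerance = 1e-12)
  # orthonormality and right-handedness everywhere
  expect_lt(max(abs(rowSums(dirs$R_dir * dirs$C))), 1e-9)
  expect_lt(max(abs(dirs$R_dir %*% dirs$L)), 1e-9)

  # normal parallel to L is flagged undefined
  normals2 <- normals
  normals2[1, ] <- c(0, 0, 1)
  mesh2 <- surface_mesh(nodes, tri, normals = normals2,
                        apex = c(0, 0, -10), mitral_center = c(0, 0, 4))
  dirs2 <- local_directions(mesh2)
  expect_false(dirs2$defined[1])
  expect_true(all(dirs2$defined[-1]))
})

test_that("strain projection is the quadratic form p' E p", {
  expect_equal(project_strain(0.1 * diag(3), c(1, 0, 0)), 0.1)
  expect_equal(project_strain(diag(c(3, 5, 7)), c(0, 1, 0)), 5)
  set.seed(41)
  for (i in 1:20) {
    E <- random_symmetric()
    p <- rnorm(3); p <- p / sqrt(sum(p^2))
    brute <- sum(outer(p, p) * E)
    expect_equal(project_strain(E, p), brute, tolerance = 1e-12)
  }
  expect_error(project_strain(diag(3), c(1, 1, 0)), "unit")
})

test_that("eigen analysis sorts ascending and takes positional medians", {
  ev <- eigen_analysis(array(diag(c(-0.1, -0.05, 0.02)), c(3, 3, 1)))
  expect_equal(ev$values[1, ], c(-0.1, -0.05, 0.02))
  expect_equal(eigen_analysis(array(0, c(3, 3, 1)))$values[1, ], rep(0, 3))
  # positional medians across three known diagonal tensors
  Es <- array(0, c(3, 3, 3))
  Es[, , 1] <- diag(c(-3, 0, 1))
  Es[, , 2] <- diag(c(-1, 2, 5))
  Es[, , 3] <- diag(c(-2, 1, 3))
  ev <- eigen_analysis(Es)
  expect_equal(ev$medians, c(-2, 1, 3))
  # Rayleigh bound: projections lie within the eigenvalue range
  set.seed(42)
  E <- random_symmetric()
  lam <- range(eigen(E, symmetric = TRUE)$values)
  for (i in 1:20) {
    p <- rnorm(3); p <- p / sqrt(sum(p^2))
    ep <- project_strain(E, p)
    expect_gte(ep, lam[1] - 1e-12)
    expect_lte(ep, lam[2] + 1e-12)
  }
  bad <- array(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3), c(3, 3, 1))
  expect_error(eigen_analysis(bad), "symmetric")
})

test_that("mesh tracking applies forward transforms per frame", {
  ph <- phantom_fixture()
  mesh <- phantom_mesh(ph$spec)
  # identity transforms keep positions constant
  tr_id <- replicate(3, lwm_identity("reference_to_moving"),
                     simplify = FALSE)
  tk <- track_mesh(mesh, tr_id, spacing = 0.96)
  expect_equal(tk$positions[, , 3], mesh$nodes)
  # pure translation moves every node by d (in voxel units -> mm)
  src <- as.matrix(expand.grid(0:9, 0:9, 0:9)) * 6
  d <- c(2, -1, 3)
  fwd <- lwm_fit(src, sweep(src, 2, d, `+`), n = 40,
                 direction = "reference_to_moving")
  tk2 <- track_mesh(mesh, list(lwm_identity("reference_to_moving"), fwd),
                    spacing = 0.96)
  shift_mm <- tk2$positions[, , 2] - mesh$nodes
  expect_lt(max(abs(sweep(shift_mm, 2, d * 0.96))), 1e-5)
  # direction mismatch rejected
  wrong <- lwm_fit(src, src, n = 40, direction = "moving_to_reference")
  expect_error(track_mesh(mesh, list(wrong), 0.96), "reference_to_moving")
})

test_that("strain curves vanish at the reference and aggregate correctly", {
  ph <- phantom_fixture()
  mesh <- phantom_mesh(ph$spec)
  dirs <- local_directions(mesh)
  n <- nrow(mesh$nodes)
  zero <- structure(list(U = array(0, c(3, 3, n)),
                         F = array(diag(3), c(3, 3, n)),
                         E = array(0, c(3, 3, n)), frame = 1),
                    class = "strain_field")
  uni <- zero
  uni$E <- array(diag(c(-0.2, -0.1, 0.3)), c(3, 3, n))
  uni$frame <- 2
  curves <- strain_curves(list(zero, uni), dirs)
  expect_equal(unlist(curves[1, c("E_L", "E_C", "E_R")]), rep(0, 3),
               ignore_attr = TRUE)
  expect_equal(curves$eig1[2], -0.2)
  expect_equal(curves$eig3[2], 0.3)
  # uniform diagonal tensor with axis frames: E_L picks the L component
  # (L = +z for the phantom mesh)
  expect_equal(curves$E_L[2], 0.3, tolerance = 1e-9)
})
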
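test_that("amplitude profile rises to end-systole and decays to 0.1", {
  spec <- phantom_spec()
  a <- make_deformation(spec)$amplitude
  expect_equal(a[1], 0)
  expect_equal(a[spec$end_systolic_index], 1)
  expect_equal(a[spec$n_frames], 0.1, tolerance = 1e-12)
  expect_equal(which.max(a), spec$end_systolic_index)
})

test_that("forward/inverse round-trip over the shell at every frame", {
  ph <- phantom_fixture()
  set.seed(71)
  X <- cbind(runif(3000, 6, 58), runif(3000, 6, 58), runif(3000, 12, 42))
  X <- X[ph$truth$in_shell(X), , drop = FALSE]
  expect_gt(nrow(X), 500)
  for (t in seq_len(ph$spec$n_frames)) {
    y <- ph$truth$forward(X, t)
    back <- ph$truth$inverse(y, t)
    expect_lt(max(abs(back - X)), 1e-8)
  }
})

test_that("oracle strain is self-consistent with its deformation gradient", {
  ph <- phantom_fixture()
  set.seed(72)
  X <- cbind(runif(200, 15, 49), runif(200, 15, 49), runif(200, 18, 38))
  X <- X[ph$truth$in_shell(X), , drop = FALSE]
  Fa <- ph$truth$F(X, 6)
  Ea <- ph$truth$E(X, 6)
  for (k in seq_len(dim(Fa)[3])) {
    expect_lt(max(abs(Ea[, , k] -
                        (t(Fa[, , k]) %*% Fa[, , k] - diag(3)) / 2)), 1e-10)
  }
})

test_that("special deformation families have closed-form strain", {
  spec <- phantom_spec(n_frames = 2, end_systolic_index = 2)
  X <- matrix(c(30, 36, 30, 28, 30, 25), 2, 3, byrow = TRUE)
  # zero amplitude = identity
  spec0 <- phantom_spec(n_frames = 3, end_systolic_index = 3)
  tr0 <- make_deformation(spec0, type = "scale", scale_factors = c(1, 1, 1))
  expect_equal(tr0$forward(X, 2), X)
  expect_lt(max(abs(tr0$E(X, 2))), 1e-8)
  # longitudinal scaling z -> 0.9 z: E_zz = -0.095
  trs <- make_deformation(spec, type = "scale",
                          scale_factors = c(1, 1, 0.9))
  E <- trs$E(X, 2)
  expect_equal(E[3, 3, 1], -0.095, tolerance = 1e-6)
  expect_lt(max(abs(E[1:2, , 1])), 1e-7)
  # rigid rotation: E = 0 everywhere
  trr <- make_deformation(spec, type = "rigid", rotation_deg = 17,
                          translation = c(3, 2, -1))
  expect_lt(max(abs(trr$E(X, 2))), 1e-7)
  # translation family: exact displacement, zero strain
  trt <- make_deformation(spec, type = "translation",
                          translation = c(1.5, -2, 0.5))
  expect_equal(trt$forward(X, 2) - X,
               matrix(c(1.5, -2, 0.5), 2, 3, byrow = TRUE))
  expect_lt(max(abs(trt$E(X, 2))), 1e-9)
})

test_that("twist-only deformation has near-zero strain trace", {
  spec <- phantom_spec(n_frames = 2, end_systolic_index = 2,
                       twist_deg = 2, shortening = 0,
                       radial_contraction = 0)
  tr <- make_deformation(spec)
  set.seed(73)
  X <- cbind(runif(100, 15, 49), runif(100, 15, 49), runif(100, 20, 38))
  X <- X[tr$in_shell(X), , drop = FALSE]
  E <- tr$E(X, 2)
  traces <- apply(E, 3, function(e) sum(diag(e)))
  # trace vanishes to first order in the twist angle
  expect_lt(max(abs(traces)), 5e-3)
})

test_that("rendering honours determinism, identity and integer shifts", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), center = c(16, 16, 22),
                       outer_semiaxes = c(12, 12, 13), n_frames = 3,
                       end_systolic_index = 2, seed = 5)
  truth <- make_deformation(spec)
  v1 <- render_frames(spec, truth)
  v2 <- render_frames(spec, truth)
  for (t in 1:3) expect_identical(v1$frames[[t]], v2$frames[[t]])

  # zero amplitude, zero noise, fade 1: all frames identical to frame 0
  spec0 <- phantom_spec(grid_shape = c(32, 32, 32), center = c(16, 16, 22),
                        outer_semiaxes = c(12, 12, 13), n_frames = 3,
                        end_systolic_index = 2, noise_sd = 0,
                        twist_deg = 0, shortening = 0,
                        radial_contraction = 0)
  tr0 <- make_deformation(spec0)
  v0 <- render_frames(spec0, tr0)
  expect_equal(v0$frames[[2]], v0$frames[[1]], tolerance = 1e-12)
  expect_equal(v0$frames[[3]], v0$frames[[1]], tolerance = 1e-12)

  # integer translation renders as an exact shift at interior voxels
  spec_t <- phantom_spec(grid_shape = c(32, 32, 32),
                         center = c(16, 16, 22),
                         outer_semiaxes = c(10, 10, 11), n_frames = 2,
                         end_systolic_index = 2, noise_sd = 0)
  tr_t <- make_deformation(spec_t, type = "translation",
                           translation = c(2, -3, 1))
  v_t <- render_frames(spec_t, tr_t)
  inner <- 6:26
  expect_equal(v_t$frames[[2]][inner + 2, inner - 3, inner + 1],
               v_t$frames[[1]][inner, inner, inner], tolerance = 1e-10)
})

test_that("tag fading attenuates contrast geometrically", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), center = c(16, 16, 22),
                       outer_semiaxes = c(12, 12, 13), n_frames = 3,
                       end_systolic_index = 2, noise_sd = 0,
                       twist_deg = 0, shortening = 0,
                       radial_contraction = 0, fade_rate = 0.2)
  tr <- make_deformation(spec)
  v <- render_frames(spec, tr)
  dev1 <- v$frames[[2]] - spec$background_level
  dev0 <- v$frames[[1]] - spec$background_level
  expect_equal(dev1, dev0 * 0.8, tolerance = 1e-10)
})

test_that("exported truth matches closed forms and flags outside points", {
  spec <- phantom_spec(n_frames = 3, end_systolic_index = 2)
  tr <- make_deformation(spec, type = "scale",
                         scale_factors = c(0.95, 0.95, 0.95))
  lms <- phantom_landmarks(spec)
  out <- export_truth(tr, lms)
  expect_equal(nrow(out$trajectories), 3 * nrow(lms))
  # frame 1 trajectory equals the initial position, E = 0
  f1 <- out$trajectories[out$trajectories$frame == 1, ]
  expect_equal(cbind(f1$x, f1$y, f1$z), voxel_to_mm(lms, 0.96),
               ignore_attr = TRUE)
  expect_lt(max(abs(out$strain[[1]])), 1e-8)
  # uniform scaling: E = (lambda^2 - 1)/2 * I at full amplitude
  lam <- 0.95
  expect_equal(out$strain[[2]][1, 1, 1], (lam^2 - 1) / 2, tolerance = 1e-6)
  expect_lt(max(abs(out$strain[[2]][1, 2, ])), 1e-7)
  # point outside the shell is flagged
  expect_warning(export_truth(tr, rbind(lms, c(1, 1, 1))), "outside")
})

test_that("non-invertible radial parameters are rejected", {
  expect_error(make_deformation(phantom_spec(radial_contraction = 1.2)),
               "non-invertible")
})

test_that("phantom displacement and strain oracles peak at end-systole", {
  ph <- phantom_fixture()
  set.seed(74)
  X <- cbind(runif(500, 10, 54), runif(500, 10, 54), runif(500, 16, 38))
  X <- X[ph$truth$in_shell(X), , drop = FALSE]
  u_norm <- sapply(seq_len(ph$spec$n_frames), function(t) {
    median(sqrt(rowSums((ph$truth$forward(X, t) - X)^2)))
  })
  expect_equal(which.max(u_norm), ph$spec$end_systolic_index)
})
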
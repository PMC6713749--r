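test_that("weight kernel satisfies its boundary contract", {
  expect_equal(lwm_weight(0), 1)
  expect_equal(lwm_weight(1), 0)
  expect_equal(lwm_weight(0.5), 0.5)     # 1 - 3/4 + 1/4
  expect_equal(lwm_weight(1.5), 0)
  expect_equal(lwm_weight(c(0, 0.5, 2)), c(1, 0.5, 0))
  expect_error(lwm_weight(-0.1), "non-negative")
  # vanishing first derivative at both ends (numeric)
  h <- 1e-7
  expect_lt(abs((lwm_weight(h) - lwm_weight(0)) / h), 1e-6)
  expect_lt(abs((lwm_weight(1) - lwm_weight(1 - h)) / h), 1e-6)
  # monotone decreasing on [0, 1]
  r <- seq(0, 1, by = 0.01)
  expect_true(all(diff(lwm_weight(r)) <= 0))
})

make_grid_points <- function(k = 8, pitch = 2, jitter = 0) {
  g <- as.matrix(expand.grid(seq_len(k) - 1, seq_len(k) - 1,
                             seq_len(k) - 1)) * pitch
  # small symmetric grid neighbourhoods can be rank deficient for the
  # quadratic basis; jitter breaks the degeneracy where small n is wanted
  if (jitter > 0) g <- g + matrix(runif(length(g), -jitter, jitter), ncol = 3)
  g
}

test_that("LWM reproduces identity, affine and quadratic maps exactly", {
  set.seed(31)
  src <- make_grid_points()
  maps <- list(
    identity = function(p) p,
    affine = function(p) {
      A <- matrix(c(1.02, 0.01, 0, 0.02, 0.98, 0.01, 0, 0.03, 1.01), 3, 3)
      p %*% A + matrix(c(1, -2, 0.5), nrow(p), 3, byrow = TRUE)
    },
    quadratic = function(p) {
      cbind(p[, 1] + 0.001 * p[, 1]^2 + 0.002 * p[, 1] * p[, 2],
            p[, 2] - 0.001 * p[, 3]^2,
            p[, 3] + 0.0005 * p[, 2]^2 + 0.001 * p[, 1] * p[, 3])
    })
  q <- matrix(runif(600, 2, 12), 200, 3)
  for (nm in names(maps)) {
    tr <- lwm_fit(src, maps[[nm]](src), n = 40)
    got <- lwm_evaluate(tr, q)
    expect_lt(max(abs(got - maps[[nm]](q))), 1e-6)
  }
})

test_that("evaluation at a control point with single support returns its polynomial", {
  # two distant clusters: a query at one cluster's centre is influenced by
  # that cluster only
  set.seed(32)
  c1 <- matrix(rnorm(60, 0, 2), 20, 3)
  c2 <- matrix(rnorm(60, 100, 2), 20, 3)
  src <- rbind(c1, c2)
  dst <- src * 1.1
  tr <- lwm_fit(src, dst, n = 20)
  got <- lwm_evaluate(tr, c1[1, , drop = FALSE])
  expect_lt(max(abs(got - 1.1 * c1[1, ])), 1e-8)
})

test_that("far queries fall back to the nearest control point's polynomial", {
  set.seed(40)
  src <- make_grid_points(5, 1, jitter = 0.2)
  tr <- lwm_fit(src, src * 2, n = 20)
  far <- matrix(c(1000, 1000, 1000), 1, 3)
  # the fitted local map is globally p -> 2p, so the fallback polynomial
  # extrapolates it
  expect_equal(as.numeric(lwm_evaluate(tr, far)), c(2000, 2000, 2000),
               tolerance = 1e-6)
})

test_that("local support: perturbing one target only acts inside its radius", {
  set.seed(33)
  src <- make_grid_points(10, 2)
  dst <- src
  tr0 <- lwm_fit(src, dst, n = 30)
  # perturb a point near the middle of the cloud
  i <- which.min(rowSums(sweep(src, 2, colMeans(src))^2))
  dst2 <- dst
  dst2[i, ] <- dst2[i, ] + c(5, 0, 0)
  tr1 <- lwm_fit(src, dst2, n = 30)
  q <- rbind(matrix(runif(900, 0, 18), 300, 3),
             sweep(matrix(rnorm(60, 0, 0.8), 20, 3), 2, src[i, ], `+`))
  delta <- rowSums(abs(lwm_evaluate(tr1, q) - lwm_evaluate(tr0, q)))
  d_to_i <- sqrt(rowSums(sweep(q, 2, src[i, ])^2))
  # beyond every influence radius that the perturbed point participates in,
  # nothing changes; the affected neighbourhood is bounded by the largest
  # radius among control points whose fit uses point i
  nn <- sqrt(rowSums(sweep(src, 2, src[i, ])^2))
  reach <- max(tr0$radii[nn <= max(tr0$radii)]) + max(tr0$radii)
  expect_true(all(delta[d_to_i > reach] == 0))
  expect_gt(max(delta[d_to_i < 2]), 0.1)
})

test_that("weights form a partition: mean lies within local predictions", {
  set.seed(34)
  src <- make_grid_points(6, 2, jitter = 0.3)
  dst <- src + matrix(rnorm(length(src), 0, 0.1), ncol = 3)
  tr <- lwm_fit(src, dst, n = 15)
  q <- matrix(runif(150, 1, 9), 50, 3)
  got <- lwm_evaluate(tr, q)
  for (k in seq_len(nrow(q))) {
    d <- sqrt(rowSums(sweep(src, 2, q[k, ])^2))
    contrib <- which(d < tr$radii)
    if (length(contrib) < 2) next
    vals <- t(vapply(contrib, function(i) {
      dx <- q[k, ] - src[i, ]
      b <- c(1, dx, dx^2, dx[1] * dx[2], dx[1] * dx[3], dx[2] * dx[3])
      c(sum(tr$coef[i, 1:10] * b), sum(tr$coef[i, 11:20] * b),
        sum(tr$coef[i, 21:30] * b))
    }, numeric(3)))
    expect_true(all(got[k, ] >= apply(vals, 2, min) - 1e-9))
    expect_true(all(got[k, ] <= apply(vals, 2, max) + 1e-9))
  }
})

test_that("transform is numerically C1 across influence boundaries", {
  set.seed(35)
  src <- make_grid_points(8, 2)
  dst <- src + matrix(rnorm(length(src), 0, 0.2), ncol = 3)
  tr <- lwm_fit(src, dst, n = 30)
  # directional derivative continuity along a line crossing many radii
  tvals <- seq(1, 13, by = 0.01)
  line <- cbind(tvals, tvals * 0.7 + 1, tvals * 0.3 + 2)
  v <- lwm_evaluate(tr, line)
  d1 <- diff(v[, 1]) / 0.01
  # second differences stay bounded (no derivative jumps)
  expect_lt(max(abs(diff(d1))), 1.0)
})

test_that("jacobian is exact on affine maps and O(h^2) on quadratics", {
  set.seed(36)
  src <- make_grid_points()
  A <- matrix(c(1.1, 0.05, 0, -0.02, 0.9, 0.01, 0.03, 0, 1.02), 3, 3)
  tr <- lwm_fit(src, src %*% A, n = 40)
  q <- matrix(runif(30, 3, 11), 10, 3)
  J <- lwm_jacobian(tr, q, h = 0.25)
  for (k in 1:10) expect_lt(max(abs(J[, , k] - t(A))), 1e-8)

  quad <- function(p) cbind(p[, 1] + 0.002 * p[, 1]^2, p[, 2], p[, 3])
  trq <- lwm_fit(src, quad(src), n = 40)
  Jq <- lwm_jacobian(trq, q, h = 0.25)
  for (k in 1:10) {
    expect_lt(abs(Jq[1, 1, k] - (1 + 0.004 * q[k, 1])), 1e-6)
  }
})

test_that("fit validates its preconditions", {
  src <- make_grid_points(4, 1)
  expect_error(lwm_fit(src, src, n = nrow(src) + 1), "control points")
  expect_error(lwm_fit(src, src, n = 5), "at least 10")
  # coplanar control points: quadratic basis is rank deficient
  flat <- cbind(matrix(runif(80), 40, 2), 0)
  expect_error(lwm_fit(flat, flat, n = 20), "rank-deficient")
})

test_that("duplicate source positions are collapsed before fitting", {
  set.seed(37)
  src <- make_grid_points(5, 2, jitter = 0.3)
  dup <- rbind(src, src[1:30, ])
  dst <- rbind(src, src[1:30, ]) * 1.5
  tr <- lwm_fit(dup, dst, n = 50)
  expect_equal(nrow(tr$source), nrow(src))
  q <- matrix(runif(30, 1, 7), 10, 3)
  expect_lt(max(abs(lwm_evaluate(tr, q) - 1.5 * q)), 1e-7)
})

test_that("JSON serialization round-trips the transform", {
  set.seed(38)
  src <- make_grid_points(5, 2, jitter = 0.3)
  tr <- lwm_fit(src, src * 1.2 + 1, n = 20)
  path <- tempfile(fileext = ".json")
  lwm_to_json(tr, path)
  tr2 <- lwm_from_json(path)
  q <- matrix(runif(60, 0, 8), 20, 3)
  expect_equal(lwm_evaluate(tr2, q), lwm_evaluate(tr, q), tolerance = 1e-12)
  expect_equal(tr2$n, tr$n)
  expect_equal(tr2$direction, tr$direction)
})

test_that("per-evaluation radius mode is selectable", {
  set.seed(39)
  src <- make_grid_points(6, 2, jitter = 0.3)
  tr <- lwm_fit(src, src * 1.3, n = 12)
  q <- matrix(runif(30, 2, 8), 10, 3)
  a <- lwm_evaluate(tr, q, radius_mode = "control")
  b <- lwm_evaluate(tr, q, radius_mode = "evaluation")
  # both reproduce the global affine map
  expect_lt(max(abs(a - 1.3 * q)), 1e-7)
  expect_lt(max(abs(b - 1.3 * q)), 1e-7)
})

test_that("tidy and glance summarise the fit", {
  set.seed(44)
  src <- make_grid_points(5, 2, jitter = 0.3)
  tr <- lwm_fit(src, src, n = 20)
  td <- tidy(tr)
  expect_equal(nrow(td), nrow(src))
  expect_lt(max(td$residual), 1e-9)
  g <- glance(tr)
  expect_equal(g$n_control, nrow(src))
  expect_equal(g$direction, "moving_to_reference")
})
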
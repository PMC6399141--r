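test_that("MFS source surfaces scale about the centroids and stay contained", {
  ph <- fx_phantom()
  src <- ph$sources
  inner <- src$source_points[seq_len(src$n_inner), ]
  expect_equal(sqrt(rowSums(inner^2)), rep(24, nrow(inner)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(points_in_mesh(inner, ph$heart)))
  outer <- src$source_points[-seq_len(src$n_inner), ]
  expect_false(any(points_in_mesh(outer, ph$tank)))
  expect_te_error(build_sources(ph$heart, ph$tank, deflate = 1), "invalid_parameter")
  # ellipsoid heart: deflated points are strictly interior too
  ell <- make_heart_mesh(c(30, 25, 40), c(5, 0, 0), 8)
  tank2 <- make_torso_tank(ell, c(3, 3, 3), 40)
  src2 <- build_sources(ell, tank2)
  expect_true(all(points_in_mesh(src2$source_points[seq_len(src2$n_inner), ], ell)))
})

test_that("MFS system structure and kernel arithmetic", {
  ph <- fx_phantom()
  sys <- build_system(ph$sources, ph$electrodes)
  m <- nrow(ph$sources$source_points)
  expect_identical(dim(sys$A), c(256L, m + 1L))
  expect_true(all(sys$A[1:128, 1] == 1))
  expect_true(all(sys$A[129:256, 1] == 0))
  # single source at distance 1/(4pi): Dirichlet entry is exactly 1
  es1 <- electrode_set(matrix(c(0, 0, 1 / (4 * pi)), 1), "e1", 1L,
                       normals = matrix(c(0, 0, 1), 1))
  src1 <- structure(list(source_points = matrix(0, 1, 3), deflate = 0.8,
                         inflate = 1.2, n_inner = 1L), class = "mfs_sources")
  sys1 <- build_system(src1, es1)
  expect_equal(sys1$A[1, 2], 1)
  # source along the inward normal at distance r: Neumann entry +1/(4 pi r^2)
  r <- 2
  es2 <- electrode_set(matrix(c(0, 0, r), 1), "e1", 1L,
                       normals = matrix(c(0, 0, 1), 1))
  sys2 <- build_system(src1, es2)
  expect_equal(sys2$A[2, 2], -1 / (4 * pi * r^2))
})

test_that("Tikhonov SVD solver against the normal-equations oracle", {
  set.seed(10)
  for (rep in 1:3) {
    A <- matrix(rnorm(50 * 80), 50, 80)
    b <- rnorm(50)
    sol <- tikhonov_solve(A, b, 0.1)
    oracle <- solve(crossprod(A) + 0.01 * diag(80), crossprod(A, b))
    expect_lt(max(abs(sol$coeffs - oracle)), 1e-8)
    expect_equal(sol$residual_norm, sqrt(sum((A %*% sol$coeffs - b)^2)),
                 tolerance = 1e-10)
    expect_equal(sol$solution_norm, sqrt(sum(sol$coeffs^2)), tolerance = 1e-10)
  }
  # lam = 0 on a well-conditioned square system is an exact solve
  Asq <- diag(5) + 0.1 * matrix(rnorm(25), 5)
  bsq <- rnorm(5)
  expect_lt(tikhonov_solve(Asq, bsq, 0)$residual_norm, 1e-8)
  # heavy damping kills the solution
  x0 <- tikhonov_solve(Asq, bsq, 0)$coeffs
  xb <- tikhonov_solve(Asq, bsq, 1e6 * max(svd(Asq)$d))$coeffs
  expect_lt(sqrt(sum(xb^2)), 1e-6 * sqrt(sum(x0^2)))
  expect_te_error(tikhonov_solve(matrix(c(1, NA, 1, 1), 2), c(1, 1), 0.1),
                  "input_error")
})

test_that("Tikhonov norms are monotone in lambda", {
  set.seed(11)
  A <- matrix(rnorm(40 * 30), 40, 30)
  b <- rnorm(40)
  grid <- 10^seq(-6, 2, length.out = 40)
  sols <- lapply(grid, function(l) tikhonov_solve(A, b, l))
  sn <- vapply(sols, `[[`, 0, "solution_norm")
  rn <- vapply(sols, `[[`, 0, "residual_norm")
  expect_true(all(diff(sn) <= 1e-12))
  expect_true(all(diff(rn) >= -1e-12))
})

test_that("CRESO selection: rank-1 oracle, fallback, finite differences", {
  # rank-1, sigma = 1, u' b = 1: lambda* solves 3 l^4 - 8 l^2 + 1 = 0
  A1 <- diag(c(1, 0))
  b1 <- c(1, 0)
  grid <- exp(seq(log(1e-4), log(1), length.out = 200))
  lam <- creso_select(A1, b1, grid)
  root <- sqrt((8 - sqrt(52)) / 6)
  step <- log(grid[2] / grid[1])
  expect_lt(abs(log(as.numeric(lam) / root)), step + 1e-12)
  expect_warning(creso_select(A1, c(0, 0), grid), class = "creso_fallback")
  # analytic C(lambda) vs central finite differences of lambda^2 ||x||^2
  set.seed(12)
  A <- matrix(rnorm(30 * 20), 30, 20)
  b <- rnorm(30)
  sv <- svd(A)
  lams <- 10^seq(-3, 0, length.out = 7) * sv$d[1]
  C <- tankecgi:::creso_curve(sv, b, lams)
  for (i in seq_along(lams)) {
    h <- 1e-6 * lams[i]
    f <- function(l) {
      s <- tikhonov_solve(sv, b, l)
      l^2 * s$solution_norm^2
    }
    fd <- (f(lams[i] + h) - f(lams[i] - h)) / (2 * h)
    expect_lt(abs(C[i] - fd) / abs(fd), 1e-6)
  }
})

test_that("sphere-phantom ECGI recovery", {
  ph <- fx_phantom()
  f <- fx_harmonic_field(3, seed = 3)
  ts <- signal_block(matrix(f$tank_values, ncol = 1), rate = 1000,
                     channel_ids = ph$electrodes$labels)
  rec <- reconstruct_egms(ts, ph$sources, ph$heart, ph$electrodes)
  x <- rec$samples[, 1]
  truth <- f$heart_values
  expect_gt(cor(x, truth), 0.95)
  # potentials are referenced quantities: compare centred patterns
  relrmse <- sqrt(mean(((x - mean(x)) - (truth - mean(truth)))^2)) / sd(truth)
  expect_lt(relrmse, 0.2)
  # 30 dB tank noise, 5 seeds
  for (s in 1:5) {
    set.seed(s)
    noisy <- f$tank_values + rnorm(128, sd = sd(f$tank_values) / 10^(30 / 20))
    tsn <- signal_block(matrix(noisy, ncol = 1), rate = 1000,
                        channel_ids = ph$electrodes$labels)
    expect_gt(cor(reconstruct_egms(tsn, ph$sources, ph$heart,
                                   ph$electrodes)$samples[, 1], truth), 0.9)
  }
})

test_that("reconstruction linearity, zero input, channel guards", {
  ph <- fx_phantom()
  f <- fx_harmonic_field(2, seed = 8)
  ts <- signal_block(cbind(f$tank_values, 2 * f$tank_values), rate = 1000,
                     channel_ids = ph$electrodes$labels)
  rec <- reconstruct_egms(ts, ph$sources, ph$heart, ph$electrodes, lam = 1e-3)
  expect_equal(rec$samples[, 2], 2 * rec$samples[, 1], tolerance = 1e-9)
  z <- signal_block(matrix(0, 128, 2), rate = 1000,
                    channel_ids = ph$electrodes$labels)
  expect_lt(max(abs(suppressWarnings(
    reconstruct_egms(z, ph$sources, ph$heart, ph$electrodes))$samples)), 1e-8)
  bad <- ph$electrodes
  bad$valid[1:50] <- FALSE
  expect_te_error(reconstruct_egms(ts, ph$sources, ph$heart, bad),
                  "reconstruction_refused")
})
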
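truth_cam <- function() camera_model(c(0, 0, 300), c(0, 0, 0))

test_that("perspective projection basics", {
  cam <- truth_cam()
  ctr <- project(cam, matrix(c(0, 0, 0), 1))
  expect_equal(c(ctr$u, ctr$v), c(49.5, 49.5))
  behind <- project(cam, matrix(c(0, 0, 400), 1))
  expect_false(behind$visible)
  # two points on one ray through the camera project identically
  p <- project(cam, rbind(c(10, 5, 0), c(5, 2.5, 150)))
  expect_equal(p$u[1], p$u[2])
  expect_equal(p$v[1], p$v[2])
  # doubling focal_scale doubles offsets from the image centre
  cam2 <- camera_model(cam$X_COP, cam$X_FOC, focal_scale = 2 * cam$focal_scale)
  p2 <- project(cam2, rbind(c(10, 5, 0)))
  expect_equal(p2$u - 49.5, 2 * (p$u[1] - 49.5))
  expect_equal(p2$v - 49.5, 2 * (p$v[1] - 49.5))
  expect_te_error(camera_model(c(0, 0, 1), c(0, 0, 1)), "degenerate_camera")
})

test_that("reprojection cost", {
  cam <- truth_cam()
  es <- place_electrodes(fx_sphere30(), 12, seed = 2)
  pr <- project(cam, es$positions)
  E2D <- cbind(pr$u, pr$v)
  expect_equal(as.numeric(electrode_cost(cam, es, E2D)), 0)
  # a single 3-4-5 offset
  E2D1 <- E2D; E2D1[1, ] <- E2D1[1, ] + c(3, 4)
  one <- electrode_cost(cam, es, cbind(c(E2D1[1, 1], rep(NA, 11)),
                                       c(E2D1[1, 2], rep(NA, 11))))
  expect_equal(as.numeric(one), 5)
  # mean over two electrodes offset 0 and 10
  E2Dm <- matrix(NA_real_, 12, 2)
  E2Dm[1, ] <- E2D[1, ]; E2Dm[2, ] <- E2D[2, ] + c(10, 0)
  expect_equal(as.numeric(electrode_cost(cam, es, E2Dm)), 5)
  expect_te_error(electrode_cost(cam, es, matrix(NA_real_, 12, 2)),
                  "cost_undefined")
})

test_that("stage-1 optimization recovers a 20 mm perturbed camera", {
  cam <- truth_cam()
  h <- make_heart_mesh(c(30, 30, 35), c(0, 0, 0), 4)
  es <- place_electrodes(h, 108, seed = 2)
  pr <- project(cam, es$positions)
  E2D <- cbind(pr$u, pr$v); E2D[!pr$visible, ] <- NA
  set.seed(11)
  d <- rnorm(3); d <- d / sqrt(sum(d^2)) * 20
  init <- camera_model(cam$X_COP + d, cam$X_FOC + rnorm(3, sd = 3),
                       roll = 0.02, focal_scale = cam$focal_scale * 1.03)
  expect_gt(as.numeric(electrode_cost(init, es, E2D)), 5)
  opt <- optimize_stage1(init, es, E2D, seed = 7)
  expect_lt(attr(opt, "cost_px"), 0.5)
  # starting at the truth is a fixed point (cost stays at 0)
  opt0 <- optimize_stage1(cam, es, E2D, n_starts = 1, seed = 1)
  expect_lt(attr(opt0, "cost_px"), 1e-6)
  expect_te_error(optimize_stage1(init, es, E2D[c(1:3, rep(NA, 105)), ]),
                  "precondition_error")
})

test_that("activation-time cost and stage-2 refinement", {
  cam <- truth_cam()
  h <- fx_sphere30()
  es <- place_electrodes(h, 16, seed = 9)
  grid <- matrix(TRUE, 100, 100)
  mask <- data_mask(grid)
  at_field <- time_map(rep(100, 10000), domain_tag = "optical_pixels")
  sock_at <- time_map(rep(100, 16), domain_tag = "sock_electrodes")
  expect_equal(as.numeric(at_cost(cam, es, sock_at, at_field, mask)), 0)
  sock2 <- time_map(c(104, 106, rep(100, 14)), domain_tag = "sock_electrodes")
  pr <- project(cam, es$positions)
  expect_true(all(pr$visible))
  j <- at_cost(cam, es, sock2, at_field, mask)
  expect_equal(as.numeric(j), mean(abs(sock2$times - 100)))
  # moving the camera along its own view axis leaves a uniform-field cost flat
  cam_back <- camera_model(c(0, 0, 330), c(0, 0, 0),
                           focal_scale = cam$focal_scale)
  expect_equal(as.numeric(at_cost(cam_back, es, sock2, at_field, mask)),
               as.numeric(j))
  # a flat cost cannot be refined: stage-2 returns the input with a warning
  expect_warning(
    st2 <- optimize_stage2(cam, es, sock_at, at_field, mask),
    class = "flat_cost")
  expect_equal(st2$X_COP, cam$X_COP)
  expect_lte(attr(st2, "cost_ms"), as.numeric(at_cost(cam, es, sock_at, at_field, mask)))
})

test_that("visible submesh keeps roughly the camera-facing half", {
  h <- fx_sphere_fine()
  cam <- camera_model(c(0, 0, 1000), c(0, 0, 0), focal_scale = 1000 / 0.7)
  vs <- visible_submesh(cam, h)
  frac <- length(vs$vertices) / nrow(h$vertices)
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
  # all assigned pixels inside the frame
  expect_true(all(vs$pixels >= 0 & vs$pixels <= 99))
  # an explicitly backfacing vertex is removed
  back <- which.min(h$vertices[, 3])
  expect_false(back %in% vs$vertices)
})
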
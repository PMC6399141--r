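test_that("graph-geodesic activation matches the analytic great circle", {
  h <- fx_sphere30()
  sc <- scenario_config(pacing_site = 1L, cv_base = 0.5)
  at <- simulate_activation(h, sc)
  expect_identical(at$times[1], 0)
  antipode <- which.max(rowSums(sweep(h$vertices, 2, h$vertices[1, ])^2))
  analytic <- pi * 30 / 0.5
  expect_gte(at$times[antipode], analytic * 0.99)
  expect_lte(at$times[antipode], analytic * 1.08) # graph overestimate bound
  expect_te_error(
    simulate_activation(h, scenario_config(pacing_site = 10000L)),
    "invalid_parameter")
})

test_that("regional conduction slowing never speeds activation up", {
  h <- fx_sphere30()
  region <- perfusion_bed(h, 40L, 20)
  base <- simulate_activation(h, scenario_config(pacing_site = 1L, cv_base = 1))
  slow <- simulate_activation(h, scenario_config(
    pacing_site = 1L, cv_base = 1, perfusion_region = region,
    cv_factor_region = 0.5))
  expect_true(all(slow$times >= base$times - 1e-12))
  expect_gt(max(slow$times[region] - base$times[region]), 0)
})

test_that("action-potential templates put dVm/dt extremes at AT and AT+APD", {
  at <- time_map(c(50, 80), domain_tag = "mesh_nodes")
  vm <- synthesize_vm(at, c(200, 230), rate = 1000, n_beats = 1, cycle_ms = 500)
  d <- t(apply(vm$samples, 1, diff))
  expect_true(abs(which.max(d[1, ]) - 50) <= 1)
  expect_true(which.min(d[1, ]) >= 248 && which.min(d[1, ]) <= 252)
  # +30 ms APD shifts the repolarization marker by 30 +- 2 ms
  vm2 <- synthesize_vm(at, c(230, 230), rate = 1000, n_beats = 1, cycle_ms = 500)
  d2 <- t(apply(vm2$samples, 1, diff))
  expect_lte(abs((which.min(d2[1, ]) - which.min(d[1, ])) - 30), 2)
  expect_true(all(vm$samples >= 0 & vm$samples <= 1 + 1e-9))
  expect_te_error(
    synthesize_vm(at, c(480, 480), rate = 1000, n_beats = 1, cycle_ms = 500),
    "overlap_error")
})

test_that("unipolar electrograms carry the construction guarantees", {
  fx <- fx_beat()
  # spatially uniform Vm cancels exactly
  vmu <- fx$vm
  vmu$samples <- matrix(rep(colMeans(fx$vm$samples), each = nrow(fx$vm$samples)),
                        nrow(fx$vm$samples))
  egm0 <- synthesize_unipolar_egm(vmu, fx$heart, fx$electrodes)
  expect_lt(max(abs(egm0$samples)), 1e-12)
  # intrinsic deflection at local AT, T-wave upslope at local AT+APD
  truth_at <- fx$at$times[fx$electrodes$host_vertex]
  ats <- vapply(seq_len(24), function(i)
    at_from_egm(fx$egm$samples[i, ], fx$egm$rate), 0)
  expect_lte(max(abs(ats - truth_at)), 2)
  rts <- vapply(seq_len(24), function(i)
    rt_from_egm(fx$egm$samples[i, ], fx$egm$rate, at = ats[i]), 0)
  expect_lte(max(abs(rts - (truth_at + 190))), 2)
})

test_that("analytic concentric-spheres transfer", {
  expect_equal(sphere_transfer(0, 1, 2, 1.5), 1)
  expect_equal(sphere_transfer(1, 1, 2, 2), 3 / 5)
  # strictly decreasing in degree at the outer surface
  tl <- sphere_transfer(1:10, 30, 60, 60)
  expect_true(all(diff(tl) < 0))
  expect_te_error(forward_spheres_analytic(
    data.frame(l = 0, m = 0, c = 1), 1, 2, 2.5), "domain_error")
  expect_te_error(forward_spheres_analytic(
    data.frame(l = 0, m = 0, c = 1), 1, 2, 0.5), "domain_error")
})

test_that("MFS forward solver matches the spheres oracle within 2%", {
  ph <- fx_phantom()
  f <- fx_harmonic_field(5, seed = 42)
  blk <- signal_block(matrix(f$heart_values, ncol = 1), rate = 1000)
  out <- forward_mfs(blk, ph$heart, ph$tank, ph$electrodes)
  rel <- sqrt(mean((out$samples[, 1] - f$tank_values)^2)) /
    sqrt(mean(f$tank_values^2))
  expect_lt(rel, 0.02)
  # uniform Dirichlet data propagates unchanged (l = 0)
  blku <- signal_block(matrix(rep(2, nrow(ph$heart$vertices)), ncol = 1), rate = 1000)
  outu <- forward_mfs(blku, ph$heart, ph$tank, ph$electrodes)
  expect_lt(max(abs(outu$samples - 2)), 0.02)
  # zero in, zero out; superposition
  blk0 <- signal_block(matrix(0, nrow(ph$heart$vertices), 1), rate = 1000)
  expect_lt(max(abs(forward_mfs(blk0, ph$heart, ph$tank, ph$electrodes)$samples)), 1e-10)
  blk2 <- signal_block(cbind(f$heart_values, 2 * f$heart_values), rate = 1000)
  out2 <- forward_mfs(blk2, ph$heart, ph$tank, ph$electrodes)
  expect_equal(out2$samples[, 2], 2 * out2$samples[, 1], tolerance = 1e-8)
})

test_that("optical rendering is faithful where noiseless and unblurred", {
  fx <- fx_beat()
  cam <- camera_model(c(0, 0, 300), c(0, 0, 0))
  stack <- render_optical(fx$vm, fx$heart, cam, fx$scenario, blur_sigma_px = 0)
  expect_identical(stack$image_size, c(100L, 100L))
  expect_equal(nrow(stack$frames), 10000L)
  pv <- attr(stack, "pixel_vertex")
  covered <- which(!is.na(pv))
  expect_gt(length(covered), 500)
  idx <- covered[seq(1, length(covered), length.out = 50)]
  for (i in idx) {
    atp <- at_from_optical(stack$frames[i, ], stack$rate, stack$t0)
    expect_lte(abs(atp - fx$at$times[pv[i]]), 2)
  }
  # sync square wave is high exactly during the exposure
  sy <- stack$sync
  expect_equal(sum(sy), ncol(stack$frames) * stack$sync_rate / stack$rate)
  # camera that misses the heart entirely
  away <- camera_model(c(0, 0, 300), c(0, 0, 600))
  expect_te_error(render_optical(fx$vm, fx$heart, away, fx$scenario),
                  "empty_view")
})
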
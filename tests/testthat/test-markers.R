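test_that("electrogram AT marker and translation equivariance", {
  tt <- seq(0, 499, by = 1)
  egm <- -plogis((tt - 120) / 0.8) + 0.3 * plogis((tt - 320) / 6)
  expect_lte(abs(at_from_egm(egm, 1000) - 120), 1)
  # shifting the trace start time shifts the marker exactly
  expect_equal(at_from_egm(egm, 1000, t0 = 15) - at_from_egm(egm, 1000), 15)
  # shifting the waveform itself
  egm2 <- -plogis((tt - 135) / 0.8) + 0.3 * plogis((tt - 335) / 6)
  expect_equal(at_from_egm(egm2, 1000) - at_from_egm(egm, 1000), 15)
  expect_true(is.na(at_from_egm(rep(0.5, 500), 1000)))
  set.seed(5)
  expect_true(is.na(at_from_egm(rnorm(500, sd = 1e-9), 1000)))
})

test_that("optical AT marker and polarity contract", {
  tt <- seq(0, 499, by = 1)
  f <- plogis((tt - 80) / 0.8) * plogis(-(tt - 280) / 6)
  expect_lte(abs(at_from_optical(f, 1000) - 80), 2)
  expect_true(is.na(at_from_optical(-f, 1000)))    # inverted polarity
  expect_true(is.na(at_from_optical(rep(1, 500), 1000))) # constant
})

test_that("repolarization markers", {
  tt <- seq(0, 499, by = 1)
  egm <- -plogis((tt - 100) / 0.8) + 0.3 * plogis((tt - 300) / 6)
  at <- at_from_egm(egm, 1000)
  expect_lte(abs(rt_from_egm(egm, 1000, at = at) - 300), 2)
  # APD + 30 shifts RT by 30 +- 2
  egm2 <- -plogis((tt - 100) / 0.8) + 0.3 * plogis((tt - 330) / 6)
  expect_lte(abs(rt_from_egm(egm2, 1000, at = at) -
                 rt_from_egm(egm, 1000, at = at) - 30), 2)
  # window beyond the trace end is invalid
  expect_true(is.na(rt_from_egm(egm, 1000, at = 600)))
  f <- plogis((tt - 80) / 0.8) * plogis(-(tt - 280) / 6)
  expect_lte(abs(rt_from_optical(f, 1000, at = 80) - 280), 2)
  expect_true(is.na(rt_from_optical(tt / 500, 1000, at = 80))) # monotone rise
})

test_that("noiseless beat: all four marker rules recover truth, RMSE <= 2 ms", {
  fx <- fx_beat()
  truth_at <- fx$at$times[fx$electrodes$host_vertex]
  truth_rt <- truth_at + 190
  mk <- detect_markers(fx$egm)
  expect_lt(sqrt(mean((mk$at$times - truth_at)^2)), 2)
  expect_lt(sqrt(mean((mk$rt$times - truth_rt)^2)), 2)
  cam <- camera_model(c(0, 0, 300), c(0, 0, 0))
  stack <- render_optical(fx$vm, fx$heart, cam, fx$scenario, blur_sigma_px = 0)
  pv <- attr(stack, "pixel_vertex")
  grid <- matrix(FALSE, 100, 100)
  rc <- which(!is.na(pv))
  grid[cbind((rc - 1) %/% 100 + 1, (rc - 1) %% 100 + 1)] <- TRUE
  omk <- optical_markers(stack, data_mask(grid))
  ok <- !is.na(pv) & omk$at$valid
  expect_lt(sqrt(mean((omk$at$times[ok] - fx$at$times[pv[ok]])^2)), 2)
  okr <- !is.na(pv) & omk$rt$valid
  expect_lt(sqrt(mean((omk$rt$times[okr] -
                       (fx$at$times[pv[okr]] + 190))^2)), 2)
  # cross-modality RT agreement at matched sites (within +-3 ms)
  lin <- (fx$electrodes$host_vertex %in% pv)
  for (i in which(lin)[1:10]) {
    px <- which(pv == fx$electrodes$host_vertex[i])[1]
    expect_lte(abs(mk$rt$times[i] - omk$rt$times[px]), 3)
  }
})

test_that("marker sets enforce rt > at", {
  at <- time_map(c(10, 20), domain_tag = "sock_electrodes")
  rt_bad <- time_map(c(5, 50), domain_tag = "sock_electrodes")
  expect_te_error(marker_set(at, rt_bad), "invalid_marker")
})

test_that("GAF fit matches a dense least-squares oracle", {
  set.seed(21)
  n <- 50
  edges <- cbind(seq_len(n - 1), 2:n)
  extra <- cbind(sample(n, 30, TRUE), sample(n, 30, TRUE))
  extra <- extra[extra[, 1] != extra[, 2], ]
  edges <- rbind(edges, extra)
  delta <- rnorm(nrow(edges), sd = 3)
  w <- runif(nrow(edges), 0.5, 1)
  mu <- 1e-2
  t_pkg <- tankecgi:::gaf_fit(edges, delta, w, n, mu, anchor = 0)
  # dense oracle built from first principles
  B <- matrix(0, nrow(edges), n)
  B[cbind(seq_len(nrow(edges)), edges[, 1])] <- -1
  B[cbind(seq_len(nrow(edges)), edges[, 2])] <- 1
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    L[i, j] <- L[i, j] - 1; L[j, i] <- L[j, i] - 1
    L[i, i] <- L[i, i] + 1; L[j, j] <- L[j, j] + 1
  }
  M <- t(B) %*% diag(w) %*% B + mu * t(L) %*% L
  rhs <- t(B) %*% (w * delta)
  t_or <- qr.solve(M + matrix(1 / n, n, n), rhs) # pin the constant mode
  t_or <- t_or - mean(t_or)
  expect_lt(max(abs(t_pkg - t_or)), 1e-6)
})

test_that("GAF recovers consistent-delay fields and smooths under noise", {
  h <- fx_sphere30()
  sc <- scenario_config(pacing_site = 1L, cv_base = 1, apd_base = 190,
                        noise_snr_db = Inf, seed = 2)
  at <- simulate_activation(h, sc)
  vm <- synthesize_vm(at, apd_field(h, sc), rate = 1000, n_beats = 1,
                      cycle_ms = 500)
  all_nodes <- electrode_set(h$vertices, sprintf("n%03d", seq_len(nrow(h$vertices))),
                             seq_len(nrow(h$vertices)))
  egm <- synthesize_unipolar_egm(vm, h, all_nodes)
  # exact consistent delays through gaf_fit recover a smooth field < 0.1 ms
  # up to gauge (the Laplacian penalty biases kinked fields; see vignette)
  smooth <- 20 * sin(h$vertices[, 1] / 30) + 15 * cos(h$vertices[, 2] / 40)
  e <- mesh_edges(h)
  delta <- smooth[e[, 2]] - smooth[e[, 1]]
  t_fit <- tankecgi:::gaf_fit(e, delta, rep(1, nrow(e)), nrow(h$vertices),
                              mu = 1e-2, anchor = mean(smooth))
  err <- t_fit - smooth
  expect_lt(max(abs(err - mean(err))), 0.1)
  # full pipeline on clean traces tracks the truth closely
  gaf <- global_activation_field(egm, h)
  expect_gt(cor(gaf$times, at$times), 0.97)
  # spatial smoothing property under noise
  set.seed(3)
  egmn <- egm
  egmn$samples <- egm$samples + matrix(rnorm(length(egm$samples),
                                             sd = 0.05 * sd(egm$samples)),
                                       nrow(egm$samples))
  gafn <- global_activation_field(egmn, h)
  rawn <- vapply(seq_len(nrow(egmn$samples)), function(i)
    at_from_egm(egmn$samples[i, ], egmn$rate), 0)
  Lap <- matrix(0, nrow(h$vertices), nrow(h$vertices))
  for (k in seq_len(nrow(e))) {
    i <- e[k, 1]; j <- e[k, 2]
    Lap[i, j] <- -1; Lap[j, i] <- -1
    Lap[i, i] <- Lap[i, i] + 1; Lap[j, j] <- Lap[j, j] + 1
  }
  expect_lt(sqrt(sum((Lap %*% gafn$times)^2)), sqrt(sum((Lap %*% rawn)^2)))
})

test_that("GAF degenerate cases", {
  b <- signal_block(matrix(rnorm(500), 1, 500), rate = 1000)
  single <- global_activation_field(b, cbind(integer(0), integer(0)))
  expect_equal(single$times[1], at_from_egm(b$samples[1, ], 1000))
})
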
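make_stack <- function(frames, ...) optical_stack(frames, ...)

test_that("spatial averaging: kernel size, impulse response, no-op warning", {
  np <- 100 * 100
  frames <- matrix(1, np, 3)
  st <- make_stack(frames)
  expect_equal(spatial_average(st)$frames, frames) # constant invariant
  # 2.1 mm at 0.7 mm/px is a 3 px window: a unit impulse spreads to 1/9
  imp <- matrix(0, np, 1)
  center <- px_idx <- 50 * 100 + 50 + 1
  imp[center, 1] <- 1
  sti <- make_stack(imp)
  out <- spatial_average(sti)
  expect_equal(out$frames[center, 1], 1 / 9)
  expect_equal(sum(out$frames[, 1] > 0), 9L)
  expect_equal(sum(out$frames[, 1]), 1)
  expect_warning(spatial_average(make_stack(imp), kernel_mm = 0.5),
                 class = "kernel_too_small")
})

test_that("spatial averaging respects the data mask", {
  np <- 100 * 100
  set.seed(1)
  frames <- matrix(rnorm(np), np, 1)
  grid <- matrix(FALSE, 100, 100); grid[40:60, 40:60] <- TRUE
  st <- make_stack(frames, mask = grid)
  out <- spatial_average(st)
  inm <- as.logical(t(grid))
  expect_equal(out$frames[!inm, 1], frames[!inm, 1]) # untouched outside
  expect_false(isTRUE(all.equal(out$frames[inm, 1], frames[inm, 1])))
})

test_that("temporal averaging: window, ramp, variance reduction", {
  b <- signal_block(matrix(5, 2, 50), rate = 1000)
  expect_equal(temporal_average(b)$samples, b$samples)
  step <- signal_block(matrix(rep(c(rep(0, 25), rep(1, 25)), each = 1), 1, 50),
                       rate = 1000)
  out <- temporal_average(step) # 1.5 ms at 1 kHz -> 3 samples
  expect_equal(out$samples[1, 24:27], c(0, 1 / 3, 2 / 3, 1))
  set.seed(2)
  noise <- signal_block(matrix(rnorm(20000), 2, 10000), rate = 1000)
  vr <- var(as.numeric(noise$samples)) / var(as.numeric(temporal_average(noise)$samples))
  expect_lt(abs(vr - 3), 0.6) # ~3x within 20%
})

test_that("20% data mask: threshold, components, closing idempotence", {
  np <- 100 * 100
  # all pixels at 0.19 of the max amplitude except one
  frames <- matrix(0, np, 2)
  frames[, 2] <- 0.19
  center <- 50 * 100 + 51
  frames[center, 2] <- 1
  m <- compute_mask(make_stack(frames))
  expect_equal(sum(m$grid), 1L)
  expect_true(m$grid[51, 51])
  # a 10-pixel satellite component is removed, the 5x10 block stays
  frames2 <- matrix(0, np, 2)
  big <- as.vector(outer(20:24 * 100, 20:29, `+`)) + 1L
  small <- as.vector(outer(70:70 * 100, 60:69, `+`)) + 1L
  frames2[c(big, small), 2] <- 1
  m2 <- compute_mask(make_stack(frames2))
  expect_equal(sum(m2$grid), 50L)
  expect_false(any(m2$grid[71, 61:70]))
  # cleanup is idempotent and leaves one component
  expect_true(validate_mask(m2))
  blank <- make_stack(matrix(0, np, 2))
  expect_te_error(compute_mask(blank), "empty_mask")
})

test_that("multi-lead beat averaging", {
  set.seed(3)
  cycle <- 250
  template <- matrix(0, 4, cycle)
  for (i in 1:4) template[i, ] <- dnorm(1:cycle, mean = 60 + 5 * i, sd = 3)
  clean <- cbind(template, template, template, template)
  sig <- signal_block(clean, rate = 1000)
  # n_beats = 1 returns the first cycle untouched
  one <- beat_average(sig, 1)
  i0 <- round(one$t0) + 1L
  expect_equal(one$samples, clean[, i0:(i0 + ncol(one$samples) - 1)],
               ignore_attr = TRUE)
  # averaging 16 noisy repeats reduces residual noise ~ 4x
  clean16 <- do.call(cbind, rep(list(template), 16))
  noisy <- clean16 + matrix(rnorm(length(clean16), sd = 0.01), nrow = 4)
  avg <- beat_average(signal_block(noisy, rate = 1000), 16)
  i0 <- round(avg$t0) + 1L
  resid <- avg$samples - clean[, i0:(i0 + ncol(avg$samples) - 1)]
  ratio <- 0.01 / sd(resid)
  expect_gt(ratio, 4 * 0.8)
  expect_lt(ratio, 4 * 1.2)
  expect_te_error(beat_average(sig, 40), "insufficient_beats")
})

test_that("beat alignment recovers jittered beats exactly when noiseless", {
  cycle <- 250
  template <- matrix(0, 3, cycle)
  for (i in 1:3) template[i, ] <- dnorm(1:cycle, mean = 60 + 4 * i, sd = 3)
  jit <- c(0, 3, -2, 1)
  Tn <- cycle * 4 + 20
  x <- matrix(0, 3, Tn)
  for (k in 0:3) {
    at <- k * cycle + 10 + jit[k + 1]
    x[, at:(at + cycle - 1)] <- x[, at:(at + cycle - 1)] + template
  }
  avg <- beat_average(signal_block(x, rate = 1000), 4)
  i0 <- round(avg$t0 - 0) + 1L
  ref <- x[, i0:(i0 + ncol(avg$samples) - 1)]
  # tail columns can touch the (jittered) next beat; the aligned body is exact
  expect_equal(avg$samples[, 1:230], ref[, 1:230], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("sync alignment and 2:1 decimation", {
  elec <- signal_block(matrix(rnorm(2000), 1, 2000), rate = 2000)
  sync <- c(rep(0, 400), rep(1, 1600))
  expect_equal(sync_align(elec, sync), 200)
  # two pulses: first rising edge wins
  sync2 <- c(rep(0, 100), rep(1, 100), rep(0, 300), rep(1, 100), rep(0, 1400))
  expect_equal(sync_align(elec, sync2), 50)
  expect_te_error(sync_align(elec, rep(0, 2000)), "sync_error")
  al <- align_to_optical(elec, 200)
  expect_equal(al$rate, 1000)
  expect_equal(al$t0, 0)
  expect_equal(ncol(al$samples), length(seq(401, 2000, by = 2)))
})

test_that("bad-channel heuristic", {
  set.seed(4)
  x <- matrix(rnorm(108 * 500), 108, 500)
  x[7, ] <- 0.0001 * 5 # flatline
  b <- drop_bad_channels(signal_block(x, rate = 2000))
  expect_identical(which(!b$valid), 7L)
  healthy <- drop_bad_channels(signal_block(matrix(rnorm(5000), 10), rate = 2000))
  expect_true(all(healthy$valid))
  x2 <- matrix(rnorm(10 * 100), 10, 100)
  x2[3, 50] <- NaN
  expect_false(drop_bad_channels(signal_block(x2, rate = 2000))$valid[3])
  flat <- matrix(0, 10, 100); flat[1:2, ] <- rnorm(200)
  expect_te_error(drop_bad_channels(signal_block(flat, rate = 2000)),
                  "data_quality")
})
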
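#' Optical data masks
#'
#' Boolean pixel grid selecting optical signals worth analyzing, together
#' with the parameters that produced it. After cleanup a mask is a single
#' 8-connected component and re-applying the cleanup leaves it unchanged.
#'
#' @param grid logical `rows x cols` matrix.
#' @param provenance list of the parameters used to build the mask.
#' @return a `data_mask`.
#' @export
data_mask <- function(grid, provenance = list()) {
  structure(list(grid = grid, provenance = provenance), class = "data_mask")
}

#' @export
print.data_mask <- function(x, ...) {
  cat(sprintf("data_mask: %d / %d pixels\n", sum(x$grid), length(x$grid)))
  invisible(x)
}

# neighbour offsets: 8-connectivity, and the radius-1 disk (cross) for closing
offsets8 <- cbind(dr = rep(-1:1, 3), dc = rep(-1:1, each = 3))[-5, ]
offsets_disk1 <- rbind(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1))

shift_grid <- function(grid, dr, dc, fill = FALSE) {
  R <- nrow(grid); C <- ncol(grid)
  out <- matrix(fill, R, C)
  rs <- max(1, 1 + dr):min(R, R + dr)
  cs <- max(1, 1 + dc):min(C, C + dc)
  out[rs, cs] <- grid[rs - dr, cs - dc]
  out
}

dilate_grid <- function(grid, offsets = offsets_disk1) {
  out <- matrix(FALSE, nrow(grid), ncol(grid))
  for (i in seq_len(nrow(offsets)))
    out <- out | shift_grid(grid, offsets[i, 1], offsets[i, 2])
  out
}

erode_grid <- function(grid, offsets = offsets_disk1) {
  out <- matrix(TRUE, nrow(grid), ncol(grid))
  for (i in seq_len(nrow(offsets)))
    out <- out & shift_grid(grid, offsets[i, 1], offsets[i, 2])
  out
}

# 8-connected component labels over TRUE pixels (igraph backed)
label_components <- function(grid) {
  idx <- which(grid)
  lab <- matrix(0L, nrow(grid), ncol(grid))
  if (!length(idx)) return(lab)
  R <- nrow(grid)
  r <- (idx - 1L) %% R + 1L; cc <- (idx - 1L) %/% R + 1L
  edges <- NULL
  pos <- matrix(0L, nrow(grid), ncol(grid))
  pos[idx] <- seq_along(idx)
  for (i in seq_len(nrow(offsets8))) {
    r2 <- r + offsets8[i, 1]; c2 <- cc + offsets8[i, 2]
    ok <- r2 >= 1 & r2 <= R & c2 >= 1 & c2 <= ncol(grid)
    ok[ok] <- grid[cbind(r2[ok], c2[ok])]
    if (any(ok))
      edges <- rbind(edges, cbind(pos[idx[ok]], pos[cbind(r2[ok], c2[ok])]))
  }
  if (is.null(edges)) { # isolated pixels only
    lab[idx] <- seq_along(idx)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp[seq_along(idx)]
  lab
}

mask_cleanup <- function(grid) {
  lab <- label_components(grid)
  if (max(lab) > 0) {
    biggest <- which.max(tabulate(lab[lab > 0]))
    grid <- lab == biggest
  }
  grid <- erode_grid(dilate_grid(grid)) # morphological closing, disk radius 1
  lab <- label_components(grid)
  if (max(lab) > 0) grid <- lab == which.max(tabulate(lab[lab > 0]))
  grid
}

#' Build the 20% amplitude data mask
#'
#' Per-pixel amplitude is max - min over time; pixels below
#' `threshold_fraction` of the global maximum amplitude are removed, only the
#' largest 8-connected component is retained, and the edges are smoothed by
#' morphological closing (dilation then erosion, disk radius 1 px). The
#' cleanup is idempotent.
#'
#' @param stack an `optical_stack`.
#' @param threshold_fraction amplitude threshold as a fraction of the
#'   maximum (default 0.2).
#' @return a `data_mask`.
#' @export
compute_mask <- function(stack, threshold_fraction = 0.2) {
  amp <- pixel_amplitude(stack)
  if (max(amp) <= 0)
    te_stop("empty_mask", "stack has no temporal amplitude anywhere")
  keep <- amp >= threshold_fraction * max(amp)
  if (!any(keep)) te_stop("empty_mask", "no pixel above the amplitude threshold")
  grid <- matrix(FALSE, stack$image_size[1], stack$image_size[2])
  rc <- px_rowcol(which(keep), stack$image_size)
  grid[cbind(rc[, 1] + 1L, rc[, 2] + 1L)] <- TRUE
  data_mask(mask_cleanup(grid),
            provenance = list(threshold_fraction = threshold_fraction,
                              closing_radius_px = 1L, connectivity = 8L))
}

# per-pixel max-min amplitude over time
pixel_amplitude <- function(stack) {
  x <- stack$frames
  mx <- x[, 1]; mn <- x[, 1]
  for (j in seq_len(ncol(x))[-1]) {
    mx <- pmax(mx, x[, j]); mn <- pmin(mn, x[, j])
  }
  mx - mn
}

#' Validate a data mask
#'
#' @param mask a `data_mask`.
#' @return `TRUE` invisibly; errors if the mask is not a single 8-connected
#'   component or is altered by re-applying the cleanup.
#' @export
validate_mask <- function(mask) {
  lab <- label_components(mask$grid)
  if (max(lab) != 1L) te_stop("invalid_mask", "mask is not a single connected component")
  if (!identical(mask_cleanup(mask$grid), mask$grid))
    te_stop("invalid_mask", "mask cleanup is not idempotent on this mask")
  invisible(TRUE)
}

#' Spatial averaging of optical frames
#'
#' Each frame is replaced by its mean over a square window of side
#' `round(kernel_mm / pixel_mm)` pixels (3 px for the 2.1 mm kernel at
#' 0.7 mm/px), restricted to in-mask pixels; out-of-mask pixels are left
#' untouched. A kernel smaller than one pixel is a no-op with a warning.
#'
#' @param stack an `optical_stack`.
#' @param kernel_mm averaging kernel side, mm.
#' @param mask optional `data_mask` (defaults to the stack's own mask).
#' @return the filtered `optical_stack`.
#' @export
spatial_average <- function(stack, kernel_mm = 2.1, mask = NULL) {
  if (kernel_mm <= 0) te_stop("invalid_parameter", "kernel_mm must be > 0")
  k <- round(kernel_mm / stack$pixel_mm)
  if (k <= 1) {
    te_warn("kernel_too_small", "spatial kernel below one pixel; returning input")
    return(stack)
  }
  grid <- if (is.null(mask)) stack$mask else mask$grid
  np <- prod(stack$image_size)
  inm <- as.logical(t(grid))[seq_len(np)] # row-major linear mask
  h1 <- (k - 1L) %/% 2L; h2 <- k - 1L - h1
  offs <- expand.grid(dr = -h1:h2, dc = -h1:h2)
  rc <- px_rowcol(seq_len(np), stack$image_size)
  ii <- jj <- integer(0)
  for (o in seq_len(nrow(offs))) {
    r2 <- rc[, 1] + offs$dr[o]; c2 <- rc[, 2] + offs$dc[o]
    ok <- inm & r2 >= 0 & r2 < stack$image_size[1] &
      c2 >= 0 & c2 < stack$image_size[2]
    j2 <- px_index(r2[ok], c2[ok], stack$image_size)
    ok2 <- inm[j2]
    ii <- c(ii, which(ok)[ok2]); jj <- c(jj, j2[ok2])
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(np, np))
  rs <- Matrix::rowSums(W)
  out_rows <- rs > 0
  W <- Matrix::Diagonal(x = ifelse(out_rows, 1 / pmax(rs, 1), 0)) %*% W +
    Matrix::Diagonal(x = as.numeric(!out_rows), n = np)
  out <- stack
  out$frames <- as.matrix(W %*% stack$frames)
  out
}

#' Temporal averaging
#'
#' Moving average over the smallest odd sample count whose span reaches
#' `kernel_ms` (3 samples at 1 kHz for the default 1.5 ms kernel); edges are
#' handled by window truncation. Works on `signal_block` and
#' `optical_stack`.
#'
#' @param x a `signal_block` or `optical_stack`.
#' @param kernel_ms kernel duration, ms.
#' @return same type as `x`.
#' @export
temporal_average <- function(x, kernel_ms = 1.5) {
  if (kernel_ms <= 0) te_stop("invalid_parameter", "kernel_ms must be > 0")
  rate <- x$rate
  w <- 1L
  while (w * 1000 / rate < kernel_ms) w <- w + 2L
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  X <- if (inherits(x, "optical_stack")) x$frames else x$samples
  Tn <- ncol(X)
  acc <- matrix(0, nrow(X), Tn)
  cnt <- numeric(Tn)
  for (o in -h:h) {
    src <- seq_len(Tn) + o
    ok <- src >= 1 & src <= Tn
    acc[, ok] <- acc[, ok] + X[, src[ok]]
    cnt[ok] <- cnt[ok] + 1
  }
  Y <- sweep(acc, 2, cnt, `/`)
  if (inherits(x, "optical_stack")) x$frames <- Y else x$samples <- Y
  x
}

#' Multi-lead beat averaging
#'
#' Detects pacing beats on the cross-channel RMS trace, aligns each beat to
#' the first by maximizing the cross-correlation of the RMS trace at integer
#' sample lags, and averages the first `n_beats` aligned cycles.
#'
#' @param signals a `signal_block` containing at least `n_beats` cycles.
#' @param n_beats number of beats to average.
#' @param refractory_ms minimum separation between detected beat onsets.
#' @param max_lag_samples alignment search half-width, samples.
#' @return a `signal_block` holding one averaged cycle; attribute `lags`
#'   records the per-beat alignment lags.
#' @export
beat_average <- function(signals, n_beats, refractory_ms = 150,
                         max_lag_samples = 20L) {
  X <- signals$samples[signals$valid, , drop = FALSE]
  Tn <- ncol(X)
  e <- sqrt(colMeans(X^2)) # cross-channel RMS trace
  thr <- min(e) + 0.5 * (max(e) - min(e))
  above <- which(e >= thr)
  refr <- round(refractory_ms * signals$rate / 1000)
  onsets <- above[c(TRUE, diff(above) > refr)]
  if (length(onsets) < n_beats)
    te_stop("insufficient_beats",
            sprintf("detected %d beats, need %d", length(onsets), n_beats))
  onsets <- onsets[seq_len(n_beats)]
  cycle <- if (length(onsets) >= 2) round(stats::median(diff(onsets)))
           else Tn - onsets[1] + 1L
  pre <- min(onsets[1] - 1L, round(0.15 * cycle))
  starts <- onsets - pre
  r <- sqrt(colMeans(signals$samples[signals$valid, , drop = FALSE]^2))
  seg <- function(s, lag) {
    idx <- (s + lag):(s + lag + cycle - 1L)
    idx[idx >= 1 & idx <= Tn]
  }
  ref_idx <- seg(starts[1], 0L)
  lags <- integer(n_beats)
  for (k in seq_len(n_beats)[-1]) {
    cand <- -max_lag_samples:max_lag_samples
    score <- vapply(cand, function(l) {
      idx <- starts[k] + l + seq_along(ref_idx) - 1L
      ok <- idx >= 1 & idx <= Tn # partial windows allowed at the edges
      if (mean(ok) < 0.8) return(-Inf)
      suppressWarnings(stats::cor(r[ref_idx[ok]], r[idx[ok]]))
    }, 0)
    lags[k] <- cand[which.max(score)]
  }
  acc <- matrix(0, nrow(signals$samples), cycle)
  cnt <- numeric(cycle)
  for (k in seq_len(n_beats)) {
    idx <- starts[k] + lags[k] + 0:(cycle - 1L)
    ok <- idx >= 1 & idx <= Tn
    acc[, ok] <- acc[, ok] + signals$samples[, idx[ok], drop = FALSE]
    cnt[ok] <- cnt[ok] + 1
  }
  out <- signal_block(sweep(acc, 2, pmax(cnt, 1), `/`), rate = signals$rate,
                      t0 = signals$t0 + (starts[1] - 1) * 1000 / signals$rate,
                      channel_ids = signals$channel_ids, valid = signals$valid)
  attr(out, "lags") <- lags
  attr(out, "onsets") <- onsets
  out
}

#' Optical/electrical temporal alignment
#'
#' Finds the first rising edge of the camera-sync square wave (threshold at
#' half amplitude) and returns the electrical time, in ms, of optical frame
#' zero.
#'
#' @param electrical `signal_block` on the electrical timebase.
#' @param sync numeric square wave sampled at `electrical$rate`.
#' @return offset in ms.
#' @export
sync_align <- function(electrical, sync) {
  if (is.null(sync) || diff(range(sync)) == 0)
    te_stop("sync_error", "sync wave contains no edge")
  thr <- (max(sync) + min(sync)) / 2
  hi <- sync >= thr
  rising <- which(!hi[-length(hi)] & hi[-1]) + 1L
  if (!length(rising)) {
    if (hi[1]) rising <- 1L else te_stop("sync_error", "no rising edge found")
  }
  electrical$t0 + (rising[1] - 1L) * 1000 / electrical$rate
}

#' Re-base electrical data onto the optical clock
#'
#' Shifts `t0` so the sync offset becomes time zero and, for 2 kHz data,
#' decimates 2:1 onto the 1 kHz optical timebase.
#'
#' @param electrical `signal_block`.
#' @param offset_ms value from [sync_align()].
#' @param optical_rate target rate, Hz.
#' @return a `signal_block` on the optical timebase.
#' @export
align_to_optical <- function(electrical, offset_ms, optical_rate = 1000) {
  tt <- sb_times(electrical)
  start <- which.min(abs(tt - offset_ms))
  step <- max(1L, round(electrical$rate / optical_rate))
  idx <- seq(start, ncol(electrical$samples), by = step)
  signal_block(electrical$samples[, idx, drop = FALSE], rate = electrical$rate / step,
               t0 = tt[start] - offset_ms, channel_ids = electrical$channel_ids,
               valid = electrical$valid)
}

#' Automatic bad-channel detection
#'
#' Flags channels whose temporal standard deviation is below 1% of the
#' median channel SD (flatline / lead fracture) or that contain non-finite
#' samples. Errors if more than half the channels would be discarded.
#'
#' @param signals a `signal_block`.
#' @return the block with `valid` updated.
#' @export
drop_bad_channels <- function(signals) {
  sds <- apply(signals$samples, 1, stats::sd)
  nonfinite <- apply(signals$samples, 1, function(x) any(!is.finite(x)))
  live <- is.finite(sds) & sds > 0
  med <- if (any(live)) stats::median(sds[live]) else 0
  bad <- nonfinite | !is.finite(sds) | sds < 0.01 * med | med == 0
  if (sum(bad) > 0.5 * length(bad))
    te_stop("data_quality", "more than 50% of channels flagged bad")
  signals$valid <- signals$valid & !bad
  signals
}
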
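#' Multichannel signal blocks
#'
#' Container for electrograms or per-node transmembrane potentials: a
#' `channels x time` sample matrix with sampling rate (Hz), start offset `t0`
#' (ms), channel identifiers and per-channel validity.
#'
#' @param samples numeric `channels x time` matrix.
#' @param rate sampling rate in Hz (1000 for optical-timebase data, 2000 for
#'   electrical recordings by default).
#' @param t0 time of the first sample, ms.
#' @param channel_ids character vector of channel identifiers.
#' @param valid per-channel logical.
#' @return a `signal_block`.
#' @export
signal_block <- function(samples, rate, t0 = 0,
                         channel_ids = sprintf("ch%03d", seq_len(nrow(samples))),
                         valid = rep(TRUE, nrow(samples))) {
  samples <- as.matrix(samples)
  if (!is_scalar_num(rate) || rate <= 0) te_stop("invalid_parameter", "rate must be > 0")
  if (length(channel_ids) != nrow(samples) || length(valid) != nrow(samples))
    te_stop("invalid_parameter", "channel metadata length mismatch")
  structure(list(samples = samples, rate = rate, t0 = t0,
                 channel_ids = as.character(channel_ids), valid = as.logical(valid)),
            class = "signal_block")
}

#' @export
print.signal_block <- function(x, ...) {
  cat(sprintf("signal_block: %d channels x %d samples @ %g Hz (t0 = %g ms, %d valid)\n",
              nrow(x$samples), ncol(x$samples), x$rate, x$t0, sum(x$valid)))
  invisible(x)
}

# time axis in ms
sb_times <- function(block) block$t0 + (seq_len(ncol(block$samples)) - 1) * 1000 / block$rate

#' Optical fluorescence stacks
#'
#' A voltage-dye movie: `100 x 100 x T` normalized fluorescence frames at
#' 1 kHz with 0.7 mm pixels, a boolean data mask, and the camera-sync square
#' wave sampled on the electrical timebase. Frames are stored as a
#' `(rows*cols) x T` matrix in row-major pixel order (0-based row/col, origin
#' top-left).
#'
#' @param frames `(rows*cols) x T` matrix.
#' @param rate frame rate Hz (default 1000).
#' @param pixel_mm pixel pitch in mm (default 0.7).
#' @param mask logical `rows x cols` matrix.
#' @param sync optional numeric square wave (electrical timebase).
#' @param sync_rate sampling rate of `sync` in Hz.
#' @param image_size `c(rows, cols)`, default `c(100, 100)`.
#' @param t0 time of frame 0, ms.
#' @return an `optical_stack`.
#' @export
optical_stack <- function(frames, rate = 1000, pixel_mm = 0.7,
                          mask = NULL, sync = NULL, sync_rate = 2000,
                          image_size = c(100L, 100L), t0 = 0) {
  frames <- as.matrix(frames)
  if (nrow(frames) != prod(image_size))
    te_stop("invalid_parameter", "frames must have rows*cols pixel rows")
  if (pixel_mm <= 0) te_stop("invalid_parameter", "pixel_mm must be > 0")
  if (is.null(mask)) mask <- matrix(TRUE, image_size[1], image_size[2])
  structure(list(frames = frames, rate = rate, pixel_mm = pixel_mm,
                 mask = mask, sync = sync, sync_rate = sync_rate,
                 image_size = as.integer(image_size), t0 = t0),
            class = "optical_stack")
}

#' @export
print.optical_stack <- function(x, ...) {
  cat(sprintf("optical_stack: %dx%d px x %d frames @ %g Hz, %.2g mm/px, %d in mask\n",
              x$image_size[1], x$image_size[2], ncol(x$frames), x$rate,
              x$pixel_mm, sum(x$mask)))
  invisible(x)
}

# linear pixel index (row-major, 0-based row/col) <-> (row, col)
px_index <- function(row, col, image_size) row * image_size[2] + col + 1L
px_rowcol <- function(idx, image_size) {
  cbind(row = (idx - 1L) %/% image_size[2], col = (idx - 1L) %% image_size[2])
}

#' Activation / repolarization time maps
#'
#' Per-node or per-pixel scalar times in ms with validity flags and a domain
#' tag identifying what the entries index.
#'
#' @param times numeric vector (ms).
#' @param valid logical vector.
#' @param domain_tag one of `mesh_nodes`, `sock_electrodes`, `optical_pixels`,
#'   `ecgi_nodes`.
#' @return a `time_map`.
#' @export
time_map <- function(times, valid = is.finite(times),
                     domain_tag = c("mesh_nodes", "sock_electrodes",
                                    "optical_pixels", "ecgi_nodes")) {
  domain_tag <- match.arg(domain_tag)
  valid <- as.logical(valid) & is.finite(times)
  structure(list(times = as.numeric(times), valid = valid, domain_tag = domain_tag),
            class = "time_map")
}

#' @export
print.time_map <- function(x, ...) {
  v <- x$times[x$valid]
  cat(sprintf("time_map [%s]: %d entries (%d valid), range %.1f..%.1f ms\n",
              x$domain_tag, length(x$times), sum(x$valid),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Scenario configuration for synthetic sequences
#'
#' Bundles a pacing protocol (2 ms pulses at 2 Hz by default, i.e. a 500 ms
#' cycle), baseline conduction velocity and action-potential duration, the
#' perfusion-bed perturbation (the LAD cold/Sotalol analogue: slower
#' conduction and/or longer APD in a contiguous vertex region), the optical
#' noise level and the random seed.
#'
#' @param pacing_site vertex index of the pacing stimulus.
#' @param pacing_cycle_ms pacing cycle length, ms.
#' @param cv_base conduction velocity, mm/ms (1 mm/ms is typical working-
#'   myocardium epicardial conduction).
#' @param apd_base baseline action-potential duration, ms.
#' @param perfusion_region integer vertex indices of the perturbed bed.
#' @param cv_factor_region multiplicative conduction-velocity factor inside
#'   the region (< 1 slows conduction).
#' @param apd_delta_region additive APD change inside the region, ms.
#' @param noise_snr_db additive-noise SNR for rendered/recorded signals, dB.
#' @param seed integer seed for all stochastic steps of the scenario.
#' @return a `scenario_config`.
#' @export
scenario_config <- function(pacing_site, pacing_cycle_ms = 500, cv_base = 1,
                            apd_base = 200, perfusion_region = integer(),
                            cv_factor_region = 1, apd_delta_region = 0,
                            noise_snr_db = 20, seed = 1L) {
  if (cv_base <= 0) te_stop("invalid_parameter", "cv_base must be > 0")
  if (apd_base <= 0) te_stop("invalid_parameter", "apd_base must be > 0")
  if (pacing_cycle_ms <= apd_base)
    te_stop("invalid_parameter", "pacing cycle must exceed apd_base")
  structure(list(pacing_site = as.integer(pacing_site),
                 pacing_cycle_ms = pacing_cycle_ms, cv_base = cv_base,
                 apd_base = apd_base,
                 perfusion_region = as.integer(perfusion_region),
                 cv_factor_region = cv_factor_region,
                 apd_delta_region = apd_delta_region,
                 noise_snr_db = noise_snr_db, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Select a contiguous perfusion-bed region
#'
#' Returns all vertices within a geodesic radius of a seed vertex — the
#' synthetic analogue of the separately perfused LAD bed.
#'
#' @param mesh heart `trimesh`.
#' @param center_vertex vertex index at the bed centre.
#' @param radius_mm geodesic radius, mm.
#' @return integer vertex indices.
#' @export
perfusion_bed <- function(mesh, center_vertex, radius_mm) {
  g <- mesh_graph(mesh)
  d <- as.numeric(igraph::distances(g, v = center_vertex))
  which(d <= radius_mm)
}
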
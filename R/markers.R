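# Activation / repolarization marker detection.
#
# Marker conventions: electrogram AT = time of minimum dV/dt of the
# intrinsic deflection; optical AT = maximum dF/dt of the upstroke;
# electrogram RT = maximum dV/dt of the T wave; optical RT = minimum dF/dt
# during repolarization. Derivatives are first central differences at the
# native rate; ties break to the earliest sample.

# central-difference derivative; NA at both ends
central_diff <- function(x, rate) {
  n <- length(x)
  d <- rep(NA_real_, n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2000 # per ms
  d
}

window_idx <- function(times, window) {
  if (is.null(window)) seq_along(times)
  else which(times >= window[1] & times < window[2])
}

marker_extremum <- function(trace, rate, t0, window, mode, noise_floor) {
  tt <- t0 + (seq_along(trace) - 1) * 1000 / rate
  idx <- window_idx(tt, window)
  idx <- idx[idx > 1 & idx < length(trace)]
  if (!length(idx)) return(NA_real_)
  if (diff(range(trace[idx])) <= noise_floor) return(NA_real_)
  d <- central_diff(trace, rate)[idx]
  k <- if (mode == "min") which.min(d) else which.max(d)
  structure(tt[idx[k]], extremum = d[k], d_range = range(d))
}

#' Electrogram activation time
#'
#' Argmin of the first central difference within the QRS window; ties break
#' to the earliest sample. Traces whose in-window range does not exceed
#' `noise_floor` are marked invalid (`NA`).
#'
#' @param trace numeric electrogram samples.
#' @param rate sampling rate, Hz.
#' @param t0 time of the first sample, ms.
#' @param qrs_window `c(start, end)` ms, half-open; `NULL` = whole trace.
#' @param noise_floor amplitude below which the trace counts as flat.
#' @return time in ms, or `NA` when invalid.
#' @export
at_from_egm <- function(trace, rate, t0 = 0, qrs_window = NULL,
                        noise_floor = 1e-6) {
  as.numeric(marker_extremum(trace, rate, t0, qrs_window, "min", noise_floor))
}

#' Optical activation time
#'
#' Argmax of dF/dt during the upstroke. An inverted trace (depolarization
#' seen as a downstroke, |min dF/dt| exceeding max dF/dt) fails the polarity
#' check and is invalid.
#'
#' @inheritParams at_from_egm
#' @param window `c(start, end)` ms.
#' @export
at_from_optical <- function(trace, rate, t0 = 0, window = NULL,
                            noise_floor = 1e-6) {
  m <- marker_extremum(trace, rate, t0, window, "max", noise_floor)
  if (length(m) == 1 && is.na(m)) return(NA_real_)
  dr <- attr(m, "d_range")
  if (-dr[1] > dr[2]) return(NA_real_) # polarity check
  as.numeric(m)
}

#' Electrogram repolarization time
#'
#' Argmax of dV/dt within the T-wave window, by default
#' `[at + rt_window[1], at + rt_window[2])` ms.
#'
#' @inheritParams at_from_egm
#' @param at activation time of this trace, ms.
#' @param rt_window offsets from `at` bounding the T-wave search, ms.
#' @export
rt_from_egm <- function(trace, rate, t0 = 0, at, rt_window = c(50, 450),
                        noise_floor = 1e-6) {
  if (is.na(at)) return(NA_real_)
  as.numeric(marker_extremum(trace, rate, t0, at + rt_window, "max", noise_floor))
}

#' Optical repolarization time
#'
#' Argmin of dF/dt within the repolarization window; a trace with no
#' negative slope in the window (no repolarization) is invalid.
#'
#' @inheritParams rt_from_egm
#' @export
rt_from_optical <- function(trace, rate, t0 = 0, at, rt_window = c(50, 450),
                            noise_floor = 1e-6) {
  if (is.na(at)) return(NA_real_)
  m <- marker_extremum(trace, rate, t0, at + rt_window, "min", noise_floor)
  if (length(m) == 1 && is.na(m)) return(NA_real_)
  if (attr(m, "extremum") >= 0) return(NA_real_)
  as.numeric(m)
}

#' Marker sets
#'
#' AT and RT maps detected from one modality, with the search windows used.
#' `rt > at` wherever both are valid.
#'
#' @param at,rt `time_map`s.
#' @param method_tag one of `egm_dvdt`, `optical_dfdt`, `ecgi_gaf`.
#' @param windows list of the QRS/T-wave windows used.
#' @return a `marker_set`.
#' @export
marker_set <- function(at, rt, method_tag = c("egm_dvdt", "optical_dfdt", "ecgi_gaf"),
                       windows = list()) {
  method_tag <- match.arg(method_tag)
  both <- at$valid & rt$valid
  if (any(rt$times[both] <= at$times[both]))
    te_stop("invalid_marker", "rt must exceed at where both valid")
  structure(list(at = at, rt = rt, method_tag = method_tag, windows = windows),
            class = "marker_set")
}

#' Detect AT/RT markers on every channel of a signal block
#'
#' @param block `signal_block` of electrograms (or optical traces with
#'   `optical = TRUE`).
#' @param qrs_window AT search window (ms), `NULL` = whole trace.
#' @param rt_window T-wave window offsets from AT, ms.
#' @param optical use the optical marker rules instead of the electrogram ones.
#' @param domain_tag domain tag for the produced maps.
#' @return a `marker_set`.
#' @export
detect_markers <- function(block, qrs_window = NULL, rt_window = c(50, 450),
                           optical = FALSE, domain_tag = "sock_electrodes") {
  n <- nrow(block$samples)
  at <- rt <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!block$valid[i]) next
    tr <- block$samples[i, ]
    if (optical) {
      at[i] <- at_from_optical(tr, block$rate, block$t0, qrs_window)
      rt[i] <- rt_from_optical(tr, block$rate, block$t0, at[i], rt_window)
    } else {
      at[i] <- at_from_egm(tr, block$rate, block$t0, qrs_window)
      rt[i] <- rt_from_egm(tr, block$rate, block$t0, at[i], rt_window)
    }
  }
  marker_set(time_map(at, domain_tag = domain_tag),
             time_map(rt, domain_tag = domain_tag),
             method_tag = if (optical) "optical_dfdt" else "egm_dvdt",
             windows = list(qrs = qrs_window, rt = rt_window))
}

#' Per-pixel optical markers
#'
#' Applies the optical marker rules to every in-mask pixel of a stack.
#'
#' @param stack an `optical_stack`.
#' @param mask a `data_mask`.
#' @inheritParams detect_markers
#' @return a `marker_set` on `optical_pixels` (row-major linear order).
#' @export
optical_markers <- function(stack, mask, qrs_window = NULL,
                            rt_window = c(50, 450)) {
  np <- prod(stack$image_size)
  inm <- as.logical(t(mask$grid))[seq_len(np)]
  at <- rt <- rep(NA_real_, np)
  for (i in which(inm)) {
    tr <- stack$frames[i, ]
    at[i] <- at_from_optical(tr, stack$rate, stack$t0, qrs_window)
    rt[i] <- rt_from_optical(tr, stack$rate, stack$t0, at[i], rt_window)
  }
  marker_set(time_map(at, domain_tag = "optical_pixels"),
             time_map(rt, domain_tag = "optical_pixels"),
             method_tag = "optical_dfdt",
             windows = list(qrs = qrs_window, rt = rt_window))
}

#' Global activation field for ECGI electrograms
#'
#' Rather than marking each reconstructed electrogram independently, node
#' activation times are fitted to pairwise inter-electrogram delays. For
#' every mesh edge the delay is the lag (within `max_lag_ms`) maximizing the
#' cross-correlation of the two derivative traces; edges whose correlation
#' peak is below `cc_min` are dropped. Node times solve the weighted least
#' squares problem `min sum w_ij (t_j - t_i - delta_ij)^2 + mu ||L t||^2`
#' (`w` = correlation peak, `L` = unweighted graph Laplacian), and the
#' additive gauge is fixed by matching the mean of `t` to the mean of the
#' per-node min-dV/dt estimates. This spatially smooths the activation map.
#'
#' Note that reconstructed electrograms have limited spatial resolution, so
#' delays between immediate mesh neighbours may be unresolvable; passing a
#' geodesic-radius adjacency (see [radius_adjacency()]) lets the fit use the
#' longer-range delays that ECGI can actually measure.
#'
#' @param egms `signal_block` of reconstructed electrograms on heart nodes.
#' @param adjacency a heart `trimesh` (its edges are used) or a two-column
#'   matrix of node-index pairs.
#' @param max_lag_ms delay search half-width, ms.
#' @param cc_min minimum correlation peak to keep an edge.
#' @param mu Laplacian smoothing weight.
#' @param qrs_window window for the gauge anchor estimates, ms.
#' @return `time_map` on `ecgi_nodes`.
#' @export
global_activation_field <- function(egms, adjacency, max_lag_ms = 30, cc_min = 0.5,
                                    mu = 1e-2, qrs_window = NULL) {
  valid <- which(egms$valid)
  nv <- length(valid)
  raw <- vapply(seq_len(nrow(egms$samples)), function(i)
    if (egms$valid[i]) at_from_egm(egms$samples[i, ], egms$rate, egms$t0,
                                   qrs_window) else NA_real_, 0)
  if (nv == 1L)
    return(time_map(raw, valid = egms$valid, domain_tag = "ecgi_nodes"))
  e <- if (inherits(adjacency, "trimesh")) mesh_edges(adjacency)
       else matrix(as.integer(adjacency), ncol = 2)
  e <- e[e[, 1] %in% valid & e[, 2] %in% valid, , drop = FALSE]
  remap <- match(seq_len(nrow(egms$samples)), valid)
  ei <- remap[e[, 1]]; ej <- remap[e[, 2]]
  Tn <- ncol(egms$samples)
  D <- (egms$samples[valid, 3:Tn, drop = FALSE] -
        egms$samples[valid, 1:(Tn - 2), drop = FALSE])
  D <- D - rowMeans(D)
  D <- D / pmax(sqrt(rowMeans(D^2)), .Machine$double.eps)
  L <- round(max_lag_ms * egms$rate / 1000)
  m <- length(ei)
  best_cc <- rep(-Inf, m); best_lag <- integer(m)
  Td <- ncol(D)
  for (l in -L:L) {
    a <- max(1, 1 - l); b <- min(Td, Td - l)
    cc <- rowSums(D[ei, a:b, drop = FALSE] * D[ej, (a + l):(b + l), drop = FALSE]) /
      (b - a + 1)
    upd <- cc > best_cc
    best_cc[upd] <- cc[upd]; best_lag[upd] <- l
  }
  keep <- best_cc >= cc_min
  if (!any(keep)) te_stop("component_error", "all delay edges dropped")
  t <- gaf_fit(cbind(ei, ej)[keep, , drop = FALSE],
               best_lag[keep] * 1000 / egms$rate, best_cc[keep], nv, mu,
               anchor = mean(raw[valid], na.rm = TRUE))
  out <- rep(NA_real_, nrow(egms$samples))
  out[valid] <- t
  time_map(out, domain_tag = "ecgi_nodes")
}

# weighted least-squares fit of node times to edge delays with Laplacian
# smoothing; gauge fixed by pinning then re-anchoring the mean
gaf_fit <- function(edges, delta, w, n, mu = 1e-2, anchor = 0) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  if (igraph::components(g)$no != 1L)
    te_stop("component_error", "delay graph is disconnected after edge dropping")
  ei <- edges[, 1]; ej <- edges[, 2]
  mE <- length(ei)
  B <- Matrix::sparseMatrix(i = rep(seq_len(mE), 2), j = c(ei, ej),
                            x = c(rep(-1, mE), rep(1, mE)), dims = c(mE, n))
  Lap <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei), x = -1,
                              dims = c(n, n))
  Lap <- Lap + Matrix::Diagonal(x = -Matrix::rowSums(Lap))
  M <- Matrix::crossprod(B * sqrt(w)) + mu * Matrix::crossprod(Lap)
  rhs <- as.numeric(Matrix::crossprod(B, w * delta))
  t <- c(0, as.numeric(Matrix::solve(M[-1, -1, drop = FALSE], rhs[-1])))
  t - mean(t) + anchor
}


#' Geodesic-radius adjacency for the global activation field
#'
#' All node pairs closer than `radius_mm` along the mesh surface.
#'
#' @param mesh heart `trimesh`.
#' @param radius_mm geodesic radius, mm.
#' @return two-column matrix of node pairs.
#' @export
radius_adjacency <- function(mesh, radius_mm) {
  D <- igraph::distances(mesh_graph(mesh))
  which(D <= radius_mm & upper.tri(D), arr.ind = TRUE)
}
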
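#' Simulate an activation sequence on the heart mesh
#'
#' Ground-truth activation times are graph geodesics: the activation time of
#' a vertex is the shortest-path travel time from the pacing site through the
#' mesh edge graph, each edge costing `length / cv`. Edges with both endpoints
#' in the perfusion region use `cv_base * cv_factor_region` (the cold-LAD
#' analogue of slowed conduction). This overestimates true surface geodesics
#' by up to ~8% (documented limitation of edge-graph wavefronts).
#'
#' @param heart heart `trimesh`.
#' @param scenario a `scenario_config`.
#' @return a `time_map` on `mesh_nodes`, `AT(pacing_site) = 0`.
#' @export
simulate_activation <- function(heart, scenario) {
  nv <- nrow(heart$vertices)
  if (scenario$pacing_site < 1L || scenario$pacing_site > nv)
    te_stop("invalid_parameter", "pacing_site is not a mesh vertex")
  e <- mesh_edges(heart)
  len <- row_norms(heart$vertices[e[, 1], , drop = FALSE] -
                   heart$vertices[e[, 2], , drop = FALSE])
  in_region <- e[, 1] %in% scenario$perfusion_region &
               e[, 2] %in% scenario$perfusion_region
  cv <- ifelse(in_region, scenario$cv_base * scenario$cv_factor_region,
               scenario$cv_base)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  at <- as.numeric(igraph::distances(g, v = scenario$pacing_site,
                                     weights = len / cv))
  if (any(!is.finite(at)))
    te_stop("unreachable_vertex", "mesh is disconnected: unreachable vertices")
  time_map(at, domain_tag = "mesh_nodes")
}

#' Per-node APD field for a scenario
#'
#' Baseline APD plus the additive regional perturbation (Sotalol/temperature
#' analogue).
#'
#' @inheritParams simulate_activation
#' @return numeric APD per vertex, ms.
#' @export
apd_field <- function(heart, scenario) {
  apd <- rep(scenario$apd_base, nrow(heart$vertices))
  apd[scenario$perfusion_region] <- apd[scenario$perfusion_region] +
    scenario$apd_delta_region
  apd
}

#' Synthesize transmembrane action potentials
#'
#' Template action-potential trains on mesh nodes: a fast sigmoid upstroke
#' (time constant `tau_up`, ~1 ms rise) centred at AT, a plateau, and a
#' slower sigmoid repolarization centred at AT + APD. By construction the
#' maximum dVm/dt sits at AT (within one sample) and the minimum dVm/dt at
#' AT + APD (within two samples); amplitudes are normalized to [0, 1].
#'
#' @param at `time_map` of activation times on mesh nodes (ms).
#' @param apd numeric per-node APD (ms).
#' @param rate sampling rate, Hz (>= 500).
#' @param n_beats number of pacing cycles to synthesize.
#' @param cycle_ms pacing cycle length, ms.
#' @param tau_up,tau_rep upstroke / repolarization time constants, ms.
#' @return a `signal_block` (one channel per node).
#' @export
synthesize_vm <- function(at, apd, rate = 1000, n_beats = 1, cycle_ms = 500,
                          tau_up = 0.6, tau_rep = 6) {
  if (rate < 500) te_stop("invalid_parameter", "rate must be >= 500 Hz")
  if (any(apd <= 0)) te_stop("invalid_parameter", "apd must be positive")
  if (max(at$times + apd) + 8 * tau_rep >= cycle_ms)
    te_stop("overlap_error", "AT + APD reaches into the next cycle")
  tt <- seq(0, n_beats * cycle_ms - 1000 / rate, by = 1000 / rate)
  n <- length(at$times)
  vm <- matrix(0, n, length(tt))
  for (b in seq_len(n_beats) - 1L) {
    t_on <- outer(at$times + b * cycle_ms, tt, function(a, t) t - a)
    t_off <- sweep(t_on, 1, apd, `-`)
    vm <- vm + stats::plogis(t_on / tau_up) * stats::plogis(-t_off / tau_rep)
  }
  signal_block(vm, rate = rate,
               channel_ids = sprintf("node%04d", seq_len(n)),
               valid = at$valid)
}

#' Synthesize unipolar electrograms at sock electrodes
#'
#' Far-field-minus-local construction: the electrogram at electrode `e` is
#' `k * (sum_j u_j Vm_j(t) - Vloc(e, t))` where the far-field weights
#' `u_j` are inverse-square-distance over nodes farther than `rho` from the
#' electrode (normalized to sum 1) and `Vloc` is the mean Vm over nodes
#' within `rho`. The local term guarantees the paper-standard marker
#' semantics: the steepest local depolarization appears as the minimum
#' d(phi)/dt (intrinsic deflection) and the steepest local repolarization as
#' the maximum d(phi)/dt (T-wave upslope).
#'
#' @param vm `signal_block` of transmembrane potentials on heart nodes.
#' @param heart heart `trimesh`.
#' @param electrodes `electrode_set` on the heart.
#' @param rho local-neighbourhood radius, mm.
#' @param k positive output gain.
#' @return a `signal_block`, one channel per electrode.
#' @export
synthesize_unipolar_egm <- function(vm, heart, electrodes, rho = 3, k = 1) {
  if (nrow(vm$samples) != nrow(heart$vertices))
    te_stop("invalid_parameter", "vm must be defined on heart vertices")
  ne <- length(electrodes$labels)
  d <- sqrt(pmax(outer(rowSums(electrodes$positions^2), rep(1, nrow(heart$vertices))) +
                 outer(rep(1, ne), rowSums(heart$vertices^2)) -
                 2 * electrodes$positions %*% t(heart$vertices), 0))
  W <- matrix(0, ne, nrow(heart$vertices))
  for (i in seq_len(ne)) {
    loc <- d[i, ] <= rho
    if (!any(loc)) te_stop("configuration_error",
                           sprintf("electrode %s has no nodes within rho", electrodes$labels[i]))
    far <- !loc
    u <- numeric(ncol(W))
    if (any(far)) {
      u[far] <- 1 / d[i, far]^2
      u[far] <- u[far] / sum(u[far])
    }
    u[loc] <- u[loc] - 1 / sum(loc)
    W[i, ] <- u
  }
  signal_block(k * (W %*% vm$samples), rate = vm$rate, t0 = vm$t0,
               channel_ids = electrodes$labels, valid = electrodes$valid)
}

# ---- spherical harmonics (analytic volume-conductor oracle) ----

# Associated Legendre P_l^m(x) without Condon-Shortley phase, for all l<=lmax
# at fixed m; returns matrix length(x) x (lmax-m+1).
assoc_legendre <- function(x, lmax, m) {
  pmm <- rep(1, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, (1 - x) * (1 + x)))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- pmm * fact * somx2
      fact <- fact + 2
    }
  }
  out <- matrix(0, length(x), lmax - m + 1L)
  out[, 1] <- pmm
  if (lmax > m) {
    pmmp1 <- x * (2 * m + 1) * pmm
    out[, 2] <- pmmp1
    if (lmax > m + 1) for (l in (m + 2):lmax) {
      pll <- (x * (2 * l - 1) * pmmp1 - (l + m - 1) * pmm) / (l - m)
      pmm <- pmmp1; pmmp1 <- pll
      out[, l - m + 1L] <- pll
    }
  }
  out
}

#' Real spherical-harmonic basis
#'
#' Evaluates the real orthonormal spherical harmonics up to degree `lmax` at
#' unit directions; columns ordered `(l, m)` with `m = -l..l`.
#'
#' @param dirs `n x 3` matrix of (not necessarily unit) directions.
#' @param lmax maximum degree.
#' @return list with `basis` (`n x (lmax+1)^2`) and data.frame `lm` of degree
#'   and order per column.
#' @export
sph_basis <- function(dirs, lmax) {
  dirs <- normalize_rows(as.matrix(dirs))
  ct <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  ncol_tot <- (lmax + 1L)^2
  B <- matrix(0, nrow(dirs), ncol_tot)
  ls <- integer(ncol_tot); ms <- integer(ncol_tot)
  col <- 0L
  plm <- lapply(0:lmax, function(m) assoc_legendre(ct, lmax, m))
  for (l in 0:lmax) for (m in (-l):l) {
    col <- col + 1L
    am <- abs(m)
    nrm <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
    p <- plm[[am + 1L]][, l - am + 1L]
    B[, col] <- if (m == 0) nrm * p
                else if (m > 0) sqrt(2) * nrm * p * cos(m * phi)
                else sqrt(2) * nrm * p * sin(am * phi)
    ls[col] <- l; ms[col] <- m
  }
  list(basis = B, lm = data.frame(l = ls, m = ms))
}

#' Analytic concentric-spheres forward transfer
#'
#' For the source-free shell between an inner sphere of radius `a` (Dirichlet
#' data) and an outer sphere of radius `R` (zero normal current — the tank
#' wall), a degree-`l` harmonic component is carried to radius `r` by
#' `T_l(r) = (r^l + l/(l+1) R^(2l+1) r^-(l+1)) / (a^l + l/(l+1) R^(2l+1) a^-(l+1))`.
#'
#' @param coeffs data.frame with columns `l`, `m`, `c` — inner-surface
#'   spherical-harmonic coefficients.
#' @param a inner (heart) radius, mm.
#' @param R outer (tank) radius, mm.
#' @param eval_radius evaluation radius `r`, `a < r <= R`.
#' @return `coeffs` with `c` multiplied per degree by `T_l(eval_radius)`.
#' @export
forward_spheres_analytic <- function(coeffs, a, R, eval_radius) {
  if (!(a > 0 && a < R)) te_stop("domain_error", "need 0 < a < R")
  if (!(eval_radius > a && eval_radius <= R))
    te_stop("domain_error", "eval_radius must lie in (a, R]")
  coeffs$c <- coeffs$c * sphere_transfer(coeffs$l, a, R, eval_radius)
  coeffs
}

#' @rdname forward_spheres_analytic
#' @param l degree (vectorized).
#' @export
sphere_transfer <- function(l, a, R, eval_radius) {
  r <- eval_radius
  num <- r^l + (l / (l + 1)) * R^(2 * l + 1) * r^(-(l + 1))
  den <- a^l + (l / (l + 1)) * R^(2 * l + 1) * a^(-(l + 1))
  num / den
}

#' Evaluate a spherical-harmonic field at points
#'
#' @param coeffs data.frame `l`, `m`, `c`.
#' @param points `n x 3` positions.
#' @param center sphere centre.
#' @return numeric vector of field values.
#' @export
eval_sph_field <- function(coeffs, points, center = c(0, 0, 0)) {
  dirs <- sweep(as.matrix(points), 2, center, `-`)
  sb <- sph_basis(dirs, max(coeffs$l))
  idx <- match(paste(coeffs$l, coeffs$m), paste(sb$lm$l, sb$lm$m))
  as.numeric(sb$basis[, idx, drop = FALSE] %*% coeffs$c)
}

# ---- MFS forward solver ----

# Free-space kernel matrices between collocation/evaluation points and sources.
mfs_dirichlet_rows <- function(points, sources) {
  d <- sqrt(pmax(outer(rowSums(points^2), rep(1, nrow(sources))) +
                 outer(rep(1, nrow(points)), rowSums(sources^2)) -
                 2 * points %*% t(sources), 0))
  if (any(d < 1e-9)) te_stop("singular_kernel", "a point coincides with an MFS source")
  cbind(1, 1 / (4 * pi * d))
}

mfs_neumann_rows <- function(points, normals, sources) {
  n <- nrow(points); m <- nrow(sources)
  dx <- outer(points[, 1], sources[, 1], `-`)
  dy <- outer(points[, 2], sources[, 2], `-`)
  dz <- outer(points[, 3], sources[, 3], `-`)
  d3 <- (dx^2 + dy^2 + dz^2)^1.5
  if (any(d3 < 1e-18)) te_stop("singular_kernel", "a point coincides with an MFS source")
  cbind(0, -(dx * normals[, 1] + dy * normals[, 2] + dz * normals[, 3]) /
             (4 * pi * d3))
}

# Truncated-SVD pseudoinverse solve, rcond relative to sigma_max.
pinv_solve <- function(A, B, rcond = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > rcond * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% B) / sv$d[keep])
}

#' Forward torso-tank problem by MFS collocation
#'
#' Solves the interior Laplace boundary-value problem (Dirichlet potentials
#' on the heart surface, zero normal current on the tank wall) by
#' least-squares collocation on fictitious sources — heart vertices deflated
#' by `factors[1]` about the heart centroid plus tank vertices inflated by
#' `factors[2]` about the tank centroid — then evaluates the potential at the
#' tank electrodes. The default factors (0.7, 1.3) and source density differ
#' deliberately from the inverse module's (0.8, 1.2) so that inverse tests do
#' not commit the inverse crime.
#'
#' @param heart_potentials `signal_block` on heart vertices (mV).
#' @param heart,tank `trimesh` surfaces, heart strictly inside tank.
#' @param tank_electrodes `electrode_set` on the tank.
#' @param factors `c(deflate, inflate)` source-surface scalings.
#' @param tol relative collocation-residual warning threshold (error at 10x).
#' @return `signal_block` of tank-electrode potentials.
#' @export
forward_mfs <- function(heart_potentials, heart, tank, tank_electrodes,
                        factors = c(0.7, 1.3), tol = 0.05) {
  op <- mfs_forward_operator(heart, tank, tank_electrodes, factors)
  forward_apply(op, heart_potentials, tol = tol)
}

#' @rdname forward_mfs
#' @export
mfs_forward_operator <- function(heart, tank, tank_electrodes,
                                 factors = c(0.7, 1.3)) {
  if (!(factors[1] < 1 && factors[2] > 1))
    te_stop("invalid_parameter", "factors must be (deflate < 1, inflate > 1)")
  hc <- colMeans(heart$vertices); tc <- colMeans(tank$vertices)
  src <- rbind(sweep(sweep(heart$vertices, 2, hc, `-`) * factors[1], 2, hc, `+`),
               sweep(sweep(tank$vertices, 2, tc, `-`) * factors[2], 2, tc, `+`))
  A <- rbind(mfs_dirichlet_rows(heart$vertices, src),
             mfs_neumann_rows(tank$vertices, tank$vertex_normals, src))
  sv <- svd(A)
  keep <- sv$d > 1e-12 * sv$d[1]
  P <- sv$v[, keep, drop = FALSE] %*% (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  list(A = A, P = P, E = mfs_dirichlet_rows(tank_electrodes$positions, src),
       n_heart = nrow(heart$vertices), electrodes = tank_electrodes)
}

#' @rdname forward_mfs
#' @param op a precomputed [mfs_forward_operator()].
#' @export
forward_apply <- function(op, heart_potentials, tol = 0.05) {
  B <- rbind(heart_potentials$samples,
             matrix(0, nrow(op$A) - op$n_heart, ncol(heart_potentials$samples)))
  X <- op$P %*% B
  res <- op$A %*% X - B
  bn <- sqrt(colSums(B^2)); rn <- sqrt(colSums(res^2))
  rel <- ifelse(bn > 1e-12, rn / bn, 0)
  if (any(rel > 10 * tol))
    te_stop("ill_conditioned", sprintf("forward collocation residual %.3g above 10x tolerance",
                                       max(rel)))
  if (any(rel > tol))
    te_warn("ill_conditioned", sprintf("forward collocation residual %.3g above tolerance", max(rel)))
  signal_block(op$E %*% X, rate = heart_potentials$rate, t0 = heart_potentials$t0,
               channel_ids = op$electrodes$labels,
               valid = op$electrodes$valid)
}

#' Render the optical-mapping movie
#'
#' Z-buffer rasterization of the camera-visible epicardium: every pixel
#' covered by a front-facing, depth-nearest triangle takes the normalized Vm
#' of the triangle vertex with the largest barycentric weight (piecewise
#' constant shading), scaled by `amplitude_field`. Frames are then blurred
#' in-plane with a Gaussian (photon-scattering analogue) and seeded Gaussian
#' noise at `scenario$noise_snr_db` is added everywhere; background pixels
#' carry noise only. The sync channel is a square wave on the electrical
#' timebase, high exactly while the camera is exposing.
#'
#' @param vm `signal_block` of Vm on heart nodes at the optical rate; its
#'   `t0` is the exposure start on the shared clock.
#' @param heart heart `trimesh`.
#' @param camera a `camera_model`.
#' @param scenario a `scenario_config` (noise level + seed).
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 disables).
#' @param amplitude_field optional per-vertex fluorescence amplitude.
#' @param sync_rate electrical sampling rate for the sync wave, Hz.
#' @return an `optical_stack`; attributes `pixel_vertex` (visible vertex per
#'   covered pixel) and `covered` carry the ground-truth assignment.
#' @export
render_optical <- function(vm, heart, camera, scenario, blur_sigma_px = 1,
                           amplitude_field = NULL, sync_rate = 2000) {
  ras <- rasterize_mesh(camera, heart)
  covered <- !is.na(ras$pixel_vertex)
  if (!any(covered)) te_stop("empty_view", "heart entirely outside the camera frustum")
  np <- prod(camera$image_size)
  Tn <- ncol(vm$samples)
  amp <- amplitude_field %||% rep(1, nrow(heart$vertices))
  F0 <- matrix(0, np, Tn)
  F0[covered, ] <- amp[ras$pixel_vertex[covered]] * vm$samples[ras$pixel_vertex[covered], ]
  if (blur_sigma_px > 0) {
    G1 <- gaussian_blur_matrix(camera$image_size[1], blur_sigma_px)
    G2 <- gaussian_blur_matrix(camera$image_size[2], blur_sigma_px)
    F0 <- as.matrix(Matrix::kronecker(G1, G2) %*% F0) # row-major pixel order
  }
  if (is.finite(scenario$noise_snr_db)) {
    sig_rms <- stats::sd(as.numeric(F0[covered, ]))
    noise_sd <- sig_rms / 10^(scenario$noise_snr_db / 20)
    set.seed(child_seed(scenario$seed, 77L))
    F0 <- F0 + matrix(stats::rnorm(np * Tn, sd = noise_sd), np, Tn)
  }
  dur_ms <- Tn * 1000 / vm$rate
  n_sync <- ceiling((vm$t0 + dur_ms) * sync_rate / 1000)
  tt <- (seq_len(n_sync) - 1) * 1000 / sync_rate
  sync <- as.numeric(tt >= vm$t0 & tt < vm$t0 + dur_ms)
  st <- optical_stack(F0, rate = vm$rate, pixel_mm = camera$pixel_mm,
                      sync = sync, sync_rate = sync_rate,
                      image_size = camera$image_size, t0 = vm$t0)
  attr(st, "pixel_vertex") <- ras$pixel_vertex
  attr(st, "covered") <- covered
  st
}

# 1D Gaussian blur as a row-normalized banded sparse matrix.
gaussian_blur_matrix <- function(n, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  offs <- -half:half
  w <- exp(-offs^2 / (2 * sigma^2))
  i <- rep(seq_len(n), each = length(offs))
  j <- i + rep(offs, times = n)
  keep <- j >= 1 & j <= n
  G <- Matrix::sparseMatrix(i = i[keep], j = j[keep],
                            x = rep(w, times = n)[keep], dims = c(n, n))
  Matrix::Diagonal(x = 1 / Matrix::rowSums(G)) %*% G
}
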
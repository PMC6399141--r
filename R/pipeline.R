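#' Default pipeline configuration
#'
#' The stated synthetic world: a 30x30x40 mm ellipsoidal heart (4 mm mean
#' edge) centred in a 5x-scaled tank, a 108-electrode sock, 256 tank
#' electrodes of which 128 record, 2 Hz pacing (500 ms cycles, 2 beats),
#' electrograms at 2 kHz, a 100x100 px / 0.7 mm optical window at 1 kHz
#' starting 100 ms into the electrical recording, 20 dB optical and 30 dB
#' electrical SNR, and two sequences — anterior pacing with normal perfusion
#' and the same pacing with a slowed/late-repolarizing LAD-bed analogue
#' (conduction velocity x0.7, APD +40 ms over a 20 mm-radius bed).
#'
#' @param seed global seed.
#' @param n_sequences how many of the default sequences to keep.
#' @param heart_edge_mm heart mesh resolution (mean edge target).
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, n_sequences = 2L,
                                    heart_edge_mm = 4) {
  list(
    seed = as.integer(seed),
    geometry = list(
      heart_semi_axes = c(30, 30, 35), heart_center = c(0, 0, 0),
      heart_edge_mm = heart_edge_mm,
      tank_scale = c(3.5, 3.5, 2.5), tank_edge_mm = 14,
      n_sock = 108L, n_tank = 256L, n_tank_recording = 128L),
    camera = list(
      X_COP = c(0, 0, 300), X_FOC = c(0, 0, 0), roll = 0,
      init_cop_offset_mm = 20, init_foc_offset_mm = 5,
      init_roll_offset = 0.02, init_scale_factor = 1.03,
      ref_jitter_px = 1),
    protocol = list(
      n_beats = 2L, cycle_ms = 500, elec_rate = 2000, optical_rate = 1000,
      stim_delay_ms = 50, optical_t0_ms = 40, elec_snr_db = 30),
    sequences = lapply(seq_len(n_sequences), function(k) list(
      name = sprintf("seq_%02d", k),
      pacing = "anterior",
      cv_base = 1, apd_base = 190,
      perfusion = if (k >= 2) list(center = "anterior_offset",
                                   radius_mm = 20,
                                   cv_factor = 0.7, apd_delta = 40),
      noise_snr_db = 20)),
    mfs = list(deflate = 0.8, inflate = 1.2,
               forward_factors = c(0.7, 1.3), lam_mode = "median",
               gaf_radius_mm = 20),
    markers = list(rt_window = c(50, 450), ecgi_rt_window = c(100, 420)),
    metrics = list(cutoff_px = 5)
  )
}

#' @rdname default_pipeline_config
#' @param path JSON configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) te_stop("usage_error", paste("config not found:", path))
  jsonlite::read_json(path, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

# resolve symbolic pacing / perfusion locations to vertex indices
resolve_vertex <- function(spec, heart) {
  if (is.numeric(spec)) return(as.integer(spec))
  v <- heart$vertices
  switch(as.character(spec),
         anterior = which.max(v[, 3]),
         anterior_offset = which.min((v[, 3] - max(v[, 3]) * 0.55)^2 +
                                     (v[, 1] - 15)^2 + v[, 2]^2),
         posterior = which.min(v[, 3]),
         te_stop("invalid_parameter", paste("unknown site:", spec)))
}

add_noise_snr <- function(samples, snr_db, seed) {
  if (!is.finite(snr_db)) return(samples)
  set.seed(seed)
  samples + stats::rnorm(length(samples),
                         sd = stats::sd(as.numeric(samples)) / 10^(snr_db / 20))
}

# average a block over n_beats fixed windows [t_start + k*cycle, +cycle)
average_windows <- function(block, t_start_ms, cycle_ms, n_beats) {
  dt <- 1000 / block$rate
  n <- round(cycle_ms / dt)
  tt <- sb_times(block)
  acc <- matrix(0, nrow(block$samples), n)
  for (k in seq_len(n_beats) - 1L) {
    i0 <- which.min(abs(tt - (t_start_ms + k * cycle_ms)))
    acc <- acc + block$samples[, i0:(i0 + n - 1L), drop = FALSE]
  }
  signal_block(acc / n_beats, rate = block$rate, t0 = t_start_ms,
               channel_ids = block$channel_ids, valid = block$valid)
}

#' Run the full torso-tank validation pipeline
#'
#' Simulate, preprocess, align, reconstruct, mark and compare: for every
#' configured sequence the pipeline generates ground-truth activation, Vm,
#' sock electrograms, tank potentials (mismatched-forward MFS) and the
#' optical movie; preprocesses the optical stack (spatial/temporal
#' averaging, 20% mask), syncs and beat-averages the electrical data; aligns
#' the camera in two stages on sequence 1; reconstructs epicardial
#' electrograms by ECGI; detects AT/RT markers in each modality; and
#' produces the per-sequence sock-vs-optical and ECGI-vs-optical AT/RT
#' comparison table plus repolarization gradient profiles.
#'
#' @param config configuration list, see [default_pipeline_config()].
#' @param out_dir run directory (created; artifacts and `summary.csv` are
#'   written there). `NULL` keeps everything in memory.
#' @return invisible list with geometry, cameras, per-sequence results and
#'   the `summary` data.frame.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  st <- pipeline_simulate(config)
  st <- pipeline_preprocess(st)
  st <- pipeline_align(st)
  st <- pipeline_reconstruct(st)
  st <- pipeline_markers(st)
  st <- pipeline_compare(st)
  if (!is.null(out_dir)) pipeline_write(st, out_dir)
  invisible(st)
}

# ---- stage: simulate -------------------------------------------------------

pipeline_simulate <- function(config) {
  g <- config$geometry; pr <- config$protocol
  fwd_op <- NULL
  seed <- config$seed %||% 1L
  heart <- make_heart_mesh(g$heart_semi_axes, g$heart_center, g$heart_edge_mm)
  tank <- make_torso_tank(heart, g$tank_scale, g$tank_edge_mm)
  sock <- place_electrodes(heart, g$n_sock, seed = child_seed(seed, 1))
  tank_all <- place_electrodes(tank, g$n_tank, seed = child_seed(seed, 2),
                               label_prefix = "T")
  rec_idx <- seq_len(g$n_tank_recording)
  tank_rec <- electrode_set(tank_all$positions[rec_idx, , drop = FALSE],
                            tank_all$labels[rec_idx],
                            tank_all$host_vertex[rec_idx],
                            normals = tank_all$normals[rec_idx, , drop = FALSE])
  cam_truth <- camera_model(config$camera$X_COP, config$camera$X_FOC,
                            roll = config$camera$roll %||% 0)
  sequences <- list()
  for (i in seq_along(config$sequences)) {
    sq <- config$sequences[[i]]
    region <- integer()
    if (!is.null(sq$perfusion))
      region <- perfusion_bed(heart, resolve_vertex(sq$perfusion$center, heart),
                              sq$perfusion$radius_mm)
    sc <- scenario_config(
      pacing_site = resolve_vertex(sq$pacing, heart),
      pacing_cycle_ms = pr$cycle_ms, cv_base = sq$cv_base %||% 1,
      apd_base = sq$apd_base %||% 200, perfusion_region = region,
      cv_factor_region = if (is.null(sq$perfusion)) 1 else sq$perfusion$cv_factor,
      apd_delta_region = if (is.null(sq$perfusion)) 0 else sq$perfusion$apd_delta,
      noise_snr_db = sq$noise_snr_db %||% 20,
      seed = child_seed(seed, 10 + i))
    at_true <- simulate_activation(heart, sc)
    apd <- apd_field(heart, sc)
    # shift by the stimulus delay and simulate one spare beat so that the
    # optical window can hold n_beats complete cycles
    at_sim <- time_map(at_true$times + (pr$stim_delay_ms %||% 50),
                       at_true$valid, "mesh_nodes")
    vm2k <- synthesize_vm(at_sim, apd, rate = pr$elec_rate,
                          n_beats = pr$n_beats + 1L, cycle_ms = pr$cycle_ms)
    all_nodes <- electrode_set(heart$vertices,
                               sprintf("node%04d", seq_len(nrow(heart$vertices))),
                               seq_len(nrow(heart$vertices)))
    phi_nodes <- synthesize_unipolar_egm(vm2k, heart, all_nodes)
    sock_egm <- signal_block(phi_nodes$samples[sock$host_vertex, , drop = FALSE],
                             rate = pr$elec_rate,
                             channel_ids = sock$labels)
    sock_egm$samples <- add_noise_snr(sock_egm$samples, pr$elec_snr_db,
                                      child_seed(sc$seed, 3))
    if (is.null(fwd_op))
      fwd_op <- mfs_forward_operator(heart, tank, tank_rec,
                                      factors = config$mfs$forward_factors)
    tank_sig <- forward_apply(fwd_op, phi_nodes)
    tank_sig$samples <- add_noise_snr(tank_sig$samples, pr$elec_snr_db,
                                      child_seed(sc$seed, 4))
    # optical window: 1 kHz Vm cropped to [optical_t0, end)
    keep <- seq(1, ncol(vm2k$samples), by = round(pr$elec_rate / pr$optical_rate))
    tt <- sb_times(vm2k)[keep]
    win <- tt >= pr$optical_t0_ms &
      tt < pr$optical_t0_ms + pr$n_beats * pr$cycle_ms + 160
    vm1k <- signal_block(vm2k$samples[, keep[win], drop = FALSE],
                         rate = pr$optical_rate, t0 = pr$optical_t0_ms)
    stack <- render_optical(vm1k, heart, cam_truth, sc,
                            sync_rate = pr$elec_rate)
    sequences[[sq$name %||% sprintf("seq_%02d", i)]] <-
      list(name = sq$name %||% sprintf("seq_%02d", i), scenario = sc,
           at_true = at_true, apd = apd, sock_egm = sock_egm,
           tank_sig = tank_sig, stack = stack)
  }
  list(config = config, heart = heart, tank = tank, sock = sock,
       tank_all = tank_all, tank_rec = tank_rec, cam_truth = cam_truth,
       sequences = sequences)
}

# ---- stage: preprocess -----------------------------------------------------

pipeline_preprocess <- function(st) {
  pr <- st$config$protocol
  for (nm in names(st$sequences)) {
    sq <- st$sequences[[nm]]
    stack <- spatial_average(sq$stack)
    stack <- temporal_average(stack)
    mask <- compute_mask(stack)
    sq$mask <- mask
    offset <- sync_align(sq$sock_egm, stack$sync)
    sq$sync_offset_ms <- offset
    sq$sock_aligned <- align_to_optical(drop_bad_channels(sq$sock_egm), offset,
                                        pr$optical_rate)
    sq$tank_aligned <- align_to_optical(drop_bad_channels(sq$tank_sig), offset,
                                        pr$optical_rate)
    stack$t0 <- 0 # optical clock: frame 0 at time 0
    sq$stack_pp <- stack
    # beat-average sock on its own detected beats; re-use that window for
    # tank and optical so all modalities share one clock
    sq$sock_beat <- beat_average(sq$sock_aligned, pr$n_beats)
    t0w <- sq$sock_beat$t0
    sq$tank_beat <- average_windows(sq$tank_aligned, t0w, pr$cycle_ms, pr$n_beats)
    ob <- average_windows(
      signal_block(stack$frames, rate = stack$rate, t0 = 0),
      t0w, pr$cycle_ms, pr$n_beats)
    sq$stack_beat <- optical_stack(ob$samples, rate = stack$rate,
                                   pixel_mm = stack$pixel_mm, mask = mask$grid,
                                   image_size = stack$image_size, t0 = ob$t0)
    attr(sq$stack_beat, "pixel_vertex") <- attr(sq$stack, "pixel_vertex")
    st$sequences[[nm]] <- sq
  }
  st
}

# ---- stage: align ----------------------------------------------------------

pipeline_align <- function(st) {
  cc <- st$config$camera
  seed <- st$config$seed %||% 1L
  pr <- project(st$cam_truth, st$sock$positions)
  set.seed(child_seed(seed, 21))
  E2D <- cbind(pr$u, pr$v) +
    matrix(stats::rnorm(2 * nrow(st$sock$positions),
                        sd = cc$ref_jitter_px %||% 1), ncol = 2)
  E2D[!pr$visible, ] <- NA
  set.seed(child_seed(seed, 22))
  dcop <- stats::rnorm(3); dcop <- dcop / vnorm(dcop) * (cc$init_cop_offset_mm %||% 20)
  init <- camera_model(st$cam_truth$X_COP + dcop,
                       st$cam_truth$X_FOC + stats::rnorm(3, sd = (cc$init_foc_offset_mm %||% 5) / sqrt(3)),
                       roll = st$cam_truth$roll + (cc$init_roll_offset %||% 0.02),
                       focal_scale = st$cam_truth$focal_scale * (cc$init_scale_factor %||% 1.03))
  st$E2D <- E2D
  st$cam_init <- init
  st$cam_stage1 <- optimize_stage1(init, st$sock, E2D,
                                   n_starts = cc$n_starts %||% 5,
                                   seed = child_seed(seed, 23))
  # stage 2 on the first sequence's activation maps
  sq <- st$sequences[[1]]
  sock_mk <- detect_markers(sq$sock_beat,
                            rt_window = st$config$markers$rt_window %||% c(50, 450))
  opt_mk <- optical_markers(sq$stack_beat, sq$mask,
                            rt_window = st$config$markers$rt_window %||% c(50, 450))
  st$cam_stage2 <- tryCatch(
    optimize_stage2(st$cam_stage1, st$sock, sock_mk$at, opt_mk$at, sq$mask),
    tankecgi_warning = function(w) st$cam_stage1)
  st$stage_costs <- c(init = electrode_cost(init, st$sock, E2D),
                      stage1 = attr(st$cam_stage1, "cost_px") %||% NA)
  st
}

# ---- stage: reconstruct ----------------------------------------------------

pipeline_reconstruct <- function(st) {
  st$sources <- build_sources(st$heart, st$tank, st$tank_rec,
                              deflate = st$config$mfs$deflate %||% 0.8,
                              inflate = st$config$mfs$inflate %||% 1.2)
  for (nm in names(st$sequences)) {
    st$sequences[[nm]]$ecgi <- reconstruct_egms(
      st$sequences[[nm]]$tank_beat, st$sources, st$heart, st$tank_rec,
      lam_mode = st$config$mfs$lam_mode %||% "median")
  }
  st
}

# ---- stage: markers --------------------------------------------------------

pipeline_markers <- function(st) {
  rtw <- st$config$markers$rt_window %||% c(50, 450)
  r <- st$config$mfs$gaf_radius_mm %||% 20
  st$gaf_adjacency <- radius_adjacency(st$heart, r)
  for (nm in names(st$sequences)) {
    sq <- st$sequences[[nm]]
    sq$sock_markers <- detect_markers(sq$sock_beat, rt_window = rtw)
    sq$optical_markers <- optical_markers(sq$stack_beat, sq$mask, rt_window = rtw)
    at_gaf <- global_activation_field(sq$ecgi, st$gaf_adjacency %||% st$heart)
    ertw <- st$config$markers$ecgi_rt_window %||% c(100, 420)
    rt <- vapply(seq_len(nrow(sq$ecgi$samples)), function(i)
      rt_from_egm(sq$ecgi$samples[i, ], sq$ecgi$rate, sq$ecgi$t0,
                  at = at_gaf$times[i], rt_window = ertw), 0)
    sq$ecgi_markers <- list(at = at_gaf,
                            rt = time_map(rt, domain_tag = "ecgi_nodes"),
                            method_tag = "ecgi_gaf")
    st$sequences[[nm]] <- sq
  }
  st
}

# ---- stage: compare --------------------------------------------------------

pipeline_compare <- function(st) {
  cam <- st$cam_stage2 %||% st$cam_stage1
  cutoff <- st$config$metrics$cutoff_px %||% 5
  rows <- list()
  for (nm in names(st$sequences)) {
    sq <- st$sequences[[nm]]
    # sock electrodes -> pixels
    prs <- project(cam, st$sock$positions)
    viss <- which(prs$visible & front_facing(st$heart, cam)[st$sock$host_vertex])
    ps <- pair_to_pixels(cbind(prs$u[viss], prs$v[viss]), sq$mask, cutoff)
    sock_pairs <- data.frame(i = viss[ps$point], j = ps$pixel)
    # ecgi nodes -> pixels (visible submesh assignment)
    vs <- visible_submesh(cam, st$heart)
    pe <- pair_to_pixels(cbind(vs$proj$u[vs$vertices], vs$proj$v[vs$vertices]),
                         sq$mask, cutoff)
    ecgi_pairs <- data.frame(i = vs$vertices[pe$point], j = pe$pixel)
    cmp <- list(
      sock_vs_optical_at = compare_maps(sq$sock_markers$at, sq$optical_markers$at, sock_pairs),
      sock_vs_optical_rt = compare_maps(sq$sock_markers$rt, sq$optical_markers$rt, sock_pairs),
      ecgi_vs_optical_at = compare_maps(sq$ecgi_markers$at, sq$optical_markers$at, ecgi_pairs),
      ecgi_vs_optical_rt = compare_maps(sq$ecgi_markers$rt, sq$optical_markers$rt, ecgi_pairs))
    sq$comparisons <- cmp
    sq$pairs <- list(sock = sock_pairs, ecgi = ecgi_pairs)
    # repolarization gradient profile across the perfusion-bed border
    if (length(sq$scenario$perfusion_region)) {
      sq$gradient <- gradient_profiles(st, sq, cam)
    }
    st$sequences[[nm]] <- sq
    for (cn in names(cmp))
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = nm, comparison = cn, cc = cmp[[cn]]$cc,
        rmse_ms = cmp[[cn]]$rmse, n_pairs = cmp[[cn]]$n_pairs)
  }
  st$summary <- do.call(rbind, rows)
  st
}

front_facing <- function(mesh, camera) {
  rowSums(mesh$vertex_normals * sweep(mesh$vertices, 2, camera$X_COP, `-`)) < 0
}

# optical + ECGI RT profiles against distance from the bed centre ("star"),
# inside a box spanning the bed border
gradient_profiles <- function(st, sq, cam) {
  region <- sq$scenario$perfusion_region
  vs <- visible_submesh(cam, st$heart)
  vis_reg <- intersect(vs$vertices, region)
  if (!length(vis_reg)) return(NULL)
  pix <- vs$pixels[match(vis_reg, vs$vertices), , drop = FALSE]
  ref <- round(colMeans(pix)) # star: bed centre in the image
  half <- max(8L, round(max(stats::dist(pix)) / 2) + 6L)
  roi <- c(max(0, ref[1] - half), min(st$cam_truth$image_size[1] - 1, ref[1] + half),
           max(0, ref[2] - half), min(st$cam_truth$image_size[2] - 1, ref[2] + half))
  # per-pixel ECGI RT map via the node -> pixel assignment
  np <- prod(sq$stack_beat$image_size)
  ec <- rep(NA_real_, np)
  lin <- px_index(vs$pixels[, 1], vs$pixels[, 2], sq$stack_beat$image_size)
  ec[lin] <- sq$ecgi_markers$rt$times[vs$vertices]
  list(optical = gradient_profile(sq$optical_markers$rt, roi, ref,
                                  sq$stack_beat$pixel_mm,
                                  sq$stack_beat$image_size, "optical"),
       ecgi = gradient_profile(time_map(ec, domain_tag = "optical_pixels"),
                               roi, ref, sq$stack_beat$pixel_mm,
                               sq$stack_beat$image_size, "ecgi"),
       ref = ref, roi = roi, region_pixels = pix)
}

# ---- artifacts -------------------------------------------------------------

pipeline_write <- function(st, out_dir) {
  gdir <- file.path(out_dir, "geometry")
  dir.create(gdir, showWarnings = FALSE, recursive = TRUE)
  write_ply(st$heart, file.path(gdir, "heart.ply"))
  write_ply(st$tank, file.path(gdir, "tank.ply"))
  write_vtk(st$heart, file.path(gdir, "heart.vtk"))
  write_electrodes_csv(st$sock, file.path(gdir, "sock_electrodes.csv"))
  write_electrodes_csv(st$tank_all, file.path(gdir, "tank_electrodes.csv"))
  write_camera_json(st$cam_truth, file.path(out_dir, "camera_truth.json"))
  if (!is.null(st$cam_stage1))
    write_camera_json(st$cam_stage1, file.path(out_dir, "camera_stage1.json"))
  if (!is.null(st$cam_stage2))
    write_camera_json(st$cam_stage2, file.path(out_dir, "camera_stage2.json"))
  for (nm in names(st$sequences)) {
    sq <- st$sequences[[nm]]
    sdir <- file.path(out_dir, nm)
    dir.create(sdir, showWarnings = FALSE)
    write_timemap_csv(sq$at_true, file.path(sdir, "truth_at.csv"))
    if (!is.null(sq$mask)) write_mask_csv(sq$mask, file.path(sdir, "mask.csv"))
    if (!is.null(sq$sock_markers)) {
      write_timemap_csv(sq$sock_markers$at, file.path(sdir, "sock_at.csv"))
      write_timemap_csv(sq$sock_markers$rt, file.path(sdir, "sock_rt.csv"))
    }
    if (!is.null(sq$ecgi_markers)) {
      write_timemap_csv(sq$ecgi_markers$at, file.path(sdir, "ecgi_at.csv"))
      write_timemap_csv(sq$ecgi_markers$rt, file.path(sdir, "ecgi_rt.csv"))
      utils::write.csv(data.frame(lambda = attr(sq$ecgi, "lambda_trace")),
                       file.path(sdir, "lambda_trace.csv"), row.names = FALSE)
    }
    if (!is.null(sq$gradient)) {
      utils::write.csv(rbind(sq$gradient$optical$samples, sq$gradient$ecgi$samples),
                       file.path(sdir, "rt_gradient_profile.csv"), row.names = FALSE)
    }
  }
  if (!is.null(st$summary))
    utils::write.csv(st$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = st$config$seed, package = "tankecgi",
         version = tryCatch(as.character(utils::packageVersion("tankecgi")),
                            error = function(e) "dev"),
         config = st$config),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE, null = "null")
  invisible(out_dir)
}
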
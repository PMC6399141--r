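# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cache <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# 162-vertex sphere, r = 30 mm
fx_sphere30 <- function() fx_cache("sphere30", function()
  make_heart_mesh(c(30, 30, 30), c(0, 0, 0), 8))

# fine sphere for visibility statistics
fx_sphere_fine <- function() fx_cache("sphere_fine", function()
  make_heart_mesh(c(30, 30, 30), c(0, 0, 0), 2))

# concentric-spheres phantom: heart r = 30, tank r = 60, 128 electrodes
fx_phantom <- function() fx_cache("phantom", function() {
  heart <- make_heart_mesh(c(30, 30, 30), c(0, 0, 0), 8)
  tank <- make_heart_mesh(c(60, 60, 60), c(0, 0, 0), 15)
  electrodes <- place_electrodes(tank, 128, seed = 5, label_prefix = "T")
  list(heart = heart, tank = tank, electrodes = electrodes,
       a = 30, R = 60,
       sources = build_sources(heart, tank, electrodes))
})

# random degree-limited spherical-harmonic field on the phantom
fx_harmonic_field <- function(deg, seed) {
  ph <- fx_phantom()
  sb <- sph_basis(ph$heart$vertices, deg)
  set.seed(seed)
  coeffs <- data.frame(l = sb$lm$l, m = sb$lm$m, c = stats::rnorm(nrow(sb$lm)))
  list(coeffs = coeffs,
       heart_values = eval_sph_field(coeffs, ph$heart$vertices),
       tank_values = eval_sph_field(
         forward_spheres_analytic(coeffs, ph$a, ph$R, ph$R),
         ph$electrodes$positions))
}

# single-beat synthetic heart with electrodes and markers ground truth
fx_beat <- function() fx_cache("beat", function() {
  heart <- fx_sphere30()
  sc <- scenario_config(pacing_site = which.max(heart$vertices[, 3]),
                        cv_base = 1, apd_base = 190, noise_snr_db = Inf,
                        seed = 7)
  at <- simulate_activation(heart, sc)
  apd <- apd_field(heart, sc)
  vm <- synthesize_vm(at, apd, rate = 1000, n_beats = 1, cycle_ms = 500)
  electrodes <- place_electrodes(heart, 24, seed = 3)
  egm <- synthesize_unipolar_egm(vm, heart, electrodes)
  list(heart = heart, scenario = sc, at = at, apd = apd, vm = vm,
       electrodes = electrodes, egm = egm)
})

# small mini-pipeline configuration (fast; used by pipeline/CLI tests)
fx_mini_config <- function(seed = 1L) {
  cfg <- default_pipeline_config(seed = seed, heart_edge_mm = 8)
  cfg$geometry$n_sock <- 32L
  cfg$geometry$n_tank <- 120L
  cfg$geometry$n_tank_recording <- 96L
  cfg$geometry$tank_edge_mm <- 28
  cfg$camera$n_starts <- 2L
  cfg
}

expect_te_error <- function(expr, class) {
  expect_error(expr, class = class)
}
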
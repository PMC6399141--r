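---
title: "Methods: a synthetic torso-tank platform for validating ECGI against optical mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a synthetic torso-tank platform for validating ECGI against optical mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`tankecgi` emulates a torso-tank ECGI validation experiment: an isolated
heart inside an electrolyte-filled human-shaped tank, an epicardial
electrode sock, tank-surface electrodes, and voltage-dye optical mapping of
the anterior epicardium through the tank wall. Every data product is
synthesized from a seeded configuration, so each algorithm in the analysis
chain — camera alignment, the MFS/Tikhonov/CRESO inverse solution, marker
detection, map comparison — can be tested against known ground truth. This
vignette records the models, their assumptions, the tunable parameters, and
the numerical decisions that were genuinely open.

## The synthetic world

**Geometry.** The epicardium is an analytic ellipsoid (default semi-axes
30 × 30 × 35 mm, a pig-heart-sized ventricular mass) triangulated by
icosphere subdivision; the subdivision level is chosen so the measured mean
edge length is closest to a 4 mm target, matching fluoroscopy-derived
meshes. The tank is a second ellipsoid scaled from the heart (default
3.5 × 3.5 × 2.5), giving wall-to-epicardium distances of roughly 65–100 mm —
typical electrode-to-heart distances for tank body-surface mapping. The
algorithms are geometry-generic; anatomical realism is deliberately out of
scope. Electrodes (108 sock, 256 tank of which 128 record) are snapped to
mesh vertices by geodesic farthest-point sampling from a seeded start, so
coverage is near-uniform and reproducible.

**Activation and repolarization.** Ground-truth activation is the
shortest-path travel time through the mesh edge graph from a pacing site,
each edge costing length/CV (CV 1 mm/ms by default, typical working
myocardium). Edges inside the perfusion bed — all vertices within a geodesic
radius of a bed centre, the analogue of the separately perfused LAD bed —
use CV × `cv_factor_region`. Graph geodesics overestimate true surface
geodesics by up to ~8 % on coarse meshes (the antipodal test asserts this
bound); that bias is irrelevant here because the same field is both the
simulation input and the comparison truth. APD is uniform (190 ms) plus an
additive regional change (+40 ms in the default perturbed sequence). Pacing
is 2 Hz (500 ms cycles); a stimulus delay of 50 ms keeps the entire beat,
including the repolarization tail, inside one cycle.

**Action potentials and electrograms.** Per-node transmembrane potentials
are products of two logistic sigmoids: a fast upstroke (τ = 0.6 ms) centred
at AT and a slower repolarization (τ = 6 ms) centred at AT + APD, normalized
to [0, 1]. By construction max dVm/dt falls at AT (±1 sample) and min dVm/dt
at AT + APD (±2 samples). Unipolar electrograms are "far field minus local":
φ(e,t) = Σⱼ uⱼ Vmⱼ(t) − V_loc(e,t), with inverse-square-distance weights
over nodes farther than ρ = 3 mm and V_loc the mean over nodes within ρ. On
a ~4 mm mesh the local set is just the host vertex, which provably gives the
classical marker semantics: the steepest local depolarization appears as the
electrogram's minimum dV/dt (intrinsic deflection) and the steepest local
repolarization as its maximum dV/dt (T-wave upslope). This is an intentional
construction, not a bidomain model: it guarantees the marker relations the
validation logic relies on, and nothing else.

**Forward problem.** Tank potentials are computed by MFS collocation on the
interior Laplace problem (Dirichlet epicardial potentials, zero normal
current at the tank wall), with sources on a heart surface deflated by 0.7
and a tank surface inflated by 1.3 and collocation at every heart and tank
vertex. The inverse solver uses a different configuration (0.8 / 1.2,
sources at tank *electrodes* only), so inverse tests do not commit the
inverse crime of inverting the exact forward model. Against the analytic
concentric-spheres solution (degree-l transfer
T_l(r) = (r^l + l/(l+1)·R^(2l+1)·r^−(l+1)) / (a^l + l/(l+1)·R^(2l+1)·a^−(l+1)))
the forward solver agrees to ~1 % relative RMS for harmonics of degree ≤ 5.

**Optical movie.** The camera is a pinhole: view axis from X_COP to X_FOC,
roll about that axis, focal scale in px per unit tangent (default: the focal
plane sampled at 0.7 mm/px). Frames are rendered by z-buffer rasterization
of front-facing triangles; each covered pixel takes the normalized Vm of the
triangle vertex with the largest barycentric weight. This piecewise-constant
shading is deliberate: it keeps per-pixel ground truth exact (each pixel has
one generating vertex), at the cost of blocky sub-triangle detail that the
Gaussian scattering blur (σ = 1 px) immediately smooths anyway. Optical
noise defaults to 20 dB SNR; electrical noise to 30 dB. Neither is a claim
about any particular camera or amplifier — they are module parameters. The
camera-sync square wave is high exactly during exposure, sampled on the
2 kHz electrical timebase.

What the generator does **not** emulate: transmural averaging (the real
optical signal integrates ~4 mm of depth; only in-plane blur is modelled),
motion artefact, fractionated electrograms, dye bleaching, illumination
inhomogeneity, and conduction anisotropy. A green end-to-end test therefore
establishes that the analysis chain is internally correct on clean
wavefront-like data — not that it is robust to every pathology of real
recordings.

## Signal processing

Averaging kernels follow the experimental settings: a 2.1 mm spatial kernel
(3 px at 0.7 mm/px, square window, uniform weights — kernel shape is not
specified experimentally, so uniform was chosen), restricted to in-mask
pixels, and a 1.5 ms temporal kernel, rounded up to the smallest odd sample
count (3 samples at 1 kHz) with edge truncation. The data mask keeps pixels
whose max−min amplitude reaches 20 % of the global maximum, retains the
largest 8-connected component, and closes the edges morphologically
(dilation then erosion, disk radius 1 px); the cleanup is idempotent and its
output is a single component. Beats are detected on the cross-channel RMS
trace (threshold at half range, 150 ms refractory), aligned to the first
beat by integer-lag cross-correlation (partial windows allowed at the
recording edges), and averaged. Bad channels are flagged automatically —
temporal SD below 1 % of the median *live-channel* SD, or any non-finite
sample — because visual inspection is not reproducible; more than 50 %
flagged channels is treated as a data-quality failure rather than silently
continuing.

## Camera alignment

Stage 1 minimizes the mean reprojection distance over electrode
correspondences with a seeded multi-start Nelder–Mead simplex over
(X_COP, X_FOC, roll, log focal_scale). Two parameters beyond the camera and
focal positions are optimized deliberately: a 6-parameter pinhole cannot
correct roll or magnification errors, and the focal-distance direction is a
gauge freedom (only the view axis matters). Stage 2 refines (X_COP, X_FOC)
against the mean absolute sock-vs-optical AT difference, bounded within
±10 % of the stage-1 parameter magnitudes; the second cost is the *absolute*
difference (the method is described as a mean absolute difference even where
a squared form is displayed; the prose reading is implemented, and the
ambiguity is recorded).

Two degeneracies surfaced during implementation and are guarded explicitly.
First, both costs are means over *currently visible* electrodes, so an
optimizer can cheat by pushing electrodes out of view and fitting the
survivors; candidate cameras that lose correspondences (stage 1) or
pairings (stage 2) relative to the start are rejected. Second, the camera
frame is built from a world-up reference; up = +z makes the frame
ill-conditioned for the near-axial views this rig actually uses (roll
becomes unidentifiable against tiny view-axis changes), so the reference is
+y with a +z fallback.

## ECGI: MFS, Tikhonov, CRESO

The inverse system has unknowns [a₀, c₁..c_m]: for each recording electrode
a Dirichlet row (free-space kernels 1/(4π‖e−s‖) matched to the measured,
Wilson-style re-referenced potential) and a Neumann row (kernel normal
derivatives matched to zero). Invalid channels lose both their rows.
Tikhonov solutions use SVD filter factors σ/(σ²+λ²); the solution norm is
non-increasing and the residual norm non-decreasing in λ (asserted as a
property test), and the residual is evaluated from the SVD pieces rather
than a closed-form difference of squared norms, which suffers catastrophic
cancellation when the fit is near-exact.

CRESO selects the smallest grid λ at which C(λ) = d/dλ [λ²‖x_λ‖²] attains an
interior local maximum (global maximum as fallback, with a warning). Two
numerical choices matter:

* **Grid floor.** The default grid spans [√ε, 1]·σ_max (ε = machine
  epsilon, 120 log-spaced points). On noiseless phantoms the signal-driven
  first local maximum can sit near 10⁻⁵·σ_max, below a 10⁻⁴·σ_max floor;
  below √ε the filtered components are numerically meaningless. The floor is
  a parameter of `creso_select`/`reconstruct_egms`.
* **Per-beat λ.** CRESO is evaluated per time sample, but the pipeline
  re-solves all samples with the *median* of the per-sample choices
  (`lam_mode = "median"`). With noisy data, per-sample first-local-maxima
  jump across up to five decades between adjacent samples; applying them
  directly injects sample-to-sample amplitude modulation that destroys any
  later delay estimation between reconstructed electrograms. The per-sample
  mode remains the default of `reconstruct_egms` itself.

Known limitation: on spectrally degenerate inputs (a *pure* low-degree
harmonic), the CRESO curve has a single broad maximum at large λ and the
selection oversmooths. Mixed-degree fields — which every simulated
potential map is — do not show this.

## Markers and the global activation field

Derivatives are first central differences at the native rate; ties break to
the earliest sample; a trace whose in-window range is below the noise floor
(default 10⁻⁶) is invalid, as is an optical trace with inverted polarity or
no negative slope in the repolarization window. Search windows are not
experimentally specified and are configurable: AT searches the whole beat,
RT searches [AT+50, AT+450) ms. For ECGI-reconstructed electrograms the
pipeline narrows the RT window to [AT+100, AT+420): Tikhonov smoothing
leaves a positive-derivative rebound immediately after the intrinsic
deflection, and the wider window catches it at its lower edge.

The global activation field estimates per-edge delays as the integer-lag
argmax of the cross-correlation of z-scored derivative traces (±30 ms,
edges with peak correlation < 0.5 dropped), then solves
min Σ w_ij (t_j − t_i − δ_ij)² + μ‖Lt‖² (μ = 10⁻², L the unweighted graph
Laplacian), with the additive gauge fixed by matching mean(t) to the mean
per-node min-dV/dt estimate. Two points:

* **Adjacency is an argument.** On a 4 mm mesh, ECGI's effective spatial
  resolution (~15 mm here) makes nearest-neighbour delays unresolvable —
  every correlation peaks at lag 0 and the fit collapses to a constant. The
  pipeline therefore supplies a 20 mm geodesic-radius adjacency
  (`radius_adjacency`), whose longer-range delays the reconstruction *can*
  measure. Mesh edges remain the default and are what the oracle tests use.
* **The Laplacian penalty is biased on kinked fields.** With exactly
  consistent delays the fit recovers smooth fields to < 0.1 ms (up to the
  gauge constant), but a field with a gradient discontinuity (the cone apex
  at a pacing site) is biased by ~0.3 ms near the kink — the small price of
  the smoothing that makes the method robust on real reconstructions. The
  same penalty underestimates spatial gradients, which is visible in the
  pipeline as a compressed ECGI activation range.

## Comparison metrics

Visible sock electrodes and mesh nodes are paired to their nearest in-mask
pixel (2D Euclidean distance, ties to the lowest (row, col), unpaired beyond
5 px so occluded or posterior points cannot leak in). CC is Pearson over
paired valid entries (reported only for ≥ 3 non-constant pairs), RMSE is the
root mean squared difference, SDs are sample (n−1), t-tests are classical
paired two-sided — all verified against brute-force or `stats` oracles.
Gradient profiles list every valid in-ROI pixel's time against its physical
distance from a reference pixel, the plot-ready form of the
across-the-border gradient analysis; the acceptance check asserts that the
ECGI repolarization profile across the perfused-bed border slopes in the
same direction as the ground truth.

## Reproducibility

Every stochastic step derives from one configuration seed through a fixed
child-seed schedule; running the same configuration twice yields
byte-identical summaries. Potentials are referenced quantities, so phantom
recovery is scored on mean-centred patterns (the Wilson re-reference
removes the absolute level by construction). Scaled-down meshes are used in
unit tests (162-vertex spheres) purely for speed; the end-to-end acceptance
runs use the full stated world (4 mm heart mesh, 108 + 256 electrodes,
100 × 100 px movie).
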
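---
title: "Methods: synthetic benchmarks for astrocyte ageing analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic benchmarks for astrocyte ageing analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`astroage` re-implements, as a verifiable pipeline, the computational
analysis used to characterise age-related remodelling of hippocampal CA1
astrocytes: 3D morphometry of dye-filled cells (Sholl profiles, domain
area, branch statistics), volume-fraction (VF) estimation of optically
unresolved perisynaptic processes, spatiotemporal Ca²⁺ event segmentation,
and voltage-clamp / field-potential analytics (input resistance, K⁺ and
glutamate-transporter current decomposition, LTP magnitude). Because no raw
data accompany the study, every stage is paired with a seeded synthetic
generator that emits machine-readable ground truth; correctness is
established by parameter recovery on planted values, by oracle equivalence
(brute-force pair counting, flood fill, voxel-shell Sholl), and by
closed-form limits (Ohm's law, mono-exponential decay, ratio arithmetic).

# The synthetic study conditions

The generator presets are the study conditions. Each printed group value is
planted as a preset parameter:

| quantity | adult | old |
|---|---|---|
| mean branch/branchlet length (µm) | 8.4 | 5.4 |
| primary branches | 8 | 7 |
| domain area (µm², projected footprint) | 2206 | 757 |
| unresolved-process VF (% of soma peak) | 4.5 | 2.1 |
| input resistance (MΩ) | 21.5 | 35.8 |
| I_K τ(5)/τ(1) | 0.81 | 1.15 |
| Ca²⁺ event median duration (s) / area (µm²) | 6 / 20.2 | 7 / 16.2 |
| LTP (% of baseline) | 153 | 128 |
| SR101 density (per 100×100 µm²) | 0.59 | 0.61 |
| dye-coupled neighbours | 7 | 3 |

Where discretization or geometry intervenes between a preset parameter and
the realised planted value, the preset carries a calibration constant fixed
at design time. Three matter in practice: the drawn branch-length mean is
scaled (`length_draw_scale`) because tiling termination and the merging of
single-daughter continuations reshape the realised segment population; the
territory radius of the old preset is set so the projected, closed,
hole-filled footprint equals 757 µm² rather than `pi * r^2` (a branch tree
does not fill its territory like a disc); and daughters that terminate
below the optical resolvability scale (`min_branch_um`: 4.5 µm for the
sparse adult arbor whose branch lengths are under test, 1.5 µm for the
dense old arbor whose footprint is under test) are discarded on both sides
of the ledger — thinning retracts tips by roughly a tube radius and spur
pruning removes what remains, so such a daughter leaves no recoverable
branch. When one daughter of a bifurcation is discarded, the survivor
simply continues its parent: no branch point exists, so parent and
survivor are merged into one planted branch, exactly as a tracer would see
them.

## Image stacks

A stack is a `[y, x, z]` voxel grid, by default 168×168×33 at 0.4 µm
laterally and 1 µm axially — the acquisition geometry of the source
recordings rescaled to a volume that keeps a full morphometry run in
seconds. A stack contains:

* a spherical soma (radius 4.5–5 µm, photon rate 140 photons/voxel); the
  old arbor is slightly less flattened (z half-extent 12 µm vs 10 µm),
  which keeps its rim-dwelling branch tips out of the single measurement
  plane the VF analysis uses;
* a branch tree grown as a recursive persistent random walk: each branch
  either bifurcates or terminates at its distal end, daughters fold
  outward (centrifugal growth), and growth is *self-avoiding* through an
  occupancy grid — astrocyte processes tile territory rather than cross.
  Outbound steps reflect off the territory ellipsoid and inbound ones off
  the soma ball (direction-gated, so a wiggling outward path is never
  folded back on itself). A daughter may pass near its parent and its
  siblings but not through unrelated processes;
* an isotropic "leaflet haze" at `leaflet_vf` × soma rate filling an
  ellipsoid that extends beyond the resolved-branch territory — leaflets
  surround the whole arbor, which is how a cell whose *resolved* footprint
  is 757 µm² can still show measurable VF 10–20 µm outside the soma
  border;
* an anisotropic Gaussian PSF (σ_xy 0.3 µm, σ_z 0.8 µm), then Poisson
  photon noise, PMT gain (2) and offset (100), and Gaussian read noise.

The read noise is deliberately large relative to the haze (haze ≈ 0.25 of
the noise sd). That is the regime the original measurements must have
occupied: the haze must stay below the 1σ hysteresis threshold (otherwise
the binarized mask would engulf the whole leaflet cloud and the "domain
area" would be the haze footprint), while remaining recoverable in *means*
of radial profiles. The adult preset carries a larger read noise than the
old one because its haze is twice as bright; per-session detector settings
differ in real acquisitions for exactly this reason.

## Calcium movies, sweeps, timecourses

Ca²⁺ movies plant constant-footprint disc events with a trapezoidal
temporal envelope at SNR 8, 1 frame/s, with 30 dark frames carrying only
the noise model. Durations are lognormal (median 6 s adult / 7 s old)
floored at 5 frames so planted events survive the >4 s astrocyte filter;
areas are lognormal with medians 20.2 / 16.2 µm². `reuse_prob` controls
re-initiation at previous spots (0.15 adult, 0.5 old). Events that cannot
be placed without 26-adjacency to an existing event are flagged
`merge_expected` in the ground truth.

Voltage-clamp sweeps are ohmic responses plus a capacitive edge transient;
synaptic sweeps are sums of per-stimulus fast transporter transients
(difference of exponentials, τ ≈ 15 ms) and a slow K⁺ envelope
(rise 20 ms, decay τ per preset) whose amplitude is *defined* at 200 ms
after the last stimulus — the measurement point of the analysis. The
5-stimulus sweep is constructed as the 4-stimulus sweep plus the planted
fifth-stimulus component, so burst subtraction has an exact target. The
transporter-block ("TBOA") sweeps contain `residual_ik_scale` × the K⁺
envelope, re-recorded per protocol as in the experiment.

fEPSP timecourses sample amplitudes every 20 s, 15 min of stable baseline,
60 min post-induction, with an exponential approach (τ = 4 min) to
`potentiation_factor` × baseline and 2% multiplicative noise.

# Analysis pipeline

## Photon calibration

Gain is the slope of the per-patch variance-vs-mean line. Patches whose
variance is structure-dominated would bias the slope, so patches are
screened for homogeneity first (sample variance vs first-difference
variance), with a one-sided trim as a safety net. The x-axis intercept
estimates the offset *only when additive read noise is negligible*: read
noise displaces the intercept by −σ²_read/gain. Both pipelines that care
about absolute levels near the noise floor therefore take the offset from
the median of a signal-free background region instead (`
estimate_offset_background`), where it is exact. The σ-relative
binarization and the soma-normalized VF are invariant to residual gain
error.

## Segmentation

Noise σ comes from dark frames when present, else from a lateral corner
box — never from the whole stack — and is estimated on the *unclipped*
intensities (clipping at zero deflates a MAD). Tubular contrast is
enhanced by plane-wise coherence-enhancing diffusion along all three axes
(structure-tensor steered, Weickert-type; the steering field is computed
once per plane from the pre-smoothed image and kept frozen, which is an
order of magnitude faster and equally effective at this noise level), the
three filtered volumes averaged. Binarization is hysteresis at 1σ/3σ with
26-connectivity, followed by pruning of components under 100 voxels
(components of exactly 100 are kept).

## Branch graph

The mask minus a padded soma ball (soma radius + 3 µm: at optical
resolution the crowded proximal processes merge into one body there) is
thinned to a curve skeleton by
topology-preserving directional thinning (simple-point tests: one
26-connected foreground component and one 6-connected background component
in the neighbourhood; endpoints preserved). Two practical refinements
matter:

* *Mask regularization.* Surface noise bumps form voxel-scale handles;
  a topology-preserving thinning must keep every loop, which shatters the
  skeleton into short cycle edges. A sub-voxel Gaussian smooth of the mask
  followed by re-thresholding removes those handles before thinning.
* *Soma complex.* Within ~3 µm of the soma the crowded proximal processes
  merge optically into one body; thinning a merged body yields lattice
  artefacts. That shell is treated as part of the soma, and each branch
  entering it becomes one anchor (skeleton voxels in the halo are
  clustered spatially; the innermost voxel of each cluster is the entry
  point).

The skeleton is traced into junction-to-junction paths and cleaned by
graph surgery: spurs shorter than 2 µm pruned, sub-2 µm bridges between
junction doublets contracted, and degree-2 nodes spliced back into single
edges. Terminal tips are extended along their final direction while still
inside the mask (thinning retracts ends by about the tube radius), and
primary edges are rooted at the soma surface. Edges shorter than 2 µm are
junction artefacts and are excluded from the mean branch length.

Sholl analysis counts transversal crossings of graph polylines with
concentric spheres (5–50 µm, 1 µm step) about the soma centre; the
voxel-shell count is the independent oracle in the tests. Domain area is
the morphologically closed (3 µm), hole-filled z maximum projection of the
mask. The noiseless ground-truth footprint uses the same closing and a
threshold at the pipeline's effective resolution (PSF ⊕ diffusion
averaging), so recovery is compared like for like; residual noise-driven
rim accretion still inflates the measured footprint by ~10%, which is why
the recovery property is tested at 15% rather than the 5% a noiseless
comparison would allow.

## Volume fraction

The soma plane is chosen by maximal integrated soma intensity, with a
saturation check. Five full lines at 72° yield ten half-profiles,
normalized to the soma peak of a strongly smoothed copy of the plane (the
raw maximum is biased upward by noise). Profiles are sampled at 0.1 µm
with a 1.6 µm transverse line width (finite-width line profiles, as in
standard line-scan tools). Branch peaks are excised where the excess over
a running-median baseline (12 µm window) exceeds 10 percentage points over
more than 0.5 µm; runs are detected on a 1 µm boxcar-smoothed excess (a
fluctuation must be coherent at branch scale, otherwise single-sample
noise at the adult noise level would be "excised" preferentially on the
positive side and bias VF down); each qualifying run is widened to where
the excess falls below a quarter of the threshold and then by a further
0.4 µm of fixed margin, so branch shoulders and their optical tails do not
leak into the average. Excised samples are dropped, never
interpolated. VF is the mean surviving fluorescence 10–20 µm beyond the
soma border; the cell value is the mean over the ten half-profiles. The
soma border is the first crossing of 30% of peak on the radially averaged
profile — at 50% the crossing sits inside the PSF-blurred soma flank,
which would drag the window's inner edge into the branch-tip zone of the
compact old arbor. The fraction is a configuration argument.

## Calcium events

Per pixel, F₀ is a rolling 20th percentile (121 s window); the threshold
is k·σ above *baseline*, i.e. the quantile offset between the 20th
percentile and the noise median is added back before thresholding —
without that correction every event gains spurious edge frames. Active
runs of ≤ 4 s are erased (the astrocyte/neuron discrimination), active
voxels are combined by 26-connectivity in (x, y, t), and components below
10 voxels discarded. Durations, maximal-projection areas, volumes and
first-frame intensity-weighted initiation pixels follow; initiation spots
are binned 2×2 by default.

## Electrophysiology

I-V and input resistance use plateau-minus-baseline windows (last 100 ms
of the step). Mono-exponential fits include a free offset (holding-current
drift) and use Levenberg-Marquardt from log-linear starting values; a
segment that ends farther from zero than it starts is rejected as
non-decaying. The transporter current is isolated by least-squares scaling
of the transporter-block template to the tail of the mixed current
(beyond last stimulus + 100 ms) and subtraction; for the fifth response
the template is itself burst-subtracted, mirroring the signal path. LTP
magnitude is the 50–60 min post-HFS mean over the baseline mean, with a
15 min / CV stability gate on the baseline.

# Statistics

Group comparisons use the equal-variance two-tailed t-test (Welch by
flag) and the two-sided Mann-Whitney U test with tie correction; the U
statistic is validated against exhaustive pair counting in the tests. The
source methods' line that p > 0.05 was "considered significant" is treated
as a typo; α = 0.05 with p < α significant, as every figure legend
implies. `run_pipeline()` orchestrates generation and analysis per group
and writes summary, test and provenance files; it is deterministic given
its seed.

# Problem sizes and runtime

Defaults are chosen so a full morphometry run takes a few seconds per
stack and the complete recovery suite minutes on one CPU: stacks
168×168×33, movies 64×64×600 at 1 frame/s, sweeps at 5 kHz. The
acceptance script reproduces each headline quantity at these sizes (10
stacks per imaging target, 11 movies totalling 358 planted events, 10
ephys seeds).

# What passing does and does not show

The generator emulates the *statistical* structure the estimators rely on
— PSF-limited tubes over sub-threshold haze, Poisson × gain + read noise,
rectangular-support Ca²⁺ events, mono-exponential current kinetics — not
the full texture of real tissue: no neuropil autofluorescence, no
bleaching or drift, no vascular structures, no z-dependent attenuation,
and branch trees are statistically self-avoiding random walks rather than
real arbors. Recovery on these benchmarks demonstrates that the
implementations measure what they claim under the stated model; it does
not certify performance on degraded real acquisitions.

Known limitations: the frequency density printed in the source
("0.9 s⁻¹ µm⁻²") is dimensionally implausible for 10-minute recordings —
`frequency_density()` implements the stated definition
(events / (area × duration)) and the discrepancy is simply noted; primary
branch counts on dense arbors are recovered only approximately (entering
branches can merge optically near the soma); and the domain-area recovery
carries the ~10% segmentation-widening bias discussed above.
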
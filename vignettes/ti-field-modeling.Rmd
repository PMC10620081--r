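---
title: "Modeling temporal-interference stimulation fields and analyzing envelope recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling temporal-interference stimulation fields and analyzing envelope recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tistim)
```

## The method

Temporal-interference (TI) stimulation delivers two transcranial currents
at nearby kHz carrier frequencies $f_1$ and $f_2$ through two electrically
isolated electrode pairs. Each carrier alone is too fast to drive neural
firing; where the two fields overlap, the superposed field's amplitude
envelope beats at $\Delta f = f_1 - f_2$, and neural recruitment follows
the *envelope modulation amplitude* rather than the carrier amplitude.
Because the modulation amplitude is governed by the smaller of the two
local fields, the modulation peak can sit deep in the head — over a
structure like the hippocampus — while the overlying cortex, exposed to a
large but nearly unmodulated carrier, is spared. Changing the ratio of
the two pair currents at a fixed total steers the modulation peak toward
the pair carrying the smaller current.

`tistim` implements the full computational chain behind this idea, on
synthetic inputs that it also generates:

1. **Phantoms** (`make_layered_sphere_phantom`, `embed_target`,
   `parcellate_target`, `make_orientation_field`): a layered spherical
   head (scalp, compact skull, CSF, gray matter, white matter) with a
   curved tubular deep target split into anterior/middle/posterior
   thirds, plus a per-voxel unit orientation field $\mathbf n$
   representing the local principal structure direction.
2. **Conduction solve** (`build_conductivity_tensors`,
   `solve_electrode_pair`, `injected_current`, `normalize_to_current`):
   the electro-quasistatic, ohmic-current-dominated problem
   $\nabla \cdot \sigma \nabla \varphi = 0$ per electrode pair, with
   anisotropic tensors, Dirichlet contacts and insulating outer
   boundaries, normalized to a stated injected current.
3. **Exposure metrics** (`exposure_maps`, `steering_sweep`,
   `roi_summary`): the projected envelope-modulation amplitude
   $$|E_{\mathrm{AM}}(\mathbf n,\mathbf r)| =
     \big|\,|(\mathbf E_1+\mathbf E_2)\cdot\mathbf n| -
     |(\mathbf E_1-\mathbf E_2)\cdot\mathbf n|\,\big|
     = 2\min(|\mathbf E_1\cdot\mathbf n|,|\mathbf E_2\cdot\mathbf n|),$$
   the projected absolute amplitude
   $|\mathbf E_1\cdot\mathbf n| + |\mathbf E_2\cdot\mathbf n|$ (the beat
   cycle peak), current-ratio steering sweeps and ROI summaries.
4. **Recording analysis** (`bandpass`, `envelope`, `modulation_metrics`,
   `analyze_recording`, `depth_profile`, `interpolate_map`): the
   depth-electrode pipeline — first-order Butterworth bandpass,
   Hilbert-transform envelope with a low-pass smoother, epoch-wise
   modulation amplitude/ratio, per-electrode normalization, spatial
   derivatives along the shaft and interpolated 2D maps.

## The conduction model and its discretization

The quasistatic approximation treats tissue as a purely resistive medium
at kHz frequencies: displacement currents and wave propagation are
neglected, and the potential obeys
$\nabla\cdot\sigma\nabla\varphi = 0$ with $\pm V/2$ on the two contact
patches of the active pair and zero normal current elsewhere. Fields are
exactly linear in the drive, so each pair is solved once at 1 V, the
injected current is measured by integrating the normal current density
$\mathbf j = \sigma\mathbf E$ over a closed voxel surface enclosing one
contact, and the solution is rescaled to the target current (1 mA by
convention). Condition-specific maps are then pure scalings — the
pipeline never re-solves per condition.

The discretization uses trilinear (Q1) hexahedral elements on the voxel
grid: node potentials, one constant conductivity tensor per voxel, and
2×2×2 Gauss quadrature. On a regular grid this is equivalent to a
symmetric 27-point finite-difference stencil. We chose the element form
over face-flux stencils because it handles full anisotropic tensors
without special cross-term treatment, produces a symmetric
positive-definite system (so conjugate gradients apply directly), and is
free of the odd–even decoupling that cell-centered gradients invite.
Piecewise-linear slab potentials are represented exactly at any
resolution, which the analytic slab tests exploit.

Anisotropy follows the standard longitudinal/transverse decomposition:
$\sigma = \sigma_t I + (\sigma_\ell - \sigma_t)\,\mathbf n\mathbf n^T$,
giving eigenvalue $\sigma_\ell$ along the fiber direction and
$\sigma_t$ transverse to it. White matter is the anisotropic tissue by
default; everything else is isotropic.

**Electrode contacts.** Contacts are spherical-cap patches of
outer-surface scalp voxels with cap radius $\sqrt{A/\pi}$ for contact
area $A$ (default 2.25 cm², matching 1.5 cm × 1.5 cm pads; 3.14 cm²
mirrors a 2-cm-diameter circular contact). Dirichlet values are applied
on the nodes of the patch faces that look outward — the faces aligned
with the patch's outward direction — so the full scalp-to-scalp path
stays resistive; constraining all patch-cell nodes would artificially
shorten the conducting gap and was measurably wrong on the analytic cube.

**Solver.** Jacobi-preconditioned conjugate gradients with a relative
residual tolerance of 1e-8 (configurable) and an iteration cap; a sparse
Cholesky direct path (`method = "direct"`) is available. Cells not
reachable from the anode through conducting tissue are excluded, which
both guards against disconnected-domain singularities and drops floating
conductors.

## Geometry, parcellation and orientation defaults

The default phantom uses shell radii 80/74/70/66/60 mm with
conductivities 0.4, 0.008, 1.79, 0.28 and 0.13 S/m (scalp, compact
skull, CSF, gray, white), values taken from the head-conductivity
meta-analysis literature and exposed as configuration defaults, not
constants. The deep target is a 6-mm-radius tube along a three-point
curved ("banana") centerline in the left hemisphere, mirror-symmetric
about the coronal plane; its conductivity is gray matter's. The tube has
flat end caps (voxels overshooting the centerline ends axially are
excluded), so its voxel count tracks the analytic cylinder volume rather
than a capsule's.

Parcellation into Ant/Mid/Post uses arc-length thirds along the embedded
centerline, measured from the anterior (+y) end — a geometry-native
substitute for atlas-coordinate cuts, which require real anatomy.
Orientation mode `along_target_axis` assigns every brain voxel the
tangent of its nearest centerline point; inside the target this is the
local long-axis direction along which organized cell populations are
conventionally assumed to lie.

Electrode placement follows fractional-circumference rules on the
analytic sphere: on the left nasion-plane circle e1 and e3 sit at 50% of
the half-circumference ∓/± 2.5 cm (5 cm between centers); on a right
plane above the eyebrow e2 and e4 sit at 20% − 1 cm and 70% + 1 cm.
Pairs are (e1,e2) and (e3,e4). A mirror-symmetric variant
(`symmetric_rule_spec`) places both electrodes of each plane
symmetrically about the 50% position; steering validation uses it
because only there does the 1:1 ratio have a geometrically defined
midpoint answer. Placement is defined for spherical phantoms only —
centers are exact points on the analytic surface, so rule arithmetic
(e.g. the 5 cm / 16 cm separations at a 28 cm half-circumference) is
reproduced exactly rather than to voxel precision.

## Exposure metrics and steering

`exposure_maps` evaluates both metrics per oriented voxel from the two
1 mA solutions scaled by the condition currents $(I_1, I_2)$. The
absolute amplitude is defined as the beat-cycle peak of the summed
projected two-tone signal, $|p_1| + |p_2|$; this closed form is verified
in the tests against a numerically traced time-domain envelope, as is
the modulation amplitude identity. Both metrics are degree-1 homogeneous
in joint current scaling and invariant to swapping the pair labels.

ROI summaries report voxel count, median and s.d. (medians are the
primary statistic), with three normalization modes: none,
`to_target_median` (the target ROI then reads exactly 1) and
`fraction_of_subregion_sum` (subregion fractions sum to 1). Steering
sweeps recompute the map per current split and report subregion
fractions plus the eam-weighted centroid of the target along its long
axis. Peak lookups (`eam_peak`) break ties by the lowest linear voxel
index, deterministically; for peak-location questions the search is
restricted to brain voxels, since with both pairs sharing the left scalp
region the global envelope maximum legitimately sits near the scalp
between the adjacent electrodes.

## The recording pipeline and its conventions

The analysis chain is bandpass (0.5–5 kHz for TI, 1–40 Hz for
conventional tACS) → analytic-signal magnitude → first-order low-pass at
0.5 kHz → epoch statistics over 25 × 1 s epochs: modulation amplitude as
the mean half-difference between envelope maxima and minima, absolute
amplitude as the median of per-epoch signal maxima, and per-electrode
normalization to the largest contact value. Field estimates along the
shaft are finite differences of contact amplitudes over contact spacing
(mV/mm ≡ V/m); 2D maps apply a 3-point moving average along contacts
(shrinking to 2-point windows at the ends) before bilinear interpolation
onto a 100 × 151 grid, rows spanning the electrode-position axis and
columns the depth axis.

Design choices where conventions genuinely diverge:

* **Filtering** defaults to zero-phase (forward–reverse) application of
  the first-order Butterworth filters, which avoids phase-distorting the
  envelope; single-pass causal filtering is available via
  `zero_phase = FALSE`. Note that the zero-phase double pass squares the
  magnitude response, so a 2 kHz carrier in the 0.5–5 kHz band is
  attenuated ≈2.7% rather than ≈1.4%; amplitude-recovery checks on clean
  band-limited synthetics therefore apply `modulation_metrics` directly.
* **Modulation ratio** is the envelope depth
  $(\mathrm{env}_{\max}-\mathrm{env}_{\min})/\mathrm{env}_{\max}$, which
  reads ≈1 for equal two-tone contributions and ≈0 for an unmodulated
  tone — the only reading consistent with near-equal deep fields showing
  ratios near 90%. The literal half-difference reading, which saturates
  at 0.5, is available via `ratio_mode = "half_difference"`.
* **Edge transients**: the first and last 100 ms of each trace are
  excluded from epoch extrema.
* The ratio denominator uses the envelope maximum (numerically
  indistinguishable from the filtered-signal sample maximum for these
  signals).

A factor-of-two convention difference is inherent and documented rather
than hidden: the field-side metric $|E_{\mathrm{AM}}|$ equals the
envelope max − min (i.e. $2\min$), while the recording-side modulation
amplitude is the *half*-difference (i.e. $\min$). Cross-module
comparisons must multiply the recording metric by 2 (or halve the field
metric); tests state which convention they use.

## What the synthetic generators emulate — and what they do not

The recording generator produces exactly the signal model the analysis
assumes: two stationary sinusoids with contact-specific amplitudes plus
additive white Gaussian noise, sampled at 30 kS/s. Default contact
profiles make pair 1 decay with depth and pair 2 contribute a deep bump
plus a small far-field floor, so the shallow contacts show a low
modulation ratio (~0.1) and the deepest contacts a ratio near 1 —
qualitatively the pattern measured across a real depth electrode. Real
recordings additionally contain drift, impulse artifacts, amplifier
nonlinearity and non-stationary coupling; passing the recovery tests
shows the estimator chain is correct and noise-stable, not that it is
robust to those artifacts.

The spherical phantom likewise preserves the topology (layered
conductor, deep bilateral-free target, curved geometry) but none of the
anatomy — no skull inhomogeneity, no CSF folds, no gyration. All
anatomy-dependent published field values are treated as qualitative
expectations (orderings, monotonicities), never asserted equalities. The
target-vs-cortex contrast (deep target receives more envelope
modulation; superficial cortex more absolute field) emerges from the
default geometry rather than being imposed.

## Numerical choices and problem sizes

* Default grid resolution is 4 mm (a 44³ grid for the 80 mm head), the
  size at which the full two-montage study — four pair solves plus
  exposure, steering and recording analysis — completes in well under a
  minute; the solver itself has been exercised to 64³ in the slab
  validations. Resolution is a config knob; at 4 mm the thinnest shell
  (skull, 4 mm) remains 6-connectivity closed because a voxel-center
  radius cannot cross a 4 mm shell in a single 4 mm step.
* PCG tolerance 1e-8, iteration cap 20 000. Typical head solves converge
  in ~200 iterations.
* Current integration uses the electrode patch bounding box grown by 3
  voxels; faces into non-conducting space are strictly insulating.
* The centerline is resampled at half the voxel size; nearest-point
  queries loop over centerline points vectorized across voxels.
* Degenerate inputs error early: empty patches, disconnected domains,
  non-unit orientations (beyond 1e-6), aliased sampling rates, epochs
  longer than the trace.

## Known limitations

* No capacitive/displacement currents and no frequency-dependent
  conductivity — the quasistatic, ohmic-dominated regime is assumed, not
  checked against tissue dispersion data.
* Electrode placement rules require the analytic spherical geometry;
  arbitrary phantoms need explicit electrode coordinates.
* The voxel staircase limits contact-geometry fidelity; contact area is
  matched only to within the surface-voxel quantization.
* The orientation-free "maximal over directions" modulation metric is
  not implemented; all exposure is along the supplied orientation field.
* Conductivities, geometry and noise levels are defaults to be
  overridden, not measurements.
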
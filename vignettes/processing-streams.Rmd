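---
title: "Processing streams for infant fNIRS image reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing streams for infant fNIRS image reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotstream)
```

## The question the package addresses

Group-level infant fNIRS studies are usually analysed in *channel space*:
statistics are computed per source-detector channel across subjects, which
implicitly assumes every infant has the same head size and the same array
position. Diffuse optical image reconstruction can instead place each
subject's data on a cortical surface using that subject's own head
measurements and measured array placement. `dotstream` implements five
processing streams spanning the two extremes and the two intermediate
cases, so that the *effect* of the channel-space assumptions can be
quantified:

| stream | head warp | array placement |
|---|---|---|
| `subject_parameter` | subject-specific | subject-specific |
| `constant_head_warp` | group mean | subject-specific |
| `constant_array_position` | subject-specific | group mean |
| `constant_parameter` | group mean | group mean |
| `channel_space` | group mean (projection only) | group mean |

The comparison metrics (peak node offset in a common reference space,
cortical-label match, Jaccard overlap of thresholded maps, focality
curves, per-region |T| maxima, and the combinatorial group-size analysis)
quantify how far inferences move when subject-specific geometry is
replaced by group averages.

## Head model and warping

The head model is a four-layer mesh (white matter, grey matter, CSF, and a
combined scalp+skull extra-cerebral layer) with a grey-matter surface mesh,
five cranial landmarks (Nz, Iz, Al, Ar, Cz) and a parcel label per
grey-matter surface node. The landmark coordinate frame puts Iz at the
origin, Nz on the positive y-axis, and equalizes the z-coordinates of the
preauricular points by a final rotation about y.

Warping is driven by three tape measurements — head circumference,
Ar-Cz-Al, and Nz-Cz-Iz (absent at the 5-month visit) — via axis-subset
scaling: a global scale by the circumference ratio, then repeatedly
re-measure, pick the measurement with the greatest absolute error, and
scale its axis subset (x,z for Ar-Cz-Al; y,z for Nz-Cz-Iz; x,y,z for
circumference) by target/measured. Iteration stops when residuals fall
below 6 mm (Ar-Cz-Al), 6 mm (Nz-Cz-Iz) and 3 mm (circumference). The
tolerances are deliberate: exact fitting of three scalar measurements by
anisotropic scaling over-fits measurement error and produces implausible
head shapes. A convergence guard of 50 iterations errors out with the
final residuals. Because warping only moves coordinates, node count,
ordering, mesh topology and parcel labels are preserved, giving the
one-to-one nodal correspondence the cross-stream offsets rely on. When the
Nz-Cz-Iz target is absent, the y-axis is constrained only through
circumference steps.

**Curve walks.** Scalp distances and 10-5 positions need paths *along* the
scalp. The package realizes a curve walk as the planar-section trace: the
cutting plane contains the two endpoints and a third reference point (Cz
for the sagittal and coronal curves, the preauricular point for the
lateral Iz-FPz curve, the head centre for placement bands). The section of
a closed triangulated surface with a plane is a closed polygon computed
exactly from edge crossings; the returned path is the arc passing nearest
a guide point. This is testable against analytic geodesics: on sphere
phantoms the arc length converges to the great-circle length as the mesh
refines (about 0.04% error at the default resolution). The circumference
is measured in the plane through Nz and Iz parallel to the Al-Ar axis —
on the symmetric phantom this is the natural axial circumference plane
through all four lateral landmarks.

**Units.** Meshes are stored in mm. Head measurements cross the API in cm
and are converted once at the boundary.

## Array registration

The bilateral array has 6 sources and 7 detectors per hemisphere in two
rows with 20 mm nearest-neighbour spacing, 17 channels per hemisphere (34
in total; this is the Bonferroni denominator for channel statistics). The
reference optode is the third lower optode from the posterior, intended to
sit over the tragus.

Registration uses two scalp axes per hemisphere: an x-curve from Iz to FPz
along the lateral side of the head and a y-curve from the preauricular
point to CCPz. Measured x/y displacements of the reference optode
(anterior/superior positive) are applied as *arc lengths* along these
axes; the rest of the array is laid out at 20 mm arc steps along a scalp
band through the reference point, with the upper row on a parallel band
offset 20 mm superiorly. Geodesic (arc) spacing rather than chord spacing
is enforced because the physical array follows the scalp.

Placement rules: |x| >= 1.6 cm shifts the whole array one full channel
space (20 mm) opposing the displacement sign; |y| > 1.6 cm excludes the
subject (the boundary itself, 1.6 cm, shifts but does not exclude). The
exclusion tests |y| by default with a `y_rule = "superior"` switch, since
the direction convention for exclusion is ambiguous in the field; the
re-indexing is implemented as a physical 20 mm shift of the optodes.

## Channel preprocessing

The pipeline is: prune, optical density, motion correction, residual-trial
flagging, band-pass, Beer-Lambert, block average.

* **Pruning** drops channels below an intensity floor at either wavelength
  (immediately, regardless of cardiac content) or with a cardiac coupling
  index below 0.75. The index is the zero-lag correlation of the two
  wavelengths band-passed to 0.5-2.5 Hz: a genuinely coupled optode pair
  carries the same pulse waveform at both wavelengths. Datasets with more
  than 40% invalid channels are excluded entirely.
* **Optical density** uses the channel temporal mean as reference, so OD
  is invariant to constant intensity scaling (and so is everything
  downstream).
* **Motion correction** is two-stage: detected artifact segments (samples
  deviating from a running median beyond both a robust 8-MAD threshold and
  an absolute 0.02-OD amplitude floor, with a derivative criterion for
  plateau artifacts) are spline-detrended; then a Haar discrete wavelet
  decomposition zeroes detail coefficients outside the 1.5-IQR fences,
  subject to an absolute 0.005-OD detail floor. The absolute floors matter:
  purely relative (MAD- or IQR-based) thresholds misclassify smooth
  haemodynamic structure as artifact on low-noise data. Clean signals pass
  through within 5% RMS; an isolated 10x spike is attenuated by more than
  half of its RMS error.
* **Residual trials**: any trial whose -2..20 s block overlaps a residual
  artifact padded by 4 s on each side is excluded, per channel.
* **Band-pass**: zero-phase (forward-backward) 3rd-order Butterworth,
  0.02-0.06 Hz. The mean is removed before filtering to avoid start-up
  transients.
* **DPF** follows the published general equation (cubic in wavelength,
  power law in age), valid for 690-880 nm; extinction coefficients at
  780/850 nm are packaged from the standard compilation
  (`inst/extdata/extinction_hb.csv`).
* **Block averaging** keeps trials with looking fraction >= 0.60; a
  subject needs at least three valid trials for the condition. The block
  runs -2..20 s at 10 Hz: 221 frames, 22 s.

For reconstruction, block-averaged haemoglobin is converted *back* to
per-wavelength optical density with the forward Beer-Lambert law; the
round trip is the identity to 1e-9.

## Sensitivity model and reconstruction

The default forward engine is an analytic diffusion-approximation
Green's-function product in Rytov form: the sensitivity of a channel's OD
to an absorption change at node r is G(s,r) G(r,d) / G(s,d), scaled by
nodal volume. Each channel uses a locally planar boundary through the
optode pair (outward normal from the head centre) with sources at depth
1/musp' and an image source enforcing the extrapolated-boundary condition;
an `infinite` boundary option provides the translation-invariant model
used in tests. Homogeneous optical properties per wavelength are packaged
as a CSV. This engine is a pluggable default — the surface contract
(`compute_sensitivity` returning per-wavelength channel-by-node matrices)
admits a finite-element solver without touching the rest of the pipeline.
The engine reproduces the expected banana-shaped sensitivity: reciprocal
in source/detector, concentrated between the optodes at roughly half the
separation in depth, decaying off-axis.

Reconstruction is zeroth-order Tikhonov in the underdetermined form
x = J'(JJ' + lambda^2 max(diag(JJ')) I)^-1 y with lambda = 0.1, restricted
to grey-matter volume nodes (the array has no overlapping channels, so no
depth discrimination is attempted). The regularization scale factor
max(diag(JJ')) is the common convention in diffuse optical tomography when
only a bare hyperparameter is quoted. The operator is factored once per
subject and applied to all 221 frames. Absorption changes at the two
wavelengths are converted to HbO/HbR by the per-node 2x2 extinction solve,
and mapped to the grey-matter surface by nearest grey-matter volume node
within 3 mm (falling back to the unconditional nearest node, which guards
the coarse phantom lattices used in testing; MRI-derived meshes are far
denser than the mapping radius).

Masking: the individual grey-matter mask keeps surface nodes whose
aggregate sensitivity (column sums of |J| at 780 nm) reaches 1% of its
maximum; the group mask keeps nodes present in at least three quarters of
individual masks (boundary inclusive).

## Statistics

Group maps concatenate, per node (or channel), all response-window frames
(12-16 s) across subjects into one vector and all baseline frames
(-2..0 s) into another, compared by a two-tailed two-sample t-test (pooled
variance by default; a Welch switch is provided). Bonferroni correction
uses the full grey-matter surface node count for images and the full
channel count (34) for channel space. A channel enters the group analysis
only if present (not pruned) in at least three quarters of subjects.

This statistic deserves a caveat stated plainly: consecutive frames within
a window are strongly autocorrelated, so treating them as independent
observations overstates the effective sample size and the resulting t
values should not be read as calibrated significance tests. The package
implements the convention faithfully rather than correcting it, because
its purpose is to compare *streams* under identical statistical
machinery; zero-variance nodes are reported as undefined (never
significant) rather than infinite.

Channel positions are compared with images by cortical projection: scalp
nodes within 5 mm of the channel's scalp midpoint define a least-squares
plane, and a ray along the plane normal (inward direction chosen as the
one that actually hits the cortex, which makes the result independent of
mesh orientation) is intersected with the grey-matter surface using the
Moller-Trumbore algorithm. On concentric-sphere phantoms the projection is
radial and its depth equals the shell gap. The common half-separation
depth heuristic is documentation, not part of the computation. The 5 mm
plane-fit radius assumes MRI-density scalp meshes; `run_stream` widens it
to 1.6 median edge lengths on coarser meshes.

## Synthetic data: what it emulates, and what it does not

Because the cohort data the design emulates are access-controlled, the
package generates everything it consumes.

* **Phantom**: concentric four-layer ellipsoid (default outer semi-axes
  65 x 80 x 60 mm, ECT 7 mm, CSF 2 mm, GM 4 mm), built directly in the
  landmark frame with landmarks as exact mesh vertices; a cube lattice
  split into six tetrahedra per cell forms the volume mesh; grey-matter
  parcels are equal-area longitude sectors.
* **Cohort**: head measurements normal around age-cohort means
  (circumference 42.6/44.6/46.2 cm at 5/8/12 months, SD 1.3 cm; the other
  two measures phantom-proportional at 0.429 and 0.484 of circumference so
  warp targets stay shaped like the phantom; Nz-Cz-Iz absent at 5 months);
  placement displacements zero-mean normal with SD 0.7 cm (x) and 0.8 cm
  (y), which makes the >1.6 cm exclusion fire for a small percentage of
  subjects, mirroring the exclusion cascade qualitatively.
* **Scan**: a focal cortical response (difference-of-gammas peaking at
  14 s, inside the 12-16 s window; peak HbO 2 uM with HbR at -0.33 of it —
  a moderately strong infant response) forward-projected through the
  subject's own warped-mesh sensitivity to channel OD, converted to
  intensity around lognormal channel baselines, plus shared-phase cardiac
  oscillation (4e-3 OD at 2.2 Hz, the carrier that makes channels pass the
  coupling check), linear drift, white noise (1e-3 OD), Poisson-timed
  exponential-decay motion spikes (0.05 OD, one per minute), per-trial
  Beta(8, 1.5) looking fractions, and a 6% rate of dead or decoupled
  channels. The stimulus schedule cycles VS, NV, V, VS, V, NV.

What passing tests on this generator do **not** show: the phantom is an
idealized smooth ellipsoid, so anatomical effects (folding, heterogeneous
optics, skull thickness variation) are absent; noise is stationary and
Gaussian apart from spikes; and the response is a single focal patch. The
pipeline's quantitative error bounds on real infant data will be worse;
the *ordering* results (below) exercise the geometry machinery that
drives them and are expected to transfer.

## Problem sizes and numerical choices

Default test and acceptance runs use a 33 x 48 surface grid (about 1500
vertices per surface), a 6 mm volume lattice (about 6000 nodes, 30000
tetrahedra) and cohorts of 16 subjects; the acceptance script's mechanism
cohort uses 40 subjects, matching the smallest of the study's age-cohort
sample sizes, with 100 combinatorial replicates per group size. These
sizes keep a full five-stream run in minutes on one core while leaving
the grey-matter node spacing (about 8 mm) small relative to the offsets
being measured. Ties in peak extraction break to the lowest node id;
per-size combinatorial seeds derive deterministically from the master
seed; Green's functions clip distances below 0.5 mm; degenerate inputs
(zero-variance t, empty masks, all-zero sensitivity rows) raise errors or
flagged NA values rather than silently propagating.

## What the pipeline reproduces

On synthetic cohorts with the default variability, the package reproduces
the mechanism the stream comparison was designed to expose, computed from
scratch by `scripts/acceptance.R` and the acceptance tests:

* a noiseless subject's group activation peak lands on the planted
  grey-matter node (offset 0 mm, bound 15 mm);
* individual-level mean peak node offsets order as constant-head-warp
  << constant-array-position ≈ constant-parameter: within-cohort head-size
  variability barely moves cortical inferences, while array-placement
  variability dominates;
* the combinatorial analysis shows the mean subject-parameter vs
  constant-parameter group peak offset shrinking as group size grows
  (negative Spearman rank correlation), i.e. group-level channel-space
  analyses become robust to these variability parameters at realistic
  cohort sizes — small cohorts are where the assumptions bite.

## Known limitations

* The analytic homogeneous forward model ignores tissue heterogeneity;
  swapping in a finite-element solver changes absolute sensitivities but
  none of the surrounding machinery.
* The curve-walk is a planar-section stand-in for mesh-crawling
  implementations; on smooth head-like surfaces the two agree to within
  mesh resolution, but on highly folded surfaces a planar section is not a
  geodesic.
* The concatenated-frames t statistic inherits the autocorrelation caveat
  above.
* WHO growth-standard z-scores are inputs (`headsize_associations` takes
  them precomputed); no growth-reference tables ship with the package.
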
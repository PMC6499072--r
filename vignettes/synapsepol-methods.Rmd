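---
title: "synapsepol: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{synapsepol: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapsepol)
```

## The measurement problem

A T lymphocyte that recognizes antigen on an antigen-presenting cell (APC)
builds an immunological synapse (IS): the microtubule-organizing center
(MTOC) and CD63⁺ multivesicular bodies (MVB) move toward the contact, and
cortical F-actin first accumulates at the synapse and then clears from its
center (the cIS), licensing secretion. `synapsepol` quantifies these events
from multi-channel fluorescence images. Because raw microscopy from such
experiments is rarely shareable, the package also carries a synthetic-scene
generator with exact ground truth, so each estimator can be validated by
parameter recovery rather than by eye.

## The polarization index

For each conjugate we take the cell's center of mass cellᶜ (unweighted over
the binary T-cell mask), the IS centroid (centroid of the contact segment),
and an organelle center of mass (intensity-weighted over detected punctum
pixels). With `u` the unit vector from cellᶜ toward the IS centroid,

- `B = ‖IS − cellᶜ‖` (µm),
- `A = (organelleᶜ − cellᶜ) · u` (µm, negative away from the synapse),
- `Pol. Index = A / B`, clamped to [−1, +1].

Division by `B` normalizes for cell size and shape, so the statistic is
invariant under uniform scaling of all coordinates (a property test).
Conjugates with index strictly greater than the 0.25 cutoff are scored
*polarized*; cohort polarization is the percentage of polarized conjugates.
The raw (unclamped) ratio is kept in the result for diagnostics.

Two conventions deserve comment:

- **Choice of axis.** The projection axis runs through the IS *centroid*.
  An alternative — the axis through the contact pixel nearest to cellᶜ — is
  exposed as `axis = "nearest_contact"` but not endorsed: the centroid
  variant is stable under contact-segment jitter, while the nearest-point
  variant can jump between contact pixels frame to frame.
- **Center-of-mass weighting.** The organelle centroid is
  intensity-weighted (a vesicle cloud's mass is its fluorescence); the cell
  centroid is unweighted (the normalization is geometric, by cell shape).

## Actin reorganization kinetics

Three nested floating ROIs are recomputed from each frame's segmentation:
the cell mask; the IS band, all cell pixels within `band_depth_um`
(default 1.5 µm) of the contact segment; and the cIS band, the IS-band
pixels whose nearest contact pixel lies on the central fraction
(default 0.5) of the contact arc. Frames whose segmentation fails inherit
the nearest segmented frame's masks and are flagged; more than 20% failures
abort with `unstable_conjugate`.

The tracked statistics are the framewise mean-FI ratios `IS/cell` and
`cIS/IS`. The reorganization interval is the *longest contiguous run* of
frames with `IS/cell > 1 + δ` (δ = 0.05 by default; the bare ">1" rule
fragments under shot noise), times the frame interval; the depletion
interval is the analogous run with `cIS/IS < 1 − δ`. Peak time and maximum
ratio are taken inside the winning run. A series that never exceeds the
band returns duration 0 with the global maximum — not an error.

Sensor kinetics (`sensor_fi_ratio`) normalize a cell-ROI FI series by its
value at a baseline time point (conventionally t = 30 min). Residence
half-life is the time from the FI peak until the trace first falls to
`baseline + 0.5 × (peak − baseline)`, with the final frame as baseline and
linear interpolation between frames; traces that never fall that far return
the post-peak observation span with `censored = TRUE`.

## Face-on interface geometry

From a z-stack, the IS normal is estimated in 3D (z rescaled by
`z_step / pixel_size` so distances are isotropic), and a slab of
`slab_depth_um` (default 1.5 µm) centered on the contact plane is resliced
perpendicular to that normal with trilinear interpolation and
maximum-projected. On the face-on view:

- the IS region is delimited by the outer edge of the F-actin (dSMAC)
  signal: Otsu threshold, largest component, morphological closing
  (radius 2 px), hole filling;
- the F-actin-low region is the largest contiguous region darker than
  `rim_fraction` (default 0.5) times the median intensity of the dSMAC rim
  (the outer 20% of the region's equivalent radius, at least 2 px), whose
  centroid lies within half the equivalent radius of the region centroid —
  the "central" constraint keeps peripheral gaps from scoring as cIS
  depletion;
- `area_ratio = Fact-low area / IS area`; ratios strictly above 0.1 score
  *depleted*.

The ratio is invariant to uniform intensity scaling and, being
area-normalized, approximately invariant to resampling (discretization
error ≲ 5% at rim radii ≥ 20 px).

## Colocalization and tracking

Fluorogram colocalization is the plain Pearson product-moment correlation
over masked pixel pairs; zero variance in either channel raises
`undefined_correlation` rather than returning NaN. Tracking is greedy
mutual-nearest-neighbor linking between consecutive frames — deterministic,
appropriate for the sparse-spot regime of vesicle videos — with links
capped at `max_link_px` and tracks shorter than `min_track_len` discarded.
Speeds are step displacements converted by the pixel size and frame
interval; both per-track means and the step-pooled mean are reported, since
cohort-level speed summaries are ambiguous between the two.

## The synthetic-scene generator

The forward model renders, per channel: a uniform cytosolic APC dye; a
T-cell actin channel (cytosol + bright cortical band); an organelle channel
of Gaussian puncta; and a single MTOC punctum near the organelle-cloud
centroid. Geometry is analytic — two discs/spheres flattened against a
shared contact plane, with the plane at 0.6 of the body radius from the
cell center so the contact facet is 0.8 of the cell radius: at a formed
synapse the T cell spreads onto the APC and the contact is near its widest
section. Optics and camera follow the standard fluorescence model: Gaussian
PSF blur (σ default 0.2 µm, widefield-like), Poisson shot noise
(`poisson_scale` photons per intensity unit, default 50, i.e. SNR ≈ 7 at
unit signal), then additive Gaussian read noise (sd 0.01).

Placement of the organelle cloud is exact by construction: puncta are
sampled around the target centroid, snapped into the cell mask, and
iteratively recentred until the realized intensity-weighted centroid
reproduces the requested polarization index (residual < 0.05 px). Ground
truth — masks, contact pixels, centroids, per-frame ratio profiles, track
positions — is recorded before blur and noise.

Time-lapse scenes hold the actin channel uniform over the cell (ratio
baseline exactly 1), multiply the IS band by `burst_amplitude` during the
burst interval, and multiply the cIS band by `1 − clearance_ratio` during
the clearance interval. **The clearance interval defaults to the interval
immediately following the burst**: cortical accumulation at the IS precedes
central clearance, and a clearance overlapping the burst would partially
cancel the very IS/cell elevation the burst is meant to produce. True
per-frame ratios are measured on the noise-free render with the
ground-truth ROIs, so "truth" and estimator share the ratio definition but
nothing else.

Z-stack scenes emulate **fixed phalloidin-like F-actin staining** (the
modality behind face-on depletion measurements): cytosolic signal is low
(0.08 of cortical intensity — phalloidin binds filamentous, not monomeric,
actin), the contact carries a 0.5 µm bright band, and the cleared center
drops to cytosol level over a disc whose projected area fraction equals
`true_depletion_ratio`. Depletion-assay fixtures in the tests use
σ(PSF) = 0.1 µm, confocal-like, as en-face analyses are performed on
confocal stacks; widefield time-lapse fixtures keep 0.2 µm.

Vesicle videos run at `frame_interval_s` (default 1 s) — vesicle tracking
is acquired at frame rates far faster than the minutes-scale synapse
kinetics — with constant-speed drift toward the synapse plus optional
diffusion; spots are kept inside the cell, and a spot clipped at the
boundary records its own (slower) true speed in the sidecar.

**What the generator does not emulate:** vectorial/asymmetric PSFs,
photobleaching, stage drift, multi-conjugate crowding, organelle motion
during z-acquisition, and autofluorescence. A green recovery test therefore
establishes that the estimators are correct for well-formed single
conjugates under Poisson–Gaussian noise — not that they are robust to every
real-world artifact.

## Numerical choices

- **Segmentation thresholds.** The APC channel is bimodal and uses 2-class
  Otsu. The T-cell channel is tri-modal during a cortical burst
  (background / cytosol / bright band), where 2-class Otsu can latch onto
  the cytosol–band split and reduce the "cell" to the band; the package
  therefore computes a 3-class Otsu decomposition and thresholds halfway
  between the background and cytosol class means. Both rules are invariant
  to uniform intensity scaling.
- **Connectivity** is 8 (2D) / 26 (3D) throughout; contact adjacency radius
  1 px; components are labelled in raster order, so every tie-break is
  deterministic (the MTOC tie-break picks the blob whose first pixel comes
  first in raster order).
- **Degenerate inputs** raise classed conditions (`no_cell`,
  `no_conjugate`, `no_organelles`, `degenerate_geometry`,
  `undefined_correlation`, `empty_cohort`, ...) rather than returning
  sentinel values; the pipeline downgrades per-scene errors to logged
  warnings so one bad conjugate does not kill a batch.
- **Determinism.** A scene spec's seed reproduces the scene bit for bit;
  `run_pipeline` derives per-scene seeds from the run seed, and identical
  config + seed yields byte-identical CSVs.

## Known limitations

- PSF blur dilutes the measured IS band mean, so the recovered maximum
  IS/cell ratio is biased low by up to ~9% at burst amplitude 3 under the
  default optics (duration recovery is unaffected). The bias is physics,
  not estimator error, and sits inside the 10% recovery tolerance the
  tests enforce.
- The en-face max-projection picks up some cortical shell behind the
  contact plane, inflating the delimited IS area relative to the true facet
  projection; the area *ratio* partially cancels this but retains a
  downward bias of roughly a quarter at small depletion fractions. The
  depleted/not-depleted call at the 0.1 cutoff is stable across seeds for
  the tested depletion fractions {0, 0.15, 0.3}.
- The baseline TIFF codec reads only what it writes (little-endian,
  uncompressed, single-strip grayscale); it is an exchange format for this
  package's fixtures, not a general TIFF reader.
- `residence_half_life` assumes a single dominant peak; multi-peak traces
  take the global maximum.
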
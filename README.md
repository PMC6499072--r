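# synapsepol

Quantification of polarized secretory traffic at the immunological synapse
(IS) from multi-channel fluorescence microscopy.

When a T lymphocyte conjugates with an antigen-presenting cell (APC), its
secretory machinery — CD63⁺ multivesicular bodies (MVB) and the
microtubule-organizing center (MTOC) — reorients toward the contact, while
cortical F-actin transiently accumulates at the synapse and then clears from
its center. `synapsepol` turns images of this process into numbers:

- **Conjugate segmentation** — T-cell and APC masks (Otsu thresholding +
  largest component), the contact (IS) segment, organelle puncta
  (difference-of-Gaussians + robust threshold) and the MTOC.
- **Polarization index** — the signed, size-normalized statistic
  `Pol. Index = A / B`, where `B` is the distance from the cell's center of
  mass (cellᶜ) to the IS centroid and `A` is the scalar projection of the
  organelle center-of-mass displacement onto that axis (negative away from
  the synapse). The index ranges from +1 to −1; conjugates with index
  > 0.25 are scored *polarized*, and cohort polarization percentages follow.
- **Actin kinetics** — per-frame mean-FI ratios `IS FI / cell FI` and
  `cIS FI / IS FI` from floating ROIs (re-segmented every frame); the
  reorganization interval (longest run with IS/cell ratio > 1), its peak
  ratio, the central-depletion interval, sensor FI ratios against a baseline
  time point, and residence half-life of membrane reporters.
- **Face-on interface geometry** — en-face reslice of a z-stack along the
  IS normal, IS area delimited by the dSMAC F-actin edge, and the
  F-actin-low central area ratio (`Fact-low cIS area / IS area`; > 0.1
  scores *depleted*).
- **Colocalization and tracking** — Pearson fluorogram correlation within
  masks, greedy mutual-nearest-neighbor vesicle tracking, speeds in µm/s.
- **Synthetic scene generator** — conjugate scenes (2D, z-stack,
  time-lapse) with Gaussian PSF, Poisson + Gaussian camera noise and
  machine-readable ground truth, so every measurement is testable by
  parameter recovery.

## Worked example

```r
library(synapsepol)

spec <- scene_spec(seed = 7, true_pol_index = 0.6)   # ground truth: 0.6
sim  <- generate_conjugate_scene(spec)

geom <- segment_conjugate(sim$scene)
mvb  <- detect_organelles(sim$scene, geom)
pol  <- polarization_index(geom, mvb$centroid, organelle = "MVB")
cat(sprintf("A = %.2f um, B = %.2f um, Pol. Index = %.3f, polarized: %s\n",
            pol$A * spec$pixel_size, pol$B * spec$pixel_size,
            pol$pol_index, pol$polarized))
#> A = 2.22 um, B = 3.55 um, Pol. Index = 0.626, polarized: TRUE

mt <- detect_mtoc(sim$scene, geom)
polarization_index(geom, mt$centroid, "MTOC")$pol_index
#> 0.710
```

The MVB cloud was generated at a true polarization index of 0.6; full
segmentation + detection recovers 0.626 (errors of a few hundredths are
typical at the default SNR ≈ 7). The MTOC sits close to the MVB centroid by
construction, so its index is similar — mirroring the tight MVB/MTOC
coupling seen in real conjugates.

Batch processing from a YAML config (see `validate_config()` for every key
and default):

```r
run_pipeline(list(n_scenes = 60, seed = 1, out_dir = "out"))
# writes out/scenes.csv, out/cohort.csv, out/manifest.json, out/run.log
```

or from the shell:

```sh
Rscript inst/cli/synapsepol.R cohort --config run.yaml --seed 1 --out out
```

## File formats

Scenes are written as multi-page grayscale TIFF (axes TZCYX, float32) with
a `<name>.truth.json` ground-truth sidecar (0-based pixel coordinates,
calibration recorded separately) and a `<name>.labels.tif` label raster
(1 = T cell, 2 = APC). A minimal baseline TIFF codec is built in; no
external imaging library is required.
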
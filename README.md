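# mccquant

Single-cell quantification of punctate plasma-membrane microdomains
(MCC/eisosomes) in fluorescence micrographs of budding yeast, plus the
sphingolipidomics post-processing that typically accompanies such studies —
implemented as a reproducible, fully tested R pipeline with a ground-truthed
synthetic-data generator.

## Who this is for

Groups imaging yeast membrane compartments (Nce102, Pil1, Slm1, Sur7 and
similar markers) in equatorial confocal cross-sections, who need per-cell,
per-replicate quantities rather than hand-curated ImageJ measurements:

- **patch count / density** along the membrane of each cell,
- **patch prominence** — the peak/valley intensity ratio of the membrane
  line profile,
- **PM/interior intensity ratio** and region-wise mean/integrated
  intensities,
- **Pearson colocalization** of two markers with integer-pixel shift
  correction,
- **patch-density decay** over a time lapse with half-decay-time estimation,
- **dye-uptake ratio** (interior / whole-cell integrated intensity,
  e.g. FM4-64),
- **lipidomics tables**: inorganic-phosphate (Pi) normalization, class
  pooling, log2 fold changes vs matched controls, PCA with per-lipid
  contributions, and protein–lipid Pearson correlation with the `mu_r`
  summary.

## The model in brief

Each segmented cell (integer-label mask, e.g. from Cellpose; the mask edge
bisects the membrane ring) is approximated by a moment-fitted ellipse.
A band of width *w* (default 0.4 µm) centred on the ellipse boundary is the
plasma-membrane region; the ellipse shrunk by *w*/2 is the interior; their
union is the whole cell, so PM + interior integrals equal the whole-cell
integral exactly. The membrane intensity profile *I*(θ) is sampled at 360
parametric angles by radial averaging across the band. Patches are local
maxima of the smoothed profile with topographic prominence ≥ 0.10 × median
(a relative threshold, so detection is invariant to intensity rescaling)
and ≥ 4° apart; prominence is mean(peaks)/mean(valleys); density is
count / Ramanujan perimeter. Statistics follow the hierarchical convention:
cells → replicate means → condition mean ± SD, with one-way/two-way ANOVA
and paired *t* tests on replicate means (the replicate, never the cell, is
*n*).

Because raw data of this kind are rarely deposited, the package ships a
generator (`generate_field()`, `generate_timelapse()`,
`generate_coloc_pair()`, `generate_uptake_field()`,
`generate_lipid_dataset()`) that renders elliptical cells with controlled
patch count, contrast, decay half-life, channel overlap, uptake fraction
and lipid class effects — every quantity the pipeline measures is validated
against the value it was constructed from.

## Worked example

```r
library(mccquant)

sim <- generate_field(field_params(n_cells = 6, patch_contrast = 2, seed = 42))
m <- quantify_field(sim$field, sim$mask)
m[, c("label", "area_px", "perimeter_um", "pm_interior_ratio",
      "patch_count", "patch_density_per_um", "prominence")]
```

```
 label area_px perimeter_um pm_interior_ratio patch_count patch_density_per_um prominence
     1    2002       15.861             3.438           7                0.441      1.904
     2    1553       13.996             3.267           5                0.357      1.938
     3    1502       13.777             2.967           2                0.145      1.966
     4    2050       16.051             3.194           4                0.249      1.896
     5    1364       13.427             3.525           8                0.596      1.882
     6    1316       12.868             3.185           4                0.311      1.923
```

The generator placed 7, 5, 2, 4, 8 and 4 patches on these six cells
(`sim$truth$true_patch_count`) with a true contrast of 2 and a true
PM/interior ratio of 3: counts are recovered exactly here, prominence within
a few percent (smoothing attenuates the narrow peaks slightly), and the
ratio within ~10% (patches raise the band mean above the ring baseline).

Half-decay of patch density from a synthetic time lapse (true half-life
80 min, 25 cells/frame, frames every 10 min for 2 h):

```r
tl <- generate_timelapse(field_params(n_cells = 25, seed = 7),
                         n_frames = 13, frame_interval_min = 10,
                         half_life_min = 80)
ms <- lapply(1:13, function(j) quantify_field(tl$field, tl$mask, frame = j))
curve <- patch_density_timeseries(ms, times_min = tl$field$times_min)
half_decay_time(curve, "crossing")  # 90.0 min
half_decay_time(curve, "expfit")    # 81.0 min
```

## Command line

Every stage is scriptable via `inst/cli/mccquant.R`
(`Rscript inst/cli/mccquant.R <subcommand> --key value ...`):
`simulate`, `quantify`, `coloc`, `kinetics`, `lipids`, `report`.
Images move as TIFF, tables as CSV, configs/metadata as JSON; outputs are
byte-identical across repeated runs at a fixed seed.

## Documentation

`vignettes/mccquant-methods.Rmd` describes the measurement model, the
synthetic world and its deliberate simplifications, all tunable parameters
with units and defaults, and the numerical conventions (quartile type,
tie-breaks, zero handling).
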
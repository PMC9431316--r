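---
title: "Quantifying plasma-membrane microdomains: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plasma-membrane microdomains: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mccquant)
```

# Scope

`mccquant` measures, per segmented cell in an equatorial fluorescence
cross-section of budding yeast: region intensities (whole cell, plasma
membrane, interior), the PM/interior ratio, the circular membrane intensity
profile with patch (peak) count, density and prominence, two-channel
Pearson colocalization after integer-pixel registration, patch-density
decay over time lapses with half-decay estimation, and dye-uptake ratios.
A second arm post-processes sphingolipid amount tables: Pi normalization,
class pooling, log2 fold changes, PCA with per-lipid contributions, and
protein–lipid correlation. A synthetic-data generator provides ground truth
for every one of these readouts.

Upstream steps are deliberately out of scope: segmentation itself (label
masks are ingested; common segmenters emit the format directly),
deconvolution and drift correction, and everything wet-lab.

# The measurement model

## Geometry

A cell is its label-mask region, approximated by a **moment-fitted
ellipse**: centre = pixel centroid; orientation and axis ratio from the
second central moments (with the 1/12 pixel-variance correction); both axes
rescaled so the ellipse area equals the mask area. The moment fit was
chosen over boundary least squares because it is robust for filled masks
and needs no edge extraction; for convex masks the area agreement is within
1%. Coordinates are 0-based (row, col); orientation is the major-axis angle
from the +col axis in [0, π).

Around the fitted boundary, three regions tile the cell:

* **PM band** — an annulus of width `band_width_um` (default **0.4 µm**,
  about the diffraction-limited ring thickness at 1.4 NA; the band is half
  inside, half outside the boundary, matching masks whose edges bisect the
  membrane ring);
* **interior** — the ellipse shrunk by half the band;
* **whole cell** — the ellipse grown by half the band.

Band ∪ interior = whole and band ∩ interior = ∅ exactly, so integrated
intensities satisfy PM + interior = whole to machine precision (this is a
tested invariant). Note the whole-cell region therefore includes the outer
half-band; a "whole cell" is otherwise undefined when the mask edge runs
through the middle of the membrane signal.

## Membrane profile and patch detection

The profile samples the image at 360 evenly spaced ellipse parametric
angles (configurable, ≥ 64); at each angle the intensity is the mean of 9
bilinear samples along the outward normal spanning the band. The perimeter
uses Ramanujan's second approximation (exact for circles, < 0.01% error at
yeast aspect ratios), times the pixel size.

Patches are detected on the circularly Gaussian-smoothed profile
(σ = 2 samples) as local maxima whose **topographic prominence** (computed
on the circle) is at least `0.10 × median(profile)` and whose circular
separation is at least 4°. The threshold is relative to the profile median,
so detection is invariant to uniform intensity rescaling — a tested
property. On separation conflicts the higher peak wins; exact height ties
go to the smaller angle, making detection deterministic. Valleys are the
circular minima between consecutive retained peaks; **prominence** is
mean(peak)/mean(valley) on the smoothed profile, undefined (NA, excluded
from aggregation with a count) when no patch is found. **Density** is
count/perimeter; a per-cross-section count is also emitted since published
"patch density" is sometimes per cell.

## Colocalization

Registration is an exhaustive integer-pixel search within ±5 px maximizing
the Pearson correlation of the overlap; the reported shift is the
displacement of channel 2 relative to channel 1, ties broken toward the
smaller |shift| then lexicographically. Sub-pixel registration is
deliberately omitted: the upstream correction in the emulated workflow was
done in vendor software, and integer search is the testable contract.
Per-cell Pearson coefficients are computed over each cell's mask pixels
after alignment (≥ 10 px, both channels must vary), then aggregated per
replicate. Line plots min–max normalize each channel's membrane profile
independently — "normalized" is not further specified in the emulated
workflow, so the convention is recorded in the output metadata.

## Kinetics

Per frame, patch density is summarized as median and IQR over cells
(quartile type 7, the linear-interpolation convention — conventions differ,
so it is fixed and documented). Half-decay is defined **on the median
curve**: either the first linearly interpolated crossing of half the
frame-0 median ("crossing", default), or the `T` of a least-squares fit of
`d0 * 2^(-t/T)` ("expfit", initialized from a log-linear fit). Both agree
within 10% on noiseless exponentials (tested). Per-cell half-lives are out
of scope. In the acceptance test the recovered estimate is the median over
20 simulation seeds; single-seed crossing estimates on 25-cell medians
step-jitter by ±20 min because the median of a discrete per-cell count is
itself discrete.

## Statistics

The statistical unit is the biological replicate: per-cell metrics are
averaged within each replicate (undefined values excluded, with counts),
and condition mean ± SD, one-way/two-way ANOVA and paired *t* tests all
operate on the replicate means. Grand means are *unweighted* across
replicates — with 10 vs 1000 cells the two replicates still count equally.
No post-hoc multiple-comparison correction is applied; pairwise tests are
labelled "uncorrected".

## Lipidomics

Amounts are divided by the per-sample inorganic-phosphate value (Pi is then
reset to 1, so normalizing twice is the identity). Fold changes compare
condition means against the same strain's control, plus each mutant
control against the reference-strain control; zeros are replaced by half
the smallest nonzero amount before the ratio (the choice is exposed).
PCA defaults to **auto-scaling** (centre + unit variance) because lipid
classes span orders of magnitude and a mixed-class loading plot is only
interpretable when each species contributes on a common scale; raw-centred
mode is available, and the scaling used is stored in the result. Loadings
are unit-norm, contributions are 100 × loading², and each component's sign
is fixed so its largest-magnitude loading is positive (deterministic
output). Protein–lipid correlation uses condition-level means (protein
amounts exist once per condition, as densitometry data come), a two-tailed
*p* from the *t* transform of *r* with *n* − 2 df, a per-lipid *p* ≤ 0.05
gate without multiple-testing correction, and `mu_r` = mean *r* over the
significant lipids. Correlations default to the Pi-normalized table.

# The synthetic world

## What it emulates

`generate_field()` renders non-overlapping elliptical cells (semi-axes
1.6–2.6 µm at 0.1 µm/px) as a membrane ring (0.4 µm wide, baseline
800 photons/px) with interior baseline/`pm_interior_ratio` (default 3),
carrying angular Gaussian patches. The patch bump is truncated at ±3σ and
rescaled to compact support, and patch centres keep a minimum separation of
6σ, so bumps never overlap and the noiseless peak/valley ratio equals
`patch_contrast` *exactly* — the amplitude needs no numerical solving.
Patch angles are drawn uniformly conditional on the separation (minimum
gaps plus Dirichlet-distributed surplus), exactly and without rejection.
Poisson patch counts above the geometric capacity `floor(2π/min_sep)` are
redrawn; at the default λ = 6 and capacity 11 the truncated mass is 2%, but
statistical tests that need an exact Poisson mean (λ = 8 thinning checks)
use narrower patches with capacity 20.

The camera model is Poisson shot noise on the blurred photon signal plus a
uniform background offset (10) and additive Gaussian read noise (SD 5).
Rendering is antialiased: region coverage ramps linearly over 0.5 px at the
ring boundaries. This matters — hard-edged rings alias into an angular
ripple of the band-mean profile that a topographic-prominence detector
reads as spurious peaks.

Time lapses assign each patch an exponential death time (half-life
`half_life_min`), so survival to *t* is exactly `2^(-t/T)` and loss is
monotone; cells and masks are static. Colocalization pairs reuse a
controlled fraction of channel-1 patch angles in channel 2, scale it by a
gain, and rigidly translate it. Uptake fields put a chosen fraction of each
cell's total signal into an interior pool (kept 0.3 µm clear of the band,
as interior dye structures are) and the rest on a thin membrane ring.
The lipid generator builds amounts as base × condition-class shift ×
strain-class shift × log-normal noise, multiplied by a per-sample Pi factor
in 0.6–1.6 (so Pi normalization is *required* to recover the shifts), and a
protein profile correlated with a designated class (IPC) at target ρ = 0.9
across 8 conditions.

## Chosen conditions, and why

The emulated study deconvolved its images in vendor software before
analysis, and states no acquisition noise regime; the generator's defaults
are therefore conventions, chosen once so that the package's own recovery
invariants hold at default settings (the detector parameters — smoothing 2
samples, threshold 0.10 × median, separation 4° — are the stated defaults
of the emulated workflow's contract). That yields a bright
(800 photons/px), lightly blurred (σ = 0.015 µm) world. What a green test
establishes is that *the measurement pipeline recovers what the generator
put in under these conditions* — not that it would perform identically on
dimmer, more aberrated, or crowded real data. Features of real images the
world does not contain: budding morphology and mother/bud asymmetry, cell
motion and focus drift, photobleaching, vacuole autofluorescence, spatially
varying background, and segmentation errors (masks are exact).

Two acceptance settings deserve emphasis. The **colocalization sweep** uses
patch-dominated channels (ring baseline = interior, narrow σ = 0.05 rad
patches, contrast 4), emulating dual eisosome-protein markers: with the
default bright-ring geometry, the *shared cell shape alone* produces
*r* ≈ 0.85 at zero patch overlap, and a bound like |*r*| < 0.2 at
shared-fraction 0 is only meaningful when patch signal dominates the
within-cell variance. The **ratio recovery** grid runs with patches off and
background 0, because patches legitimately raise the band mean (the
λ = 6 property test instead compares against the patch-adjusted analytic
expectation), and an unsubtracted background offset biases the ratio by
construction, not through any fault of the estimator.

# Numerical conventions and degenerate inputs

* Quartiles: type 7. Peak ties: smaller angle. Registration ties: smaller
  |shift|, then lexicographic. PCA signs: largest-|loading| positive.
* Constant profiles: zero patches, prominence undefined. Zero interior
  mean: ratio undefined, flagged. Zero whole-cell integral: uptake
  undefined, flagged. Flat channels: registration errors; per-cell
  correlation returns flagged NA. Constant lipid across conditions:
  excluded from correlation with a note. All-identical ANOVA input:
  F = 0, p = 1 by convention, flagged.
* Sub-minimum or one-pixel masks: QC rejection "degenerate", never a crash.
  Cells whose grown ellipse leaves the image: error at profile extraction,
  caught and logged by `quantify_field()`.
* Zero amounts in fold changes: pseudo-amount = half the smallest nonzero
  amount. M(IP)₂C-type species absent from an assay simply never appear in
  the class map.
* Images are written as 16-bit TIFF after rounding and clipping; the
  saturated fraction is returned and warned about. The built-in codec
  covers baseline little-endian grayscale (8/16/32-bit unsigned,
  multi-page) — the subset quantification pipelines actually exchange.
* CLI configs are JSON (`jsonlite`), not YAML: the deployment environment
  pins the available dependencies and `jsonlite` is among them.

# Known limitations

* 2D equatorial sections only (plus max projection); no 3D membrane
  reconstruction, no tangential-plane analysis.
* Integer-pixel registration; no sub-pixel refinement.
* The half-decay estimate is a property of the median curve; no per-cell
  survival modelling.
* Equivalence with any particular ImageJ macro's thresholds is not claimed;
  detector parameters are exposed instead.
* The moment fit assumes roughly elliptical, filled masks; heavily
  concave segmentations will fit poorly (and typically fail the area-gate
  QC).
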
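---
title: "Quantifying multiplexed smFISH at single-cell resolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multiplexed smFISH at single-cell resolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfishq)
```

## The problem

Single-molecule FISH assays of the RNAscope family visualise individual
mRNA molecules in tissue sections as diffraction-limited fluorescent
puncta, multiplexed over a handful of probe channels next to a DAPI
nuclear counterstain. Turning such images into per-cell expression
measurements requires a chain of decisions — which blobs are nuclei, which
puncta are single transcripts, how many transcripts a bright merged
cluster represents, which cell owns each punctum, what cell type that cell
is, and how to summarise a population's expression — and each decision has
tunable parameters that must be stated for the result to be reproducible.
`smfishq` implements that chain end-to-end, together with the comparison
statistics typically reported alongside (exact Mann–Whitney U, Pearson
correlation, extreme-outlier removal), and validates it against a
synthetic image generator with complete ground truth.

## Pipeline model, stage by stage

### Projection and normalization

Confocal stacks are reduced by per-pixel maximum projection per channel
(`load_and_project()`), then min-max normalized to [0, 1] per channel.
Normalization matters: the spot and cluster thresholds below are expressed
in normalized units, so they are relative to each field's dynamic range.
Physical coordinates use the pixel-centre convention,
`x_um = (index − 0.5) × pixel_size_um` for 1-based indices, which
round-trips centroids exactly. The default pixel size of 0.2 µm/px is
consistent with a 1024-pixel field imaged at 40×.

### Nuclear segmentation

`segment_nuclei()` thresholds the counterstain at an Otsu-initialized
level scaled by `contrast_threshold` (0.5 reproduces plain Otsu), then
splits touching candidates with a marker-controlled watershed on the
Euclidean distance transform. The `aggressiveness` parameter maps linearly
onto the watershed's h-minima suppression depth —
`depth = (1 − aggressiveness) × max(distance)` — so 0 never splits a
connected blob, and increasing it monotonically increases the object
count. Candidates are then filtered on area (default 15–250 µm²),
isoperimetric roundness `4πA/P²` (default ≥ 0.3) and mean counterstain
intensity (default ≥ 0.05). Commercial platforms expose the same six
knobs without disclosing their segmentation internals; this definition is
an open, reproducible stand-in with the identical tuning surface, and the
filter defaults are configuration, not constants.

Perimeters are measured on the marching-squares contour of the mask after
a light circular moving-average smoothing (window 3). Raw staircase
contours overestimate the perimeter of a digitised circle by ~5 %, which
would depress the roundness of a perfect disk to ~0.87; after smoothing a
disk scores ~0.98 and a square stays within 0.05 of its continuous value
π/4.

### Punctum detection and cluster decomposition

`detect_spots()` takes connected components above
`pixel_intensity_threshold` (default 0.03 normalized units), optionally
splits merged components with a local-maxima watershed controlled by
`spot_aggressiveness` (default 0.5), and discards components smaller than
`min_signal_area_um2` (default 0.45 µm²). Background is estimated per
channel as the median intensity outside all spot masks — robust and
parameter-free — and each spot records its background-subtracted
integrated intensity and its raw peak intensity.

Copy counting follows the cluster rule: a spot whose **peak** intensity
exceeds `copy_intensity_threshold` (default 0.15) is a cluster and
contributes `round(integrated / unit)` copies (half away from zero,
floored at 1); any other spot is one copy no matter its brightness. Which
intensity the 0.15 threshold applies to (peak, mean or integrated) is
under-determined in the assay's published description; we apply it to the
peak, which keeps single puncta and clusters commensurable on the
integrated scale, and record the choice here and in the configuration.
The per-copy unit is calibrated per field and probe as the median
integrated intensity of isolated puncta (`calibrate_unit_intensity()`,
requiring at least five), using single transcripts as internal positive
controls; a known unit can be supplied in the configuration instead.

### Assignment, lineage and scoring

Puncta are assigned to the nucleus with the nearest geometric centre
(Voronoi rule) if and only if that distance is at most
`max_cell_radius_um` = 25 µm — roughly the largest cortical soma — with
exact ties broken to the lowest nucleus id; everything farther is dropped
as unattributable (`assign_spots()`).

Lineage calls use marker probes (e.g. P2RY12 for microglia, SLC1A2 for
astrocytes, MAP2 for neurons): a cell is positive for a lineage at 2 or
more marker copies. Exactly one positive marker determines the lineage;
cells positive for several markers are labelled `"multiple"` and thereby
excluded from single-lineage denominators (the source method never defines
this case; excluding ambiguous cells is the conservative resolution), and
cells positive for none are `"unclassified"`.

Test-probe counts are binned as negative (0 copies) or 1+/2+/3+/4+ with
class minima 1, 4, 10 and 16 copies — half-open intervals, the only
reading consistent with all four printed minima — and summarised as

H-score = 1·(% 1+ cells) + 2·(% 2+) + 3·(% 3+) + 4·(% 4+), range 0–400.

The denominator population is configurable (`"all"`, `"probe_positive"`,
`"lineage:<label>"`) because published usage varies between scoring among
probe-positive cells and within a lineage; the default is
`"probe_positive"`, under which the class-0 percentage is zero by
construction. Samples imaged as several fields are aggregated by pooling
the per-cell tables before scoring, not by averaging per-field H-scores:
the score is defined over the entire area analysed, and pooling weights
every cell equally.

For transcripts too abundant for punctum separation (e.g. SNAP25),
`intensity_score()` reports the channel's total above-background intensity
divided by the number of cells of the relevant lineage in the field.

### Comparison statistics

`mann_whitney_exact()` computes U from mid-ranks and, for group sizes
totalling ≤ 12, an exact two-sided p by full enumeration of all
`choose(n_a + n_b, n_a)` assignments of the observed pooled values —
correct under ties, where the classical null tables are not; the doubled
one-tail arrangement count is capped at 1. Larger samples use the normal
approximation with tie-corrected variance and no continuity correction.
Both modes are exposed because published small-sample p-values do not
always state which was used. `pearson_r()` is the sample correlation with
the t-transform p on n − 2 degrees of freedom.
`remove_extreme_outliers()` drops values beyond 1.5 × IQR outside the
quartiles. That fence multiplier conventionally flags *mild* outliers
(extreme usually means 3 × IQR), but 1.5 is what the protocol we
re-implement states, so it is the default, with the multiplier exposed.
Quartiles are type-7 (linear interpolation) so results are bit-for-bit
reproducible.

## The synthetic generator: what it emulates and what it does not

`generate_field()` renders a DAPI channel of non-overlapping, mildly
elliptical nuclei (radius 3–6 µm, axis ratio 0.75–1, smoothed fill —
enough to exercise roundness filtering without a biophysical nucleus
model) and one channel per probe in which each transcript copy is a 2-D
Gaussian of integrated intensity `unit_copy_intensity`; a k-copy cluster
is k superposed copies at one site. Constant background, Gaussian pixel
noise and optional large dim autofluorescent blobs (emulating the
aggregate-laden background of diseased tissue in one channel) are added
before clipping to [0, 1].

Default study conditions: 1024 × 1024 px at 0.2 µm/px, 20 nuclei, one
probe at a mean of 5 copies per positive cell (fraction positive 1.0,
cluster fraction 0.3), PSF σ 0.3 µm, unit intensity 1.7 (peak ≈ 0.12 per
copy), background 0.02, noise SD 0.003. Copies per positive cell are
negative binomial (dispersion 4): the true per-cell copy distribution in
tissue is unknown, and the choice is flagged in the configuration. Owned
puncta fall uniformly within 8 µm of the owner nucleus centroid; combined
with the 18 µm minimum nucleus separation this makes the owner the
nearest nucleus for every owned punctum, so proximity assignment is
recoverable exactly by construction and assignment errors can be studied
separately from placement ambiguity. The noise and threshold defaults
were chosen together so that a single copy's footprint comfortably
clears the 0.45 µm² size floor while its peak (≈ 0.14 raw) stays under
the 0.15 cluster criterion, mirroring an assay imaged with conservative
settings.

What the generator does **not** emulate: realistic PSFs (no Airy rings),
3-D z-stacks beyond thin projection tests, optical sectioning artefacts,
tissue autofluorescence textures, chromatic shifts, segmentation-hostile
nuclear crowding, or FFPE fixation chemistry. Passing ground-truth
recovery tests therefore demonstrates the pipeline's internal consistency
and parameter semantics — not its performance on adversarial real tissue,
which always needs the real-time tuning the parameter surface exists for.

## The fragmentation-detectability model

Probe panels tile a transcript with up to `n_pairs` = 20 adjacent
double-Z oligo pairs, and amplification needs only `min_intact_run` = 3
consecutive bound pairs to yield a punctum. `degradation_model()` draws a
Poisson number of strand breaks per molecule and scatters them uniformly
(with replacement) over the 19 junctions between adjacent pair sites — at
probe-pair granularity, not base-pair, because that is the resolution at
which the detectability argument is posed; a molecule stays detectable if
some fragment retains 3 consecutive sites. The implementation evaluates
all molecules at once on a cut-indicator matrix with a sliding-window
minimum; tests compare it against a literal exhaustive enumeration over
cut placements. The resulting curve is flat at 1.0 until far beyond
physiological break counts — with ~8 expected breaks, detectability is
still > 99.9 % — which is the quantitative form of the observation that
punctum counts, unlike qPCR, tolerate degraded RNA.

## Numerical choices and degenerate inputs

- Blank images segment/detect to empty tables, not errors; empty masks,
  empty groups, zero-variance correlations and empty H-score denominators
  are errors with named causes.
- Watershed tolerances are floored at 1e-6 to avoid zero-tolerance
  pathologies; assignment ties are exact floating-point ties and resolve
  to the lowest id.
- `round(integrated / unit)` rounds half away from zero (not banker's
  rounding) and floors at one copy: a faint cluster still represents at
  least one molecule.
- Exclusion polygons are tested at pixel centres via even-odd
  point-in-polygon; nuclei and spots are dropped when their centroid is
  excluded, so objects straddling the boundary follow their centroid.
- Generation, quantification and the degradation simulator are
  deterministic given their seed/configuration; simulation seeds are part
  of the configuration rather than global state.

## Problem sizes used in the validation suite

The test suite validates on one full-size default field (1024² px, 20
nuclei), six 384² px fields for multi-field bookkeeping, 100 random
nucleus/spot configurations for assignment, and 10^5 molecules per point
of the detectability curve; these sizes give tight Monte-Carlo error
(SE ≤ ~0.0016 on detectable fractions) while keeping the whole suite
around a minute.

## Known limitations

- 2-D only: quantification operates on projections; overlapping cells in
  z are not separated, which real thick sections will present.
- No cytoplasmic or membranous compartment: puncta are attributed by
  nuclear proximity alone, a deliberate match to the re-implemented
  protocol rather than a cell-boundary model.
- Cluster decomposition assumes intensity scales linearly with copy
  number; fluorophore self-quenching in very dense clusters would bias
  counts low.
- The calibration of the per-copy unit requires ≥ 5 isolated puncta per
  field and probe; sparse probes (few expressing cells per field) need a
  configuration-supplied unit, and genes expressed only in rare scattered
  cells remain hard to quantify without whole-slide imaging.
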
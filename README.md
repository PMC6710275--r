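# smfishq

Single-cell quantification of multiplexed single-molecule FISH (smFISH /
RNAscope-style) images of tissue sections, in R.

Brain-bank tissue is a hostile substrate for expression profiling: RNA is
often too degraded for qPCR or sequencing, yet smFISH puncta survive
because amplification needs only a short run of intact probe-pair sites on
each transcript. What is then missing is a reproducible way to turn
multiplexed punctum images into per-cell, per-cell-type expression scores.
`smfishq` implements that pipeline for researchers quantifying probe
panels (lineage markers plus test probes) in DAPI-counterstained sections:

- **nuclear segmentation** from the counterstain (Otsu-scaled threshold +
  distance-transform watershed) with the six standard tuning features:
  nuclear size, roundness, intensity, contrast threshold and segmentation
  aggressiveness;
- **punctum detection** per probe channel with a minimum signal size of
  0.45 µm²;
- **cluster decomposition**: a spot whose peak exceeds the copy-intensity
  threshold (0.15) counts `round(integrated / unit)` copies, where the
  per-copy unit is calibrated from isolated single puncta; separate
  puncta always count one copy;
- **proximity assignment** of puncta to the nearest nucleus centroid
  within a maximum cell radius of 25 µm (Voronoi rule);
- **lineage classification** at ≥ 2 marker copies per cell, **expression
  binning** into classes 0/1+/2+/3+/4+ at copy minima 1/4/10/16, and the
  **H-score**

  `H = 1·(%1+ cells) + 2·(%2+) + 3·(%3+) + 4·(%4+)`, range 0–400,

  over a configurable denominator population (all cells, probe-positive
  cells, or one lineage); a total-intensity-per-cell score covers genes
  too abundant for punctum separation;
- **statistics**: exact (enumeration) Mann–Whitney U that is correct
  under ties, Pearson correlation with t-transform p, and the 1.5 × IQR
  extreme-outlier filter;
- a **synthetic field generator** with complete ground truth (nuclei,
  every punctum, per-cell copy tables) for validation, plus a simulator
  of probe detectability under RNA fragmentation (Poisson breaks over the
  junctions of a 20-site double-Z tiling, detectable at ≥ 3 consecutive
  intact sites).

## Worked example

Simulate a two-probe field (a microglial marker plus a test probe) and
quantify it blind to the truth:

```r
library(smfishq)

cfg <- synth_config(
  probe_specs = list(
    probe_spec("P2RY12", mean_copies = 8, fraction_positive = 0.4),
    probe_spec("TREM2",  mean_copies = 5, fraction_positive = 0.5)),
  seed = 7)
sim <- generate_field(cfg)

res <- quantify_field(sim$field, pipeline_config(
  lineage_probes = c(P2RY12 = "microglia"),
  test_probes    = "TREM2",
  denominator    = "lineage:microglia"))

nrow(res$nuclei)            # 20  (all 20 simulated nuclei recovered)
table(res$cells$lineage)
#>    microglia unclassified
#>            8           12
res$units
#>   P2RY12    TREM2
#> 1.576981 1.566180          # calibrated per-copy intensity (true: 1.7)
res$scores$TREM2
#> H-score[TREM2 | lineage:microglia] = 50.0 over 8 cells
#>   % per class: 0+: 62.5  1+: 25.0  2+: 12.5  3+: 0.0  4+: 0.0
```

The H-score of 50.0 over the 8 microglia (62.5 % of them TREM2-negative,
25 % in class 1+, 12.5 % in class 2+) is exactly the score obtained from
the generator's ground-truth copy table:

```r
h_score(cells_from_truth(sim$truth$cell_probe_copies,
                         c(P2RY12 = "microglia")),
        "TREM2", "lineage:microglia")
#> H-score[TREM2 | lineage:microglia] = 50.0 over 8 cells
```

Group comparison and fragmentation robustness:

```r
mann_whitney_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))
#> Mann-Whitney U = 0 (n = 4 vs 4), two-sided p = 0.02857 [exact]

simulate_detection_after_degradation(degradation_model(expected_breaks = 4))
#> [1] 0.99999   # punctum detection barely notices 4 breaks per molecule
```

See `vignettes/smfishq-methods.Rmd` for the model, parameter semantics,
the generator's scope and the design decisions.

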
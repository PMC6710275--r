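Package: smfishq
Title: Single-Cell Quantification of Multiplexed smFISH in Tissue Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying multiplexed single-molecule
    fluorescent in situ hybridization (smFISH, e.g. RNAscope) images of tissue
    sections at single-cell resolution: nuclear segmentation from a DAPI
    counterstain with morphometric filtering, probe punctum detection with a
    minimum-signal-size filter, decomposition of bright clusters into probe
    copy counts against a calibrated single-copy intensity, proximity
    (Voronoi) assignment of puncta to nuclei within a maximum cell radius,
    marker-based cell lineage classification, 0-4+ expression binning and
    H-score computation, plus the accompanying comparison statistics (exact
    Mann-Whitney U, Pearson correlation, extreme-outlier removal). Includes a
    synthetic field generator with full ground truth for validation and a
    simulator of probe detectability under RNA fragmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    grDevices,
    utils,
    mgcv,
    tiff,
    png,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
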
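Package: chromdyn
Title: Chromatin Compaction Dynamics and Voronoi Density Analysis of
    Nuclear Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies chromatin compaction before and during neuronal cell
    death from two-channel nuclear time-lapse imaging and from single-molecule
    localization microscopy (SMLM) data. Implements the Sobel-edge chromatin
    compaction parameter (CCP) with Otsu-based nuclear segmentation, rule-based
    classification of per-nucleus trajectories into apoptotic, necrotic-like,
    granulating and no-change fates, alignment of trajectories to the onset of
    nuclear size change, and Voronoi-tessellation density analysis of SMLM
    localization tables (FWHM filtering, blinking-event merging, polar
    transform, per-localization Voronoi densities via Gauss's area formula,
    count-normalized log10 densities and probability-density histograms).
    A seeded synthetic-microscopy generator emulates the imaging study's
    nuclear dynamics and clustered localization patterns so that every stage
    of the pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    tools,
    interp,
    FNN,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deldir,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
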
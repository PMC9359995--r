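# chromdyn

Chromatin compaction dynamics and Voronoi density analysis of nuclear
imaging data.

Neurons reorganize their chromatin *before* the classical morphological
signs of apoptosis appear. `chromdyn` provides the computational half of
that observation as a tested, reusable R pipeline for two kinds of data:

* **Two-channel nuclear time-lapse imaging** (a chromatin marker such as
  H2B::mCherry plus a caspase reporter such as NucView): per-frame Otsu
  segmentation of the nucleus, Sobel edge counting and the **chromatin
  compaction parameter**
  `CCP = edge pixels / nuclear cross-section area`,
  baseline normalization, rule-based classification of each nucleus into
  *apoptotic*, *necrotic-like*, *granulating* or *no change*, a 14-fold
  reporter rule for apoptotic events, and alignment of trajectories to the
  onset of nuclear size change.
* **SMLM localization tables** (ThunderSTORM-style CSV): FWHM filtering
  (65–225 nm), blinking-event merging (20 nm, 1 off-frame), polar transform
  about the nuclear centre of mass, per-localization **Voronoi densities**
  (cell areas by Gauss's shoelace formula, density = 1/area), count
  normalization, log10 transform, and probability-density histograms
  (area/volume normalized to 1).

A seeded synthetic-microscopy generator (`generate_timelapse()`,
`generate_culture()`, `generate_localizations()`) emulates the study's
nuclear dynamics — apoptotic shrinkage to a 0.26 area plateau, necrotic
swelling to 1.17, pre-apoptotic compaction to 1.55-fold CCP, and five
stage-specific clustered localization patterns — so the whole pipeline is
testable without any raw data.

## Worked example

Simulate a small mixed culture, measure and classify it:

```r
library(chromdyn)
library(dplyr)

cult <- generate_culture(
  n_cells = 20,
  fate_mix = c(control = 0.4, apoptosis = 0.3, necrosis = 0.2, granulating = 0.1),
  seed = 11
)
trajs <- lapply(seq_along(cult$stacks), function(i) {
  measure_stack(cult$stacks[[i]]) |>
    normalize_trajectory() |>
    mutate(cell_id = i)
}) |> bind_rows()

labels <- classify_fates(trajs)
table(truth = cult$truth$fate, predicted = labels$fate)
#>              predicted
#> truth         apoptotic granulating necrotic no_change
#>   apoptosis           6           0        0         0
#>   control             0           0        0         8
#>   granulating         0           2        0         0
#>   necrosis            0           0        4         0

aligned <- align_to_size_change(trajs)
aligned_mean(aligned, "ccp_norm", rel_time_min = -120)
#> # A tibble: 1 x 4
#>   rel_time_min  mean    sem n_cells
#>          <dbl> <dbl>  <dbl>   <int>
#> 1         -120  1.70 0.0491      10
```

All 20 programmed fates are recovered, and the mean normalized CCP of the
dying cells (apoptotic and necrotic pooled) two hours *before* their nuclear
size change is already 1.7-fold of baseline — the early-compaction signature
the classifier keys on (apoptotic nuclei alone plateau near 1.55, necrotic
near 1.9).

The SMLM side, from localization table to density summary:

```r
tab <- generate_localizations(stage_profile(1), n_molecules = 20000, seed = 42)
vd <- tab |>
  filter_by_fwhm() |>
  merge_blinking() |>
  to_polar() |>
  voronoi_density() |>
  normalize_log()
summarize_group(vd)
#> # A tibble: 1 x 4
#>   mean_log10_density sd_log10_density n_localizations n_nuclei
#>                <dbl>            <dbl>           <int>    <int>
#> 1              -7.84            0.297           19967        1
```

A stage-1 (control) nucleus shows the homogeneous density distribution,
mean −7.84 log(nm⁻²); stage-5 profiles land near −7.37, a +0.46 shift of
the distribution toward higher chromatin density. `density_pdf()`,
`radius_density_pdf()` and the `plot_*()` helpers produce the
unit-area histograms used to display these distributions.

File-based runs (TIFF + CSV in, CSV + manifest out) go through
`run_simulate_timelapse()`, `run_measure_classify()` and `run_voronoi()`,
or the thin CLI at `inst/cli/chromdyn-cli.R`
(subcommands `simulate-timelapse`, `simulate-smlm`, `measure-classify`,
`voronoi`; exit codes 0/2/3).

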
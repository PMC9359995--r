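#!/usr/bin/env Rscript
# One-time calibration of the synthetic-microscopy generator.
#
# (a) Time-lapse texture: maps the granule site-count ratio (active sites at
#     the compaction plateau / baseline sites) to the CCP ratio actually
#     measured by the Sobel/Otsu pipeline, averaged over seeds. The inverse
#     of this response (a piecewise-linear lookup) is frozen into
#     `.granule_defaults$response` so that a programmed compaction ratio
#     produces a matching measured ratio.
# (b) SMLM stages: tunes each stage profile's clustered_fraction so the full
#     post-processing chain (FWHM filter -> merge -> Voronoi -> count
#     normalization) reproduces the stage's target mean log10 normalized
#     density. Tuned fractions are frozen into `.stage_defaults`.
#
# Run from the repository root:  Rscript scripts/calibrate_generator.R
# The printed constants are pasted into R/synthetic-timelapse.R and
# R/synthetic-smlm.R; they are not recomputed at package run time.

suppressMessages(devtools::load_all(".", quiet = TRUE))

message("== (a) granule count ratio -> measured CCP ratio ==")
# disable the frozen lookup so the programmed ratio IS the raw count ratio
gd <- chromdyn:::.granule_defaults
gd$response <- list(kappa = c(0, 10), measured = c(0, 10))
assignInNamespace(".granule_defaults", gd, ns = "chromdyn")
kappas <- c(1, 1.2, 1.4, 1.6, 1.8, 2.0, 2.2, 2.5)
resp <- sapply(kappas, function(kappa) {
  mean(sapply(1:8, function(s) {
    prog <- fate_program("granulating", granulation_ccp_ratio = kappa)
    st <- generate_timelapse(prog, seed = 1000 + s)
    tr <- normalize_trajectory(measure_stack(st))
    mean(tr$ccp_norm[tr$time_min >= 150 & tr$time_min <= 250])
  }))
})
cat("kappa:    ", paste(sprintf("%.3f", kappas), collapse = ", "), "\n")
cat("measured: ", paste(sprintf("%.3f", resp), collapse = ", "), "\n")

message("== (b) stage clustered_fraction -> mean log10 normalized density ==")
measure_stage <- function(stage, frac, n = 25000, seeds = 1:3) {
  mean(sapply(seeds, function(s) {
    prof <- stage_profile(stage, clustered_fraction = frac)
    tab <- generate_localizations(prof, n, seed = 2000 + 10 * stage + s)
    tab <- merge_blinking(filter_by_fwhm(tab))
    vd <- normalize_log(voronoi_density(tab))
    mean(vd$log10_norm_density, na.rm = TRUE)
  }))
}
for (stage in 2:5) {
  target <- stage_profile(stage)$target_log10_density
  # bisection on the clustered fraction (mean density rises with clustering)
  lo <- 0; hi <- 0.8
  for (it in 1:9) {
    mid <- (lo + hi) / 2
    m <- measure_stage(stage, mid)
    if (m < target) lo <- mid else hi <- mid
  }
  frac <- (lo + hi) / 2
  cat(sprintf("stage %d: clustered_fraction = %.3f (measured %.3f, target %.2f)\n",
              stage, frac, measure_stage(stage, frac), target))
}
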
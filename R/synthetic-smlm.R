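# Stage-profile structural defaults. clustered_fraction values were frozen by
# the one-time calibration run (scripts/calibrate_generator.R) so that the
# full post-processing chain (FWHM filter -> merge -> Voronoi -> count
# normalization) reproduces the per-stage mean log10 normalized densities the
# profiles target. Stage 1 is uncalibrated by construction (complete spatial
# randomness).
.stage_defaults <- list(
  list(stage_index = 1L, clustered_fraction = 0.00, cluster_sd_nm = 150,
       clusters_per_um2 = 0.5, radius_shrink_factor = 1.00,
       ring_radius_frac = NA_real_, target_log10_density = -7.83),
  list(stage_index = 2L, clustered_fraction = 0.513, cluster_sd_nm = 150,
       clusters_per_um2 = 0.5, radius_shrink_factor = 1.00,
       ring_radius_frac = NA_real_, target_log10_density = -7.62),
  list(stage_index = 3L, clustered_fraction = 0.423, cluster_sd_nm = 100,
       clusters_per_um2 = 0.5, radius_shrink_factor = 1.00,
       ring_radius_frac = 0.8, target_log10_density = -7.58),
  list(stage_index = 4L, clustered_fraction = 0.184, cluster_sd_nm = 80,
       clusters_per_um2 = 0.4, radius_shrink_factor = 0.85,
       ring_radius_frac = NA_real_, target_log10_density = -7.60),
  list(stage_index = 5L, clustered_fraction = 0.058, cluster_sd_nm = 60,
       clusters_per_um2 = 0.4, radius_shrink_factor = 0.60,
       ring_radius_frac = NA_real_, target_log10_density = -7.37)
)

#' Localization-pattern profile for an apoptotic stage
#'
#' Describes the spatial statistics of chromatin-marker localizations at one
#' of the five apoptotic stages: stage 1 (control) is complete spatial
#' randomness in the nuclear disk; stages 2-3 mix a uniform background with a
#' Thomas-type cluster process of shrinking cluster spread (stage 3 clusters
#' concentrate on a peripheral ring); pyknotic stages 4-5 shrink the nuclear
#' radius itself, which concentrates localizations globally, so their
#' residual clustered fraction is small and the pattern approaches the
#' homogeneous dense state observed at the end of apoptosis. The defaults
#' target the per-stage mean count-normalized log10 Voronoi densities
#' (-7.83, -7.62, -7.58, -7.60, -7.37 for stages 1-5).
#'
#' @param stage_index stage 1..5.
#' @param nucleus_radius_nm baseline nuclear disk radius (default 5000 nm;
#'   see the methods vignette for the choice).
#' @param clustered_fraction,cluster_sd_nm,clusters_per_um2 Thomas-process
#'   parameters (fraction of molecules in clusters, Gaussian cluster spread,
#'   parent intensity); stage-specific defaults.
#' @param radius_shrink_factor nuclear-radius multiplier (< 1 for stages
#'   4-5).
#' @param ring_radius_frac when set, cluster parents concentrate on a ring at
#'   this fraction of the nuclear radius (stage 3 peripheral compaction).
#' @param target_log10_density intended mean count-normalized log10 Voronoi
#'   density.
#' @param sigma_lognormal_params `c(meanlog, sdlog)` of the fitted-width
#'   distribution; the defaults place mass below FWHM 65 nm and above
#'   225 nm so the width filter is exercised.
#' @param blink_run_geom_p geometric parameter of emission-run lengths.
#' @param blink_off_max off-gap (frames) between emission runs of one
#'   molecule.
#' @param blink_second_run_p probability of each additional emission run.
#' @param loc_jitter_nm per-event localization jitter sd.
#' @param n_frames acquisition length in frames.
#' @return a list of class `stage_profile`.
#' @export
stage_profile <- function(stage_index,
                          nucleus_radius_nm = 5000,
                          clustered_fraction = NULL,
                          cluster_sd_nm = NULL,
                          clusters_per_um2 = NULL,
                          radius_shrink_factor = NULL,
                          ring_radius_frac = NULL,
                          target_log10_density = NULL,
                          sigma_lognormal_params = c(meanlog = log(55), sdlog = 0.28),
                          blink_run_geom_p = 0.5,
                          blink_off_max = 1L,
                          blink_second_run_p = 0.3,
                          loc_jitter_nm = 3,
                          n_frames = 5000L) {
  stage_index <- as.integer(stage_index)
  if (!stage_index %in% 1:5) {
    abort("stage_index must be 1..5.", class = "chromdyn_validation_error")
  }
  d <- .stage_defaults[[stage_index]]
  p <- list(
    stage_index = stage_index,
    nucleus_radius_nm = nucleus_radius_nm,
    clustered_fraction = clustered_fraction %||% d$clustered_fraction,
    cluster_sd_nm = cluster_sd_nm %||% d$cluster_sd_nm,
    clusters_per_um2 = clusters_per_um2 %||% d$clusters_per_um2,
    radius_shrink_factor = radius_shrink_factor %||% d$radius_shrink_factor,
    ring_radius_frac = ring_radius_frac %||% d$ring_radius_frac,
    target_log10_density = target_log10_density %||% d$target_log10_density,
    sigma_lognormal_params = sigma_lognormal_params,
    blink_run_geom_p = blink_run_geom_p,
    blink_off_max = as.integer(blink_off_max),
    blink_second_run_p = blink_second_run_p,
    loc_jitter_nm = loc_jitter_nm,
    n_frames = as.integer(n_frames)
  )
  if (p$nucleus_radius_nm <= 0) {
    abort("nucleus_radius_nm must be > 0.", class = "chromdyn_validation_error")
  }
  if (p$clustered_fraction < 0 || p$clustered_fraction > 1) {
    abort("clustered_fraction must be in [0, 1].", class = "chromdyn_validation_error")
  }
  structure(p, class = "stage_profile")
}

#' Generate an SMLM localization table for one nucleus
#'
#' Simulates molecules from the stage's Thomas-type cluster process (parents
#' uniform - or ring-placed - in the nuclear disk; a `clustered_fraction` of
#' molecules Gaussian-scattered around parents; the remainder uniform), then
#' emits blinking events for each molecule: one or more emission runs of
#' geometric length separated by short off-gaps, with per-event localization
#' jitter, lognormal fitted widths (including mass outside the plausible
#' FWHM range, to exercise the width filter) and lognormal photon counts.
#'
#' @param profile a [stage_profile()].
#' @param n_molecules number of molecules (>= 0).
#' @param seed integer seed; identical (profile, n_molecules, seed) give
#'   identical tables.
#' @return localization tibble: `frame`, `x_nm`, `y_nm`, `sigma_nm`,
#'   `intensity_photons`, `molecule_id`, sorted by frame.
#' @export
generate_localizations <- function(profile, n_molecules, seed = 1L) {
  if (!inherits(profile, "stage_profile")) {
    abort("`profile` must be a stage_profile().", class = "chromdyn_validation_error")
  }
  if (n_molecules < 0) {
    abort("n_molecules must be >= 0.", class = "chromdyn_validation_error")
  }
  empty <- tibble(frame = integer(), x_nm = double(), y_nm = double(),
                  sigma_nm = double(), intensity_photons = double(),
                  molecule_id = integer())
  if (n_molecules == 0L) return(empty)
  with_rng(seed, {
    R <- profile$nucleus_radius_nm * profile$radius_shrink_factor
    n_clust <- round(profile$clustered_fraction * n_molecules)
    n_unif <- n_molecules - n_clust
    # molecule positions
    xs <- ys <- numeric(0)
    if (n_clust > 0) {
      area_um2 <- pi * (R / 1000)^2
      k <- max(1L, rpois(1L, profile$clusters_per_um2 * area_um2))
      if (is.finite(profile$ring_radius_frac)) {
        rp <- R * pmin(1, pmax(0, rnorm(k, profile$ring_radius_frac, 0.08)))
      } else {
        rp <- R * sqrt(runif(k))
      }
      tp <- runif(k, 0, 2 * pi)
      px <- rp * cos(tp); py <- rp * sin(tp)
      asg <- sample.int(k, n_clust, replace = TRUE)
      xs <- px[asg] + rnorm(n_clust, 0, profile$cluster_sd_nm)
      ys <- py[asg] + rnorm(n_clust, 0, profile$cluster_sd_nm)
    }
    if (n_unif > 0) {
      ru <- R * sqrt(runif(n_unif)); tu <- runif(n_unif, 0, 2 * pi)
      xs <- c(xs, ru * cos(tu)); ys <- c(ys, ru * sin(tu))
    }
    # blinking schedule, fully vectorized: per molecule one or more emission
    # runs of geometric length, separated by `blink_off_max` dark frames
    n_runs <- 1L + rgeom(n_molecules, 1 - profile$blink_second_run_p)
    total_runs <- sum(n_runs)
    run_mol <- rep(seq_len(n_molecules), n_runs)
    lens <- 1L + rgeom(total_runs, profile$blink_run_geom_p)
    f0 <- sample.int(profile$n_frames, n_molecules, replace = TRUE)
    step <- lens + profile$blink_off_max
    cs_before <- cumsum(step) - step          # global prefix sum
    grp_first <- cumsum(n_runs) - n_runs + 1L
    run_start <- f0[run_mol] + cs_before - cs_before[grp_first][run_mol]
    n_events <- sum(lens)
    ev_run <- rep(seq_len(total_runs), lens)
    frame <- rep(run_start, lens) + sequence(lens) - 1L
    mol <- run_mol[ev_run]
    out <- tibble(
      frame = frame,
      x_nm = xs[mol] + rnorm(n_events, 0, profile$loc_jitter_nm),
      y_nm = ys[mol] + rnorm(n_events, 0, profile$loc_jitter_nm),
      sigma_nm = rlnorm(n_events, profile$sigma_lognormal_params[1],
                        profile$sigma_lognormal_params[2]),
      intensity_photons = rlnorm(n_events, log(800), 0.4),
      molecule_id = mol
    )
    out[order(out$frame, out$molecule_id), , drop = FALSE]
  })
}
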
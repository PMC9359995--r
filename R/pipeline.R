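#' Default run configuration
#'
#' Nested list of every stage parameter with defaults equal to the analysis
#' constants (classification thresholds, filter/merge parameters, histogram
#' limits, generator programs), so that an empty override reproduces the
#' reference settings. Round-trips losslessly through YAML.
#'
#' @param ... named overrides, e.g. `run_config(seed = 7)` or nested lists
#'   (`run_config(classify = list(event_fold = 14))` replaces only the given
#'   fields).
#' @return a list of class `run_config`.
#' @export
run_config <- function(...) {
  base <- list(
    seed = 1L,
    log_level = "info",
    simulate = list(
      n_cells = 10L,
      fate_mix = list(control = 0.6, apoptosis = 0.2, necrosis = 0.1,
                      granulating = 0.1),
      noise_sd = 0.03,
      n_px = 96L, pixel_size_nm = 111, nucleus_radius_px = 28, n_z = 1L
    ),
    smlm = list(
      stages = 1:5, n_molecules = 20000L, nucleus_radius_nm = 5000
    ),
    measure = list(
      pixel_factor = 2L, z_method = "max", min_size = 50L, erode_px = 5L,
      n_baseline = 3L
    ),
    classify = list(
      surviving_gradient_max = 0.035, dying_end_gradient_min = 0.8,
      apoptotic_final_ccp_max_ratio = 1.1, necrotic_final_size_max_ratio = 0.75,
      granulating_final_ccp_min_increase = 0.5, event_fold = 14,
      end_window_frames = 3L, deviation_threshold = 0.1, persistence = 2L
    ),
    voronoi = list(
      fwhm_min_nm = 65, fwhm_max_nm = 225, merge_max_distance_nm = 20,
      merge_max_off_frames = 1L, pdf_bins = 50L,
      pdf_limits = c(-10, -5), radius_limits = c(0, 8000),
      color_clip = c(1e-5, 1e-3)
    )
  )
  over <- list(...)
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      if (is.list(a[[nm]]) && is.list(b[[nm]])) {
        a[[nm]] <- merge_lists(a[[nm]], b[[nm]])
      } else {
        a[[nm]] <- b[[nm]]
      }
    }
    a
  }
  structure(merge_lists(base, over), class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path file path.
#' @return `read_run_config()` a `run_config`; `write_run_config()` the path,
#'   invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Write a run manifest (config snapshot, versions, per-stage counts, input
# checksums, warnings) next to the outputs.
write_manifest <- function(out_dir, config, counts = list(), inputs = character(),
                           warnings = character()) {
  man <- list(
    package = "chromdyn",
    version = as.character(utils::packageVersion("chromdyn")),
    config = unclass(config),
    counts = counts,
    input_md5 = if (length(inputs)) as.list(tools::md5sum(inputs)) else list(),
    warnings = as.list(warnings)
  )
  path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Write / read a two-channel time-lapse stack as multi-page TIFF
#'
#' Each channel is written to its own float TIFF (`<prefix>_h2b.tif`,
#' `<prefix>_nucview.tif`), one page per frame, scaled into [0, 1] by a
#' per-channel factor recorded in `<prefix>_scale.yaml`; the reader restores
#' the original intensities. The per-frame truth table is written to
#' `<prefix>_truth.csv`.
#'
#' @param stack a `timelapse_stack`.
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_timelapse_tiff <- function(stack, prefix) {
  stopifnot(length(dim(stack$h2b)) == 3L)
  files <- character(0)
  scales <- list()
  for (ch in c("h2b", "nucview")) {
    a <- stack[[ch]]
    sc <- max(a, 1e-12)
    pages <- lapply(seq_len(dim(a)[1]), function(f) a[f, , ] / sc)
    path <- paste0(prefix, "_", ch, ".tif")
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    files <- c(files, path)
    scales[[ch]] <- sc
  }
  meta <- list(intensity_scale = scales,
               pixel_size_nm = stack$pixel_size_nm,
               frame_interval_min = stack$frame_interval_min,
               n_baseline_frames = stack$n_baseline_frames,
               fate = stack$fate,
               event_frame = if (is.na(stack$event_frame)) NULL else stack$event_frame)
  yaml::write_yaml(meta, paste0(prefix, "_scale.yaml"))
  readr::write_csv(stack$truth, paste0(prefix, "_truth.csv"), progress = FALSE)
  invisible(c(files, paste0(prefix, "_scale.yaml"), paste0(prefix, "_truth.csv")))
}

#' @rdname write_timelapse_tiff
#' @export
read_timelapse_tiff <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_scale.yaml"))
  get_ch <- function(ch) {
    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"), all = TRUE)
    a <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (f in seq_along(pages)) a[f, , ] <- pages[[f]] * meta$intensity_scale[[ch]]
    a
  }
  truth_path <- paste0(prefix, "_truth.csv")
  structure(
    list(h2b = get_ch("h2b"), nucview = get_ch("nucview"),
         pixel_size_nm = meta$pixel_size_nm,
         frame_interval_min = meta$frame_interval_min,
         n_baseline_frames = meta$n_baseline_frames,
         truth = if (file.exists(truth_path)) {
           readr::read_csv(truth_path, show_col_types = FALSE, progress = FALSE)
         } else NULL,
         fate = meta$fate %||% NA_character_,
         event_frame = meta$event_frame %||% NA_integer_),
    class = "timelapse_stack"
  )
}

#' Simulate a culture and write it to disk
#'
#' Renders `config$simulate$n_cells` nuclei, writes per-cell TIFF pairs and
#' truth CSVs plus a culture-level truth table and a run manifest.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return the culture truth tibble, invisibly.
#' @export
run_simulate_timelapse <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulate
  mix <- unlist(sim$fate_mix)
  cult <- generate_culture(
    n_cells = sim$n_cells, fate_mix = mix, noise_sd = sim$noise_sd,
    seed = config$seed,
    geometry = timelapse_geometry(sim$n_px, sim$pixel_size_nm,
                                  sim$nucleus_radius_px, sim$n_z)
  )
  for (i in seq_along(cult$stacks)) {
    write_timelapse_tiff(cult$stacks[[i]],
                         file.path(out_dir, sprintf("cell%03d", i)))
  }
  readr::write_csv(cult$truth, file.path(out_dir, "culture_truth.csv"),
                   progress = FALSE)
  write_manifest(out_dir, config, counts = list(n_cells = sim$n_cells))
  invisible(cult$truth)
}

#' Simulate per-stage localization tables and write them to disk
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return tibble of files written with stage labels, invisibly.
#' @export
run_simulate_smlm <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sm <- config$smlm
  files <- lapply(sm$stages, function(s) {
    tab <- generate_localizations(
      stage_profile(s, nucleus_radius_nm = sm$nucleus_radius_nm),
      n_molecules = sm$n_molecules, seed = child_seed(config$seed, s)
    )
    path <- file.path(out_dir, sprintf("stage%d_localizations.csv", s))
    write_localization_csv(tab, path)
    tibble(stage = s, path = path, n_localizations = nrow(tab))
  })
  files <- bind_rows(files)
  write_manifest(out_dir, config,
                 counts = as.list(setNames(files$n_localizations,
                                           paste0("stage", files$stage))))
  invisible(files)
}

#' Measure, normalize and classify a simulated or recorded culture
#'
#' Reads every `cell*_h2b.tif` / `cell*_nucview.tif` pair under `in_dir`
#' (or takes a list of `timelapse_stack` objects), measures every frame,
#' baseline-normalizes, classifies fates and writes the trajectory, label and
#' summary CSVs with fixed column layouts.
#'
#' @param config a [run_config()].
#' @param in_dir directory produced by [run_simulate_timelapse()], or a list
#'   of stacks.
#' @param out_dir output directory.
#' @return list with `trajectories`, `labels`, `summary` (invisibly).
#' @export
run_measure_classify <- function(config, in_dir, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- config$measure
  stacks <- if (is.list(in_dir) && !is.character(in_dir)) {
    in_dir
  } else {
    prefixes <- sort(unique(sub("_(h2b|nucview)\\.tif$", "",
                                list.files(in_dir, pattern = "_(h2b|nucview)\\.tif$",
                                           full.names = TRUE))))
    if (length(prefixes) == 0L) {
      abort(sprintf("no time-lapse TIFFs found under %s", in_dir),
            class = "chromdyn_file_error")
    }
    lapply(prefixes, read_timelapse_tiff)
  }
  trajs <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    tr <- measure_stack(stacks[[i]], pixel_factor = m$pixel_factor,
                        z_method = m$z_method, min_size = m$min_size,
                        erode_px = m$erode_px)
    tr <- normalize_trajectory(tr, n_baseline = m$n_baseline)
    tr$cell_id <- i
    trajs[[i]] <- tr
  }
  trajectories <- bind_rows(trajs) |>
    select("cell_id", "frame", "time_min", "area", "edge_count", "ccp",
           "nucview_mean", "valid", dplyr::everything())
  cl <- config$classify
  thr <- classifier_thresholds(
    surviving_gradient_max = cl$surviving_gradient_max,
    dying_end_gradient_min = cl$dying_end_gradient_min,
    apoptotic_final_ccp_max_ratio = cl$apoptotic_final_ccp_max_ratio,
    necrotic_final_size_max_ratio = cl$necrotic_final_size_max_ratio,
    granulating_final_ccp_min_increase = cl$granulating_final_ccp_min_increase,
    event_fold = cl$event_fold, end_window_frames = cl$end_window_frames
  )
  labels <- classify_fates(trajectories, thr)
  aligned <- align_to_size_change(trajectories,
                                  deviation_threshold = cl$deviation_threshold,
                                  persistence = cl$persistence)
  labels <- left_join(labels, select(aligned$t0, "cell_id", t0 = "t0_frame"),
                      by = "cell_id") |>
    select("cell_id", "fate", "vitality", "step2_apoptotic", "step3_necrotic",
           "step4_granulating", "t0", "event_frame", dplyr::everything())
  summ <- summarize_culture(labels)
  readr::write_csv(trajectories, file.path(out_dir, "trajectories.csv"), progress = FALSE)
  readr::write_csv(labels, file.path(out_dir, "labels.csv"), progress = FALSE)
  readr::write_csv(summ$fates, file.path(out_dir, "summary.csv"), progress = FALSE)
  write_manifest(out_dir, config,
                 counts = list(n_cells = length(stacks),
                               n_frames = nrow(trajectories),
                               n_excluded = sum(labels$excluded)))
  invisible(list(trajectories = trajectories, labels = labels, summary = summ))
}

#' Run the Voronoi density chain over localization CSVs
#'
#' For each input file the chain runs in the canonical order: read, FWHM
#' filter, blinking merge, optional crop, polar transform, Voronoi densities,
#' count normalization, histograms. Groups with fewer than 4 usable
#' localizations are skipped with a warning. Writes per-group density CSVs,
#' pooled 1D/2D histogram CSVs and a group summary CSV, plus a manifest with
#' per-stage row counts.
#'
#' @param config a [run_config()].
#' @param files named character vector of localization CSV paths (names are
#'   group labels), or a directory containing `*_localizations.csv`.
#' @param out_dir output directory.
#' @param crop optional list with `x_range`, `y_range`.
#' @return list with `densities` (tibble), `summary`, `pdf1d`, `pdf2d`
#'   (invisibly).
#' @export
run_voronoi <- function(config, files, out_dir, crop = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  v <- config$voronoi
  if (length(files) == 1L && dir.exists(files)) {
    paths <- list.files(files, pattern = "_localizations\\.csv$", full.names = TRUE)
    names(paths) <- sub("_localizations\\.csv$", "", basename(paths))
    files <- paths
  }
  if (is.null(names(files)) || any(names(files) == "")) {
    names(files) <- sub("\\.csv$", "", basename(files))
  }
  params <- filter_merge_params(fwhm_min_nm = v$fwhm_min_nm,
                                fwhm_max_nm = v$fwhm_max_nm,
                                merge_max_distance_nm = v$merge_max_distance_nm,
                                merge_max_off_frames = v$merge_max_off_frames)
  counts <- list()
  dens_all <- list()
  for (g in names(files)) {
    tab <- read_localization_csv(files[[g]])
    n_read <- nrow(tab)
    tab <- filter_by_fwhm(tab, params)
    n_filt <- nrow(tab)
    tab <- merge_blinking(tab, params)
    n_merged <- nrow(tab)
    if (!is.null(crop)) {
      tab <- crop_to_nucleus(tab, crop$x_range, crop$y_range)
    }
    if (nrow(tab) < 4L) {
      warn(sprintf("group '%s': fewer than 4 usable localizations; skipped.", g))
      counts[[g]] <- list(read = n_read, filtered = n_filt, merged = n_merged,
                          densified = 0L)
      next
    }
    tab <- to_polar(tab)
    tab <- voronoi_density(tab)
    tab <- normalize_log(tab)
    tab$group <- g
    counts[[g]] <- list(read = n_read, filtered = n_filt, merged = n_merged,
                        densified = sum(!tab$boundary_excluded))
    dens_all[[g]] <- tab
    readr::write_csv(select(tab, "group", "frame", "x_nm", "y_nm", "r_nm",
                            "theta", "cell_area_nm2", "raw_density",
                            "norm_density", "log10_norm_density",
                            "boundary_excluded"),
                     file.path(out_dir, paste0(g, "_density.csv")),
                     progress = FALSE)
  }
  if (length(dens_all) == 0L) {
    write_manifest(out_dir, config, counts = counts)
    warn("run_voronoi(): no group had enough localizations.")
    return(invisible(NULL))
  }
  dens <- bind_rows(dens_all)
  pdf1 <- density_pdf(dens, group = "group", bins = v$pdf_bins,
                      limits = v$pdf_limits)
  pdf2 <- radius_density_pdf(dens, r_limits = v$radius_limits,
                             d_limits = v$pdf_limits,
                             color_clip = v$color_clip)
  summ <- summarize_group(dens, group = "group")
  readr::write_csv(pdf1, file.path(out_dir, "density_pdf.csv"), progress = FALSE)
  readr::write_csv(pdf2, file.path(out_dir, "radius_density_pdf.csv"), progress = FALSE)
  readr::write_csv(summ, file.path(out_dir, "group_summary.csv"), progress = FALSE)
  write_manifest(out_dir, config, counts = counts, inputs = unname(files))
  invisible(list(densities = dens, summary = summ, pdf1d = pdf1, pdf2d = pdf2))
}
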
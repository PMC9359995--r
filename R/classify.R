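#' Thresholds for rule-based cell-fate classification
#'
#' Bundles the fixed thresholds of the step-wise trajectory classification:
#' step 1 labels vitality from the reporter gradient (surviving below 0.035
#' throughout; dying above 0.8 at the end of the recording), step 2 flags
#' apoptotic chromatin (final relative CCP below 1.1-fold of the first
#' frame), step 3 flags necrotic shrinkage (final relative area at or below
#' 0.75 of the first frame), step 4 flags granulation (final relative CCP at
#' least 0.5 above the first frame), and a 14-fold reporter rule detects
#' apoptotic events.
#'
#' @param surviving_gradient_max step-1 "surviving" gradient bound (0.035).
#' @param dying_end_gradient_min step-1 "dying" end-of-recording gradient
#'   bound (0.8).
#' @param apoptotic_final_ccp_max_ratio step-2 bound (1.1).
#' @param necrotic_final_size_max_ratio step-3 bound (0.75).
#' @param granulating_final_ccp_min_increase step-4 minimum increase (0.5).
#' @param event_fold apoptotic-event threshold on the normalized reporter
#'   (14; strict inequality, a peak of exactly 14 is not an event).
#' @param end_window_frames how many terminal gradients count as "the end of
#'   recording" for the dying rule (default 3, i.e. the last 30 min).
#' @param gradient_mode `"signed"` (default) or `"absolute"` gradients for
#'   the step-1 surviving rule.
#' @return a list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(surviving_gradient_max = 0.035,
                                  dying_end_gradient_min = 0.8,
                                  apoptotic_final_ccp_max_ratio = 1.1,
                                  necrotic_final_size_max_ratio = 0.75,
                                  granulating_final_ccp_min_increase = 0.5,
                                  event_fold = 14,
                                  end_window_frames = 3L,
                                  gradient_mode = c("signed", "absolute")) {
  gradient_mode <- match.arg(gradient_mode)
  vals <- c(surviving_gradient_max, dying_end_gradient_min,
            apoptotic_final_ccp_max_ratio, necrotic_final_size_max_ratio,
            granulating_final_ccp_min_increase, event_fold)
  if (any(vals <= 0)) abort("all thresholds must be > 0.", class = "chromdyn_validation_error")
  if (surviving_gradient_max >= dying_end_gradient_min) {
    abort("surviving_gradient_max must be below dying_end_gradient_min.",
          class = "chromdyn_validation_error")
  }
  structure(list(
    surviving_gradient_max = surviving_gradient_max,
    dying_end_gradient_min = dying_end_gradient_min,
    apoptotic_final_ccp_max_ratio = apoptotic_final_ccp_max_ratio,
    necrotic_final_size_max_ratio = necrotic_final_size_max_ratio,
    granulating_final_ccp_min_increase = granulating_final_ccp_min_increase,
    event_fold = event_fold,
    end_window_frames = as.integer(end_window_frames),
    gradient_mode = gradient_mode
  ), class = "classifier_thresholds")
}

#' Finite-difference gradient of a normalized reporter series
#'
#' @param v numeric series (>= 2 values).
#' @return numeric vector of consecutive differences, length `length(v) - 1`.
#' @export
nucview_gradient <- function(v) {
  if (length(v) < 2L) {
    abort("nucview_gradient() needs at least 2 frames.", class = "chromdyn_validation_error")
  }
  diff(v)
}

#' Step-1 vitality label from the reporter trajectory
#'
#' `"surviving"` when every consecutive gradient of the normalized reporter
#' stays below the surviving bound over the entire recording; `"dying"` when
#' the gradient within the final `end_window_frames` steps exceeds the dying
#' bound (cell death is followed by a steep reporter rise); `"unlabeled"`
#' otherwise (e.g. an isolated mid-recording fluctuation).
#'
#' @param nucview_norm baseline-normalized reporter series.
#' @param thresholds a [classifier_thresholds()].
#' @return one of `"surviving"`, `"dying"`, `"unlabeled"`.
#' @export
label_vitality <- function(nucview_norm, thresholds = classifier_thresholds()) {
  g <- nucview_gradient(nucview_norm)
  if (thresholds$gradient_mode == "absolute") g <- abs(g)
  end_g <- tail(g, thresholds$end_window_frames)
  if (max(end_g) > thresholds$dying_end_gradient_min) return("dying")
  if (all(g < thresholds$surviving_gradient_max)) return("surviving")
  "unlabeled"
}

#' Detect an apoptotic event from the reporter series
#'
#' An apoptotic event is a normalized reporter value strictly above the
#' event threshold (14-fold by default); the event frame is the first
#' crossing.
#'
#' @inheritParams label_vitality
#' @return list with `event` (logical) and `frame` (first crossing index, or
#'   `NA` when no event).
#' @export
detect_apoptotic_event <- function(nucview_norm, thresholds = classifier_thresholds()) {
  hit <- which(nucview_norm > thresholds$event_fold)
  list(event = length(hit) > 0L,
       frame = if (length(hit)) hit[1] else NA_integer_)
}

#' Classify the fate of one nuclear trajectory
#'
#' Applies the five-step rule set to one baseline-normalized trajectory and
#' resolves the final fate with the fixed precedence
#' apoptotic > necrotic > granulating > no_change:
#' apoptotic requires the step-1 "dying" label and the step-2 chromatin flag;
#' necrotic requires the step-3 shrinkage flag, a vitality other than
#' "surviving", and no prior apoptotic assignment; granulating requires the
#' step-4 flag and no prior assignment; everything else is no_change.
#' Trajectories whose ROI contained more than one nucleus in any frame are
#' excluded with a reason code.
#'
#' @param traj tibble for a single cell, ordered by frame, with columns
#'   `ccp_norm`, `area_norm`, `nucview_norm` and optionally `valid`.
#' @param thresholds a [classifier_thresholds()].
#' @return one-row tibble: `fate`, `vitality`, step flags
#'   (`step2_apoptotic`, `step3_necrotic`, `step4_granulating`),
#'   `nucview_event`, `event_frame`, `excluded`, `exclusion_reason`.
#' @export
classify_fate <- function(traj, thresholds = classifier_thresholds()) {
  if (!is.null(traj[["valid"]]) && !all(traj[["valid"]])) {
    return(tibble(fate = NA_character_, vitality = NA_character_,
                  step2_apoptotic = NA, step3_necrotic = NA,
                  step4_granulating = NA, nucview_event = NA,
                  event_frame = NA_integer_, excluded = TRUE,
                  exclusion_reason = "multi_nucleus_roi"))
  }
  ccp_first <- traj$ccp_norm[1]; ccp_last <- traj$ccp_norm[nrow(traj)]
  area_first <- traj$area_norm[1]; area_last <- traj$area_norm[nrow(traj)]
  vitality <- label_vitality(traj$nucview_norm, thresholds)
  step2 <- ccp_last < thresholds$apoptotic_final_ccp_max_ratio * ccp_first
  step3 <- area_last <= thresholds$necrotic_final_size_max_ratio * area_first
  step4 <- (ccp_last - ccp_first) >= thresholds$granulating_final_ccp_min_increase
  fate <- if (vitality == "dying" && step2) {
    "apoptotic"
  } else if (step3 && vitality != "surviving") {
    "necrotic"
  } else if (step4) {
    "granulating"
  } else {
    "no_change"
  }
  ev <- detect_apoptotic_event(traj$nucview_norm, thresholds)
  tibble(fate = fate, vitality = vitality,
         step2_apoptotic = step2, step3_necrotic = step3,
         step4_granulating = step4, nucview_event = ev$event,
         event_frame = ev$frame, excluded = FALSE,
         exclusion_reason = NA_character_)
}

#' Classify every cell of a trajectory table
#'
#' @param trajectories tibble with one row per `cell_id` x frame, ordered by
#'   frame within cell, carrying the normalized columns used by
#'   [classify_fate()].
#' @param thresholds a [classifier_thresholds()].
#' @return tibble with one row per cell: `cell_id` plus the [classify_fate()]
#'   columns.
#' @export
classify_fates <- function(trajectories, thresholds = classifier_thresholds()) {
  trajectories |>
    group_by(.data$cell_id) |>
    dplyr::group_modify(~ classify_fate(.x, thresholds)) |>
    ungroup()
}

#' Align trajectories to the first clear change in nuclear size
#'
#' For each cell, the alignment origin `t0` is the first frame at which the
#' baseline-normalized area deviates from 1 by more than
#' `deviation_threshold` for at least `persistence` consecutive frames.
#' Cells with no such crossing (e.g. controls) carry `NA` and are excluded
#' from aligned averages. Relative time is measured from `t0` in minutes;
#' the deviation direction at `t0` records shrinkage vs swelling.
#'
#' @param trajectories tibble with `cell_id`, `frame`, `time_min`,
#'   `area_norm` (plus any further measurement columns, which are carried
#'   through).
#' @param deviation_threshold area deviation that counts as a clear change
#'   (default 0.1).
#' @param persistence number of consecutive deviating frames required
#'   (default 2).
#' @return list of class `aligned_trajectories`: `$trajectories` (input plus
#'   `rel_time_min`), `$t0` (per-cell `t0_frame`, `t0_time_min`,
#'   `direction`), and the parameters used.
#' @export
align_to_size_change <- function(trajectories, deviation_threshold = 0.1,
                                 persistence = 2L) {
  t0_tbl <- trajectories |>
    group_by(.data$cell_id) |>
    summarise(t0_frame = {
      dev <- abs(.data$area_norm - 1) > deviation_threshold
      runs <- rle(dev)
      ends <- cumsum(runs$lengths)
      hit <- which(runs$values & runs$lengths >= persistence)
      if (length(hit)) as.integer(ends[hit[1]] - runs$lengths[hit[1]] + 1L) else NA_integer_
    }, .groups = "drop")
  tt <- trajectories |>
    select("cell_id", "frame", "time_min") |>
    distinct()
  t0_tbl <- t0_tbl |>
    left_join(tt, by = c("cell_id", t0_frame = "frame")) |>
    rename(t0_time_min = "time_min")
  dir_tbl <- trajectories |>
    left_join(t0_tbl, by = "cell_id") |>
    filter(.data$frame == .data$t0_frame) |>
    mutate(direction = if_else(.data$area_norm > 1, "swelling", "shrinkage")) |>
    select("cell_id", "direction")
  t0_tbl <- left_join(t0_tbl, dir_tbl, by = "cell_id")
  out <- trajectories |>
    left_join(t0_tbl, by = "cell_id") |>
    mutate(rel_time_min = .data$time_min - .data$t0_time_min)
  structure(list(trajectories = out, t0 = t0_tbl,
                 deviation_threshold = deviation_threshold,
                 persistence = as.integer(persistence)),
            class = "aligned_trajectories")
}

#' Mean of an aligned, normalized series at given relative times
#'
#' Averages a measurement column across cells at each relative time point,
#' using only cells with a detected size-change origin.
#'
#' @param aligned an [align_to_size_change()] result.
#' @param var column to average (character, e.g. `"ccp_norm"`).
#' @param rel_time_min optional relative times (minutes) to keep.
#' @return tibble `rel_time_min`, `mean`, `sem`, `n_cells`.
#' @export
aligned_mean <- function(aligned, var, rel_time_min = NULL) {
  df <- aligned$trajectories |>
    filter(!is.na(.data$rel_time_min))
  if (!is.null(rel_time_min)) {
    df <- filter(df, .data$rel_time_min %in% !!rel_time_min)
  }
  df |>
    group_by(.data$rel_time_min) |>
    summarise(mean = mean(.data[[var]]),
              sem = if (n() > 1) sd(.data[[var]]) / sqrt(n()) else 0,
              n_cells = n(), .groups = "drop")
}

#' Summarize fate composition of a culture
#'
#' Counts and percentages per fate (all four categories reported, including
#' zeros), plus the percentage of reporter-positive cells, pooled and - when
#' a `culture` column is present - as a per-culture mean with SEM.
#'
#' @param labels tibble from [classify_fates()] (columns `fate`,
#'   `nucview_event`; optional `culture`). Excluded cells are dropped with a
#'   message.
#' @param n_cultures number of cultures (defaults to the number of distinct
#'   `culture` values, or 1).
#' @param digits decimals for reported percentages (default 1, as printed in
#'   culture summaries; use 2 for finer reporting).
#' @return list of class `culture_summary`: `$fates` (fate, count, percent),
#'   `$nucview` (pooled percent, per-culture mean and SEM), `n_cells`,
#'   `n_cultures`.
#' @export
summarize_culture <- function(labels, n_cultures = NULL, digits = 1) {
  if (nrow(labels) == 0L) {
    abort("summarize_culture(): empty label table.", class = "chromdyn_validation_error")
  }
  if (!is.null(labels[["excluded"]]) && any(labels[["excluded"]])) {
    inform(sprintf("dropping %d excluded cell(s).", sum(labels$excluded)))
    labels <- filter(labels, !.data$excluded)
  }
  n_cells <- nrow(labels)
  fates <- c("apoptotic", "necrotic", "granulating", "no_change")
  counts <- unname(vapply(fates, function(f) sum(labels$fate == f), integer(1)))
  fate_tbl <- tibble(fate = fates, count = counts,
                     percent = round(100 * counts / n_cells, digits))
  if (is.null(n_cultures)) {
    n_cultures <- if (!is.null(labels[["culture"]])) length(unique(labels$culture)) else 1L
  }
  nv <- NULL
  if (!is.null(labels[["nucview_event"]])) {
    pooled <- round(100 * sum(labels$nucview_event) / n_cells, digits)
    per <- NULL
    if (!is.null(labels[["culture"]])) {
      pc <- labels |>
        group_by(.data$culture) |>
        summarise(pct = 100 * sum(.data$nucview_event) / n(), .groups = "drop")
      per <- list(mean = mean(pc$pct),
                  sem = if (nrow(pc) > 1) sd(pc$pct) / sqrt(nrow(pc)) else 0)
    }
    nv <- list(pooled_percent = pooled, per_culture = per)
  }
  structure(list(fates = fate_tbl, nucview = nv,
                 n_cells = n_cells, n_cultures = n_cultures),
            class = "culture_summary")
}

#' @export
print.culture_summary <- function(x, ...) {
  cat(sprintf("<culture_summary> %d cells, %d culture(s)\n", x$n_cells, x$n_cultures))
  print(x$fates)
  if (!is.null(x$nucview)) {
    cat(sprintf("NucView-positive: %.1f%% (pooled)\n", x$nucview$pooled_percent))
  }
  invisible(x)
}

#' Per-stage descriptive summary of frame measurements
#'
#' Mean and SEM of nuclear area, edge count and channel intensities per
#' apoptotic stage (stage labels are taken as given; no inferential
#' statistics). A stage with a single cell reports SEM 0 with
#' `sem_defined = FALSE`; empty stages are omitted with a warning.
#'
#' @param measurements tibble with a `stage` column and measurement columns.
#' @param vars columns to summarize.
#' @return tibble: `stage`, `variable`, `mean`, `sem`, `n`, `sem_defined`.
#' @export
summarize_by_stage <- function(measurements,
                               vars = c("area", "edge_count", "h2b_mean", "nucview_mean")) {
  stages <- sort(unique(measurements$stage))
  present <- intersect(vars, names(measurements))
  if (length(setdiff(vars, present))) {
    warn(paste("missing columns dropped:", paste(setdiff(vars, present), collapse = ", ")))
  }
  empty <- setdiff(1:5, stages)
  if (length(empty)) {
    warn(paste("no cells for stage(s):", paste(empty, collapse = ", ")))
  }
  measurements |>
    tidyr::pivot_longer(dplyr::all_of(present), names_to = "variable") |>
    group_by(.data$stage, .data$variable) |>
    summarise(mean = mean(.data$value),
              sem = if (n() > 1) sd(.data$value) / sqrt(n()) else 0,
              n = n(), sem_defined = n() > 1, .groups = "drop")
}
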
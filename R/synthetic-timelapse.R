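#' Fate program for a synthetic nucleus
#'
#' A fate program specifies the programmed ("ground truth") dynamics of one
#' nucleus over a two-channel time lapse: the relative nuclear-area course,
#' the caspase-reporter (NucView) fold-change course, and the chromatin
#' granulation schedule that drives the measurable edge density. The default
#' courses reproduce the study conditions the analysis was built around:
#' apoptotic nuclei keep a stable size until the event and then shrink to a
#' 0.26 plateau within 30 min; necrotic-like nuclei swell to a 1.17 peak
#' 10 min after onset before collapsing to 0.51 within 2 h; granulation
#' (chromatin compaction) ramps up before the event so that the relative
#' compaction parameter reaches its programmed plateau (1.55 for apoptosis,
#' 1.9 for necrosis) two hours before the size change.
#'
#' @param fate one of `"control"`, `"apoptosis"`, `"necrosis"`,
#'   `"granulating"` (texture ramp without size change or reporter spike).
#' @param event_time_min minutes from acquisition start at which the nuclear
#'   size change begins (ignored for control).
#' @param granulation_onset_min minutes before the event at which granulation
#'   begins ramping (default 240).
#' @param granulation_plateau_min minutes before the event at which the
#'   programmed compaction ratio is reached and held (default 120).
#' @param granulation_ccp_ratio programmed plateau of the relative edge
#'   density; defaults per fate: apoptosis 1.55, necrosis 1.9,
#'   granulating 1.7, control 1.0.
#' @param nucview_peak programmed peak fold-change of the reporter transient
#'   (apoptosis only, default 18; the event-detection threshold is 14).
#' @param noise_sd relative additive intensity noise (default 0.03).
#' @param n_frames,frame_interval_min,n_baseline_frames acquisition contract:
#'   42 frames at 10 min (3 baseline frames + 39), matching a 30-min baseline
#'   followed by 6.5 h of imaging.
#' @return an object of class `fate_program`.
#' @export
fate_program <- function(fate = c("control", "apoptosis", "necrosis", "granulating"),
                         event_time_min = 240,
                         granulation_onset_min = 240,
                         granulation_plateau_min = 120,
                         granulation_ccp_ratio = NULL,
                         nucview_peak = 18,
                         noise_sd = 0.015,
                         n_frames = 42L,
                         frame_interval_min = 10,
                         n_baseline_frames = 3L) {
  fate <- match.arg(fate)
  if (granulation_onset_min < 0 || granulation_plateau_min < 0) {
    abort("granulation timings must be >= 0.", class = "chromdyn_validation_error")
  }
  if (granulation_plateau_min > granulation_onset_min) {
    abort("granulation_plateau_min must not exceed granulation_onset_min.",
          class = "chromdyn_validation_error")
  }
  baseline_end <- n_baseline_frames * frame_interval_min
  if (fate != "control" && event_time_min <= baseline_end) {
    abort("event_time_min must fall after the baseline frames.",
          class = "chromdyn_validation_error")
  }
  ratio <- granulation_ccp_ratio %||%
    switch(fate, control = 1.0, apoptosis = 1.55, necrosis = 1.9, granulating = 1.7)
  if (ratio < 1) abort("granulation_ccp_ratio must be >= 1.", class = "chromdyn_validation_error")
  structure(
    list(fate = fate, event_time_min = event_time_min,
         granulation_onset_min = granulation_onset_min,
         granulation_plateau_min = granulation_plateau_min,
         granulation_ccp_ratio = ratio, nucview_peak = nucview_peak,
         noise_sd = noise_sd, n_frames = as.integer(n_frames),
         frame_interval_min = frame_interval_min,
         n_baseline_frames = as.integer(n_baseline_frames)),
    class = "fate_program"
  )
}

#' Imaging geometry for the synthetic time lapse
#'
#' @param n_px square frame side in pixels (default 96).
#' @param pixel_size_nm physical pixel size (default 111).
#' @param nucleus_radius_px baseline nuclear radius in pixels (default 28,
#'   about 3.1 um at 111 nm/px).
#' @param n_z number of z-planes emitted per frame; 1 (default) emits the
#'   already-projected 2D plane, larger values emit a trivial plane stack
#'   whose maximum projection recovers the 2D image.
#' @return a list of class `timelapse_geometry`.
#' @export
timelapse_geometry <- function(n_px = 96L, pixel_size_nm = 111,
                               nucleus_radius_px = 28, n_z = 1L) {
  structure(list(n_px = as.integer(n_px), pixel_size_nm = pixel_size_nm,
                 nucleus_radius_px = nucleus_radius_px, n_z = as.integer(n_z)),
            class = "timelapse_geometry")
}

# Programmed relative-area course at times t (minutes).
area_course <- function(program, t) {
  e <- program$event_time_min
  switch(program$fate,
    control = ,
    granulating = rep(1, length(t)),
    apoptosis = piecewise(t, c(0, e - 10, e, e + 10, e + 20, e + 30),
                          c(1, 1, 0.85, 0.55, 0.30, 0.26)),
    necrosis = piecewise(t, c(0, e - 10, e, e + 10, e + 120),
                         c(1, 1, 1.13, 1.17, 0.51))
  )
}

# Programmed reporter fold-change course at times t (minutes).
nucview_course <- function(program, t) {
  e <- program$event_time_min
  t_end <- (program$n_frames - 1L) * program$frame_interval_min
  switch(program$fate,
    control = ,
    granulating = rep(1, length(t)),
    apoptosis = {
      pk <- program$nucview_peak
      v <- piecewise(t, c(0, e - 10, e, e + 10, e + 20, e + 30, e + 60),
                     c(1, 1, 0.5 * pk, pk, 0.65 * pk, 0.4 * pk, 0.25 * pk))
      # post-mortem reporter accumulation: steep terminal rise marks "dying"
      v + pmax(0, (t - (t_end - 30)) / 10) * 1.2
    },
    necrosis = piecewise(t, c(0, e - 10, e, e + 10, e + 20),
                         c(1, 1, 1.12, 1.25, 1.30))
  )
}

# Granule-activation schedule: how many granule sites are visible at time t.
# The calibrated response table maps a programmed compaction ratio to the
# site-count ratio that makes the measured CCP ratio match it.
granule_count_course <- function(program, t, n_base, response, end_frac) {
  e <- program$event_time_min
  baseline_end <- program$n_baseline_frames * program$frame_interval_min
  kappa <- stats::approx(response$measured, response$kappa,
                         xout = program$granulation_ccp_ratio, rule = 2)$y
  n_full <- round(n_base * kappa)
  start <- max(baseline_end, e - program$granulation_onset_min)
  full <- max(start + 1e-9, e - program$granulation_plateau_min)
  n <- switch(program$fate,
    control = rep(n_base, length(t)),
    granulating = piecewise(t, c(0, start, full), c(n_base, n_base, n_full)),
    necrosis = piecewise(t, c(0, start, full), c(n_base, n_base, n_full)),
    apoptosis = {
      n_end <- round(n_base * end_frac)
      piecewise(t, c(0, start, full, e + 30, e + 90),
                c(n_base, n_base, n_full, n_full, n_end))
    }
  )
  pmax(0L, as.integer(round(n)))
}

# Render one noiseless chromatin frame: shaded disk + granule spots.
render_nucleus_frame <- function(n_px, cx, cy, radius_px, base_intensity,
                                 granule_u, n_active, granule_amp,
                                 granule_sd_px, mottle, bg = 8) {
  xs <- matrix(rep(seq_len(n_px), each = n_px), n_px)   # column index
  ys <- matrix(rep(seq_len(n_px), times = n_px), n_px)  # row index
  d2 <- (xs - cx)^2 + (ys - cy)^2
  inside <- d2 <= radius_px^2
  img <- matrix(bg, n_px, n_px)
  dome <- base_intensity * (1 - 0.15 * d2 / radius_px^2)
  img[inside] <- dome[inside]
  # low-frequency mottle (fixed per cell) so baseline chromatin is not flat
  if (!is.null(mottle)) {
    for (k in seq_len(nrow(mottle))) {
      mx <- cx + mottle[k, 1] * radius_px
      my <- cy + mottle[k, 2] * radius_px
      fld <- mottle[k, 3] * base_intensity *
        exp(-((xs - mx)^2 + (ys - my)^2) / (2 * (0.35 * radius_px)^2))
      img[inside] <- img[inside] + fld[inside]
    }
  }
  if (n_active > 0) {
    w <- ceiling(4 * granule_sd_px)
    for (k in seq_len(n_active)) {
      gx <- cx + granule_u[k, 1] * radius_px
      gy <- cy + granule_u[k, 2] * radius_px
      i0 <- max(1L, floor(gy - w)); i1 <- min(n_px, ceiling(gy + w))
      j0 <- max(1L, floor(gx - w)); j1 <- min(n_px, ceiling(gx + w))
      ii <- i0:i1; jj <- j0:j1
      spot <- granule_amp * base_intensity *
        exp(-(outer((ii - gy)^2, (jj - gx)^2, `+`)) / (2 * granule_sd_px^2))
      img[ii, jj] <- img[ii, jj] + spot
    }
  }
  img
}

#' Generate a two-channel synthetic nuclear time lapse
#'
#' Renders a nucleus as a shaded disk whose radius follows the programmed
#' relative-area course, with chromatin texture modelled as Gaussian granule
#' spots whose number ramps along the granulation schedule (calibrated so the
#' measured relative compaction parameter matches the programmed ratio), and
#' a reporter channel that follows the programmed NucView course inside the
#' nuclear mask. Identical `(program, geometry, seed)` give bit-identical
#' output.
#'
#' @param program a [fate_program()].
#' @param geometry a [timelapse_geometry()].
#' @param seed integer seed.
#' @return an object of class `timelapse_stack`: numeric arrays `h2b` and
#'   `nucview` (`frames x rows x cols`, or `frames x planes x rows x cols`
#'   when `geometry$n_z > 1`), acquisition metadata, and a `truth` tibble
#'   with per-frame programmed area, reporter level, granule count, and the
#'   programmed event frame.
#' @export
generate_timelapse <- function(program, geometry = timelapse_geometry(), seed = 1L) {
  if (!inherits(program, "fate_program")) {
    abort("`program` must be a fate_program().", class = "chromdyn_validation_error")
  }
  g <- geometry
  t <- (seq_len(program$n_frames) - 1L) * program$frame_interval_min
  a <- area_course(program, t)
  r_max <- g$nucleus_radius_px * sqrt(max(a))
  if (r_max + 3 * .granule_defaults$sd_px + 2 > g$n_px / 2) {
    abort("nucleus exceeds frame bounds at maximum programmed area.",
          class = "chromdyn_geometry_error")
  }
  nv <- nucview_course(program, t)
  n_gr <- granule_count_course(program, t,
                               n_base = .granule_defaults$n_base,
                               response = .granule_defaults$response,
                               end_frac = .granule_defaults$end_frac)
  with_rng(seed, {
    n_sites <- max(n_gr, .granule_defaults$n_base)
    # granule sites in unit-disk coordinates (scale with the nucleus);
    # hard-core placement keeps spot shells from merging, so the edge count
    # grows linearly with the active-site count
    min_sep <- .granule_defaults$min_sep_px / g$nucleus_radius_px
    granule_u <- matrix(0, 0, 2)
    tries <- 0L
    while (nrow(granule_u) < n_sites && tries < 400L * n_sites) {
      tries <- tries + 1L
      th1 <- runif(1, 0, 2 * pi)
      rr1 <- 0.92 * sqrt(runif(1))
      cand <- c(rr1 * cos(th1), rr1 * sin(th1))
      if (nrow(granule_u) == 0L ||
          min((granule_u[, 1] - cand[1])^2 + (granule_u[, 2] - cand[2])^2) >= min_sep^2) {
        granule_u <- rbind(granule_u, cand)
      }
    }
    # small nuclei can jam below the requested site count; fill the remainder
    # without the separation constraint so the schedule stays defined
    while (nrow(granule_u) < n_sites) {
      th1 <- runif(1, 0, 2 * pi)
      rr1 <- 0.92 * sqrt(runif(1))
      granule_u <- rbind(granule_u, c(rr1 * cos(th1), rr1 * sin(th1)))
    }
    mottle <- cbind(x = runif(3, -0.5, 0.5), y = runif(3, -0.5, 0.5),
                    amp = c(0.08, -0.08, 0.06))
    cx <- g$n_px / 2 + 0.5
    cy <- g$n_px / 2 + 0.5
    I0 <- 140
    dims <- if (g$n_z > 1L) c(program$n_frames, g$n_z, g$n_px, g$n_px)
            else c(program$n_frames, g$n_px, g$n_px)
    h2b <- array(0, dims)
    nvch <- array(0, dims)
    zw <- if (g$n_z > 1L) {
      0.7 + 0.3 * exp(-((seq_len(g$n_z) - (g$n_z + 1) / 2)^2) / 2)
    } else 1
    for (f in seq_len(program$n_frames)) {
      r_f <- g$nucleus_radius_px * sqrt(a[f])
      base_f <- I0 * min(4, max(0.5, 1 / a[f]))
      img <- render_nucleus_frame(g$n_px, cx, cy, r_f, base_f, granule_u,
                                  n_gr[f], .granule_defaults$amp,
                                  .granule_defaults$sd_px, mottle)
      xs <- matrix(rep(seq_len(g$n_px), each = g$n_px), g$n_px)
      ys <- matrix(rep(seq_len(g$n_px), times = g$n_px), g$n_px)
      inside <- (xs - cx)^2 + (ys - cy)^2 <= r_f^2
      nvimg <- matrix(2, g$n_px, g$n_px)
      nvimg[inside] <- 20 * nv[f]
      if (g$n_z > 1L) {
        for (p in seq_len(g$n_z)) {
          h2b[f, p, , ] <- pmax(0, zw[p] * img +
            rnorm(g$n_px^2, 0, program$noise_sd * I0))
          nvch[f, p, , ] <- pmax(0, zw[p] * nvimg +
            rnorm(g$n_px^2, 0, program$noise_sd * 20))
        }
      } else {
        h2b[f, , ] <- pmax(0, img + rnorm(g$n_px^2, 0, program$noise_sd * I0))
        nvch[f, , ] <- pmax(0, nvimg + rnorm(g$n_px^2, 0, program$noise_sd * 20))
      }
    }
    event_frame <- if (program$fate %in% c("apoptosis", "necrosis")) {
      which(abs(a - 1) > 1e-12)[1]
    } else NA_integer_
    truth <- tibble(
      frame = seq_len(program$n_frames), time_min = t,
      area_true = a, nucview_true = nv, n_granules = n_gr
    )
    structure(
      list(h2b = h2b, nucview = nvch,
           pixel_size_nm = g$pixel_size_nm,
           frame_interval_min = program$frame_interval_min,
           n_baseline_frames = program$n_baseline_frames,
           truth = truth, fate = program$fate,
           event_frame = event_frame, program = program, seed = seed),
      class = "timelapse_stack"
    )
  })
}

#' @export
print.timelapse_stack <- function(x, ...) {
  cat(sprintf("<timelapse_stack> fate=%s, %d frames @ %g min, %s px\n",
              x$fate, dim(x$h2b)[1], x$frame_interval_min,
              paste(tail(dim(x$h2b), 2), collapse = "x")))
  invisible(x)
}

# Texture constants frozen by the one-time calibration run
# (scripts/calibrate_generator.R): n_base baseline granule sites, spot
# amplitude relative to the nuclear base intensity, spot sd in acquisition
# pixels, the gain mapping a programmed compaction ratio to a site-count
# ratio, and the terminal site fraction for condensed apoptotic nuclei.
.granule_defaults <- list(
  n_base = 15L, amp = 0.8, sd_px = 1.6, min_sep_px = 5, end_frac = 0.15,
  response = list(
    kappa    = c(1, 1.2, 1.4, 1.6, 1.8, 2.0, 2.2, 2.5),
    measured = c(1.0019, 1.1657, 1.3483, 1.4821, 1.6076, 1.7537,
                 1.8650, 2.0197)
  )
)

#' Generate a synthetic culture of nuclei
#'
#' Draws per-cell fates deterministically from the requested mixture by
#' largest-remainder apportionment followed by a seeded shuffle, samples
#' per-cell event times on the frame grid, and renders one time-lapse stack
#' per cell.
#'
#' @param n_cells number of nuclei (>= 1).
#' @param fate_mix named proportions over
#'   `control, apoptosis, necrosis, granulating`; must be nonnegative and sum
#'   to 1.
#' @param noise_sd relative intensity noise passed to every program.
#' @param seed integer seed.
#' @param geometry a [timelapse_geometry()].
#' @param event_time_range range (minutes) from which apoptosis/necrosis
#'   event times are drawn on the 10-min frame grid.
#' @param onset_jitter_sd sd (minutes) of the granulation-onset jitter
#'   (default 20).
#' @return list with `stacks` (list of `timelapse_stack`) and `truth`
#'   (tibble: `cell_id`, `fate`, `event_time_min`, `event_frame`, `seed`).
#' @export
generate_culture <- function(n_cells,
                             fate_mix = c(control = 0.6, apoptosis = 0.2,
                                          necrosis = 0.1, granulating = 0.1),
                             noise_sd = 0.03, seed = 1L,
                             geometry = timelapse_geometry(),
                             event_time_range = c(200, 280),
                             onset_jitter_sd = 20) {
  if (n_cells < 1) abort("n_cells must be >= 1.", class = "chromdyn_validation_error")
  fates <- c("control", "apoptosis", "necrosis", "granulating")
  mix <- setNames(rep(0, 4), fates)
  mix[names(fate_mix)] <- fate_mix
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    abort("fate_mix proportions must be >= 0 and sum to 1.",
          class = "chromdyn_validation_error")
  }
  counts <- largest_remainder(n_cells, mix)
  labels <- rep(fates, counts)
  with_rng(seed, {
    labels <- sample(labels, n_cells)
    grid <- seq(event_time_range[1], event_time_range[2], by = 10)
    event_times <- sample(grid, n_cells, replace = TRUE)
    onsets <- pmax(120, 240 + round(rnorm(n_cells, 0, onset_jitter_sd) / 10) * 10)
  })
  stacks <- vector("list", n_cells)
  truth <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    fate_i <- labels[i]
    ev <- if (fate_i %in% c("apoptosis", "necrosis")) event_times[i] else 240
    prog <- fate_program(fate_i, event_time_min = ev,
                         granulation_onset_min = onsets[i],
                         noise_sd = noise_sd)
    s_i <- child_seed(seed, i)
    stacks[[i]] <- generate_timelapse(prog, geometry, seed = s_i)
    truth[[i]] <- tibble(
      cell_id = i, fate = fate_i,
      event_time_min = if (fate_i %in% c("apoptosis", "necrosis")) ev else NA_real_,
      event_frame = stacks[[i]]$event_frame, seed = s_i
    )
  }
  list(stacks = stacks, truth = bind_rows(truth))
}
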
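#' Filtering and merging parameters for SMLM post-processing
#'
#' @param fwhm_min_nm,fwhm_max_nm retained full-width-at-half-maximum range
#'   in nm (65-225; localizations strictly outside are discarded, boundary
#'   values are kept).
#' @param fwhm_factor conversion from fitted Gaussian sigma to FWHM
#'   (default `2*sqrt(2*log(2))`); set to 1 when the table already carries
#'   FWHM values in its `sigma_nm` column.
#' @param merge_max_distance_nm maximum spatial distance for linking blinking
#'   events into one molecule (20 nm).
#' @param merge_max_off_frames maximum number of dark frames tolerated inside
#'   one molecule's emission (1).
#' @param frames_per_molecule maximum frames per merged molecule
#'   (`Inf` = unlimited).
#' @return a list of class `filter_merge_params`.
#' @export
filter_merge_params <- function(fwhm_min_nm = 65, fwhm_max_nm = 225,
                                fwhm_factor = 2 * sqrt(2 * log(2)),
                                merge_max_distance_nm = 20,
                                merge_max_off_frames = 1L,
                                frames_per_molecule = Inf) {
  if (!(fwhm_min_nm > 0 && fwhm_min_nm < fwhm_max_nm)) {
    abort("need 0 < fwhm_min_nm < fwhm_max_nm.", class = "chromdyn_validation_error")
  }
  if (merge_max_distance_nm <= 0) {
    abort("merge_max_distance_nm must be > 0.", class = "chromdyn_validation_error")
  }
  structure(list(fwhm_min_nm = fwhm_min_nm, fwhm_max_nm = fwhm_max_nm,
                 fwhm_factor = fwhm_factor,
                 merge_max_distance_nm = merge_max_distance_nm,
                 merge_max_off_frames = as.integer(merge_max_off_frames),
                 frames_per_molecule = frames_per_molecule),
            class = "filter_merge_params")
}

# ThunderSTORM-style header <-> canonical column names
.loc_header <- c(frame = "frame", x_nm = "x [nm]", y_nm = "y [nm]",
                 sigma_nm = "sigma [nm]", intensity_photons = "intensity [photon]")

#' Read an SMLM localization table (CSV)
#'
#' Reads a ThunderSTORM-dialect localization CSV: comma-separated, period
#' decimal, quoted header names with unit suffixes (`"frame"`, `"x [nm]"`,
#' `"y [nm]"`, `"sigma [nm]"`, `"intensity [photon]"`). Unknown columns
#' (e.g. `"uncertainty [nm]"`) are preserved. Rows are ordered by frame,
#' keeping input order within a frame.
#'
#' @param path file path.
#' @return tibble with canonical columns `frame`, `x_nm`, `y_nm`, `sigma_nm`,
#'   `intensity_photons`, plus any extra columns.
#' @export
read_localization_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "chromdyn_format_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nm <- names(df)
  for (canon in names(.loc_header)) {
    if (.loc_header[[canon]] %in% nm) {
      names(df)[nm == .loc_header[[canon]]] <- canon
      nm <- names(df)
    }
  }
  missing <- setdiff(names(.loc_header), names(df))
  if (length(missing)) {
    abort(sprintf("missing required column(s): %s",
                  paste(.loc_header[missing], collapse = ", ")),
          class = "chromdyn_format_error")
  }
  for (col in c("x_nm", "y_nm", "sigma_nm", "intensity_photons", "frame")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        abort(sprintf("non-numeric value in `%s` at data line %d",
                      .loc_header[[col]], bad[1]),
              class = "chromdyn_format_error")
      }
      df[[col]] <- vn
    }
  }
  bad <- which(!is.finite(df$x_nm) | !is.finite(df$y_nm))
  if (length(bad)) {
    abort(sprintf("non-finite coordinate at data line %d", bad[1]),
          class = "chromdyn_format_error")
  }
  as_tibble(df[order(df$frame), , drop = FALSE])
}

#' Write an SMLM localization table (CSV)
#'
#' Inverse of [read_localization_csv()]: canonical columns are written under
#' their ThunderSTORM-style header names; extra columns keep their names.
#'
#' @param table localization tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localization_csv <- function(table, path) {
  out <- table
  for (canon in names(.loc_header)) {
    if (canon %in% names(out)) {
      names(out)[names(out) == canon] <- .loc_header[[canon]]
    }
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Filter localizations by full width at half maximum
#'
#' Discards localizations whose FWHM (converted from the fitted Gaussian
#' sigma) is strictly smaller than `fwhm_min_nm` or strictly bigger than
#' `fwhm_max_nm`; such widths are incompatible with the theoretical PSF and
#' flag false localizations.
#'
#' @param table localization tibble with `sigma_nm`.
#' @param params a [filter_merge_params()].
#' @return filtered tibble.
#' @export
filter_by_fwhm <- function(table, params = filter_merge_params()) {
  fwhm <- params$fwhm_factor * table$sigma_nm
  table[fwhm >= params$fwhm_min_nm & fwhm <= params$fwhm_max_nm, , drop = FALSE]
}

#' Merge repeated blinking events into molecules
#'
#' Greedy frame-ordered linking: localizations of each frame join the nearest
#' open chain whose last position lies within `merge_max_distance_nm` and
#' whose last frame is at most `1 + merge_max_off_frames` frames back
#' (strictly earlier frames only; each chain accepts one localization per
#' frame). Assignment is deterministic: candidate pairs are processed by
#' increasing distance with input order as tie-break. Unmatched localizations
#' open new chains. A merged molecule reports the intensity-weighted mean
#' position and sigma, the first frame, the summed intensity and the number
#' of merged events.
#'
#' @param table localization tibble (sorted internally by frame if needed,
#'   with a notice).
#' @param params a [filter_merge_params()].
#' @return tibble of molecules: `frame`, `x_nm`, `y_nm`, `sigma_nm`,
#'   `intensity_photons`, `n_events` (+ `molecule_id` of the first event when
#'   present). Row count never exceeds the input's.
#' @export
merge_blinking <- function(table, params = filter_merge_params()) {
  n <- nrow(table)
  empty <- tibble(frame = integer(), x_nm = double(), y_nm = double(),
                  sigma_nm = double(), intensity_photons = double(),
                  n_events = integer())
  if (n == 0L) return(empty)
  if (is.unsorted(table$frame)) {
    inform("merge_blinking(): input not sorted by frame; sorting.")
    table <- table[order(table$frame), , drop = FALSE]
  }
  x <- table$x_nm; y <- table$y_nm; fr <- as.integer(table$frame)
  w <- table[["intensity_photons"]]
  if (is.null(w) || all(!is.finite(w)) || all(w <= 0)) w <- rep(1, n)
  w[!is.finite(w) | w <= 0] <- 1
  sg <- table[["sigma_nm"]] %||% rep(NA_real_, n)
  mid <- table[["molecule_id"]] %||% rep(NA, n)
  max_gap <- 1L + params$merge_max_off_frames
  dmax <- params$merge_max_distance_nm

  # chain state (grows amortised)
  cap <- 256L
  c_x <- c_y <- c_wx <- c_wy <- c_w <- c_wsg <- numeric(cap)
  c_first <- c_last <- c_n <- c_ord <- integer(cap)
  c_mid <- vector(typeof(mid), cap)
  n_chain <- 0L
  open_idx <- integer(0)
  grow <- function() {
    cap2 <- 2L * cap
    for (nmv in c("c_x", "c_y", "c_wx", "c_wy", "c_w", "c_wsg")) {
      v <- get(nmv, inherits = TRUE); length(v) <- cap2
      assign(nmv, v, inherits = TRUE)
    }
    for (nmv in c("c_first", "c_last", "c_n", "c_ord")) {
      v <- get(nmv, inherits = TRUE); length(v) <- cap2
      assign(nmv, v, inherits = TRUE)
    }
    v <- get("c_mid", inherits = TRUE); length(v) <- cap2
    assign("c_mid", v, inherits = TRUE)
    assign("cap", cap2, inherits = TRUE)
  }
  new_chain <- function(i) {
    if (n_chain == cap) grow()
    n_chain <<- n_chain + 1L
    c_x[n_chain] <<- x[i]; c_y[n_chain] <<- y[i]
    c_wx[n_chain] <<- w[i] * x[i]; c_wy[n_chain] <<- w[i] * y[i]
    c_w[n_chain] <<- w[i]
    c_wsg[n_chain] <<- if (is.na(sg[i])) 0 else w[i] * sg[i]
    c_first[n_chain] <<- fr[i]; c_last[n_chain] <<- fr[i]
    c_n[n_chain] <<- 1L; c_ord[n_chain] <<- i
    c_mid[n_chain] <<- mid[i]
    n_chain
  }
  frames <- split(seq_len(n), fr)
  for (fset in frames) {
    f <- fr[fset[1]]
    # drop chains too old to ever match again
    open_idx <- open_idx[c_last[open_idx] >= f - max_gap]
    cand <- open_idx[c_last[open_idx] < f]  # strictly earlier frames only
    if (params$frames_per_molecule < Inf) {
      cand <- cand[c_n[cand] < params$frames_per_molecule]
    }
    assigned_loc <- rep(FALSE, length(fset))
    if (length(cand)) {
      k <- min(length(cand), length(fset) + 4L)
      nn <- FNN::get.knnx(cbind(c_x[cand], c_y[cand]),
                          cbind(x[fset], y[fset]), k = k)
      pair_loc <- rep(seq_along(fset), k)
      pair_chain <- as.vector(nn$nn.index)
      pair_d <- as.vector(nn$nn.dist)
      ok <- pair_d <= dmax
      if (any(ok)) {
        ord <- order(pair_d[ok], pair_loc[ok])
        pl <- pair_loc[ok][ord]; pc <- pair_chain[ok][ord]
        used_chain <- rep(FALSE, length(cand))
        for (p in seq_along(pl)) {
          li <- pl[p]; ci <- pc[p]
          if (assigned_loc[li] || used_chain[ci]) next
          assigned_loc[li] <- TRUE; used_chain[ci] <- TRUE
          i <- fset[li]; ch <- cand[ci]
          c_wx[ch] <- c_wx[ch] + w[i] * x[i]
          c_wy[ch] <- c_wy[ch] + w[i] * y[i]
          c_w[ch] <- c_w[ch] + w[i]
          c_wsg[ch] <- c_wsg[ch] + if (is.na(sg[i])) 0 else w[i] * sg[i]
          c_x[ch] <- x[i]; c_y[ch] <- y[i]  # chain tracks its latest position
          c_last[ch] <- f; c_n[ch] <- c_n[ch] + 1L
        }
      }
    }
    for (li in which(!assigned_loc)) {
      open_idx <- c(open_idx, new_chain(fset[li]))
    }
  }
  ix <- seq_len(n_chain)
  out <- tibble(
    frame = c_first[ix],
    x_nm = c_wx[ix] / c_w[ix],
    y_nm = c_wy[ix] / c_w[ix],
    sigma_nm = c_wsg[ix] / c_w[ix],
    intensity_photons = c_w[ix],
    n_events = c_n[ix]
  )
  if (!all(is.na(mid))) out$molecule_id <- c_mid[ix]
  out[order(out$frame, c_ord[ix]), , drop = FALSE]
}

#' Crop localizations to a rectangular nuclear region
#'
#' Retains rows whose coordinates lie inside the closed rectangle
#' `x_range` x `y_range` (boundary points are kept).
#'
#' @param table localization tibble.
#' @param x_range,y_range numeric length-2 ranges in nm.
#' @return filtered tibble (warns when empty).
#' @export
crop_to_nucleus <- function(table, x_range, y_range) {
  if (any(!is.finite(c(x_range, y_range)))) {
    abort("crop ranges must be finite.", class = "chromdyn_validation_error")
  }
  out <- table[table$x_nm >= min(x_range) & table$x_nm <= max(x_range) &
               table$y_nm >= min(y_range) & table$y_nm <= max(y_range), , drop = FALSE]
  if (nrow(out) == 0L) warn("crop_to_nucleus(): no localizations retained.")
  out
}

#' Transform localizations to polar coordinates
#'
#' Uses the (unweighted) centre of mass of all localizations of the nucleus
#' as the origin, so differently positioned nuclei become comparable. Adds
#' `r_nm` (radius) and `theta` (atan2 convention, (-pi, pi]) columns; the
#' origin is stored in the `origin` attribute.
#'
#' @param table localization tibble (>= 1 row).
#' @return the input tibble with `r_nm` and `theta`.
#' @export
to_polar <- function(table) {
  if (nrow(table) == 0L) {
    abort("to_polar(): empty table.", class = "chromdyn_validation_error")
  }
  cx <- mean(table$x_nm); cy <- mean(table$y_nm)
  out <- mutate(table,
                r_nm = sqrt((.data$x_nm - cx)^2 + (.data$y_nm - cy)^2),
                theta = atan2(.data$y_nm - cy, .data$x_nm - cx))
  attr(out, "origin") <- c(x = cx, y = cy)
  out
}
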
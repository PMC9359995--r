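#' Segment the nucleus in a chromatin-channel image
#'
#' Thresholds the chromatin (H2B) channel with Otsu's method, fills holes,
#' labels 8-connected components and discards components below a minimum
#' size floor (debris). The mask is the union of the retained components;
#' regions of interest containing more than one retained component are
#' flagged so that downstream classification can exclude them.
#'
#' @param image numeric matrix (chromatin channel, after z-projection and
#'   upsampling).
#' @param min_size minimum component area in pixels (default 50).
#' @param min_contrast minimum foreground/background mean-intensity ratio for
#'   a usable segmentation (default 1.5); below it the field is treated as
#'   background-only (Otsu always splits something, even pure noise).
#' @return a list with `mask` (logical matrix), `n_components` (integer) and
#'   `empty` (TRUE when no component survives the size floor or the field
#'   lacks contrast).
#' @export
segment_nucleus <- function(image, min_size = 50L, min_contrast = 1.5) {
  if (!is.matrix(image)) abort("segment_nucleus() expects a matrix.", class = "chromdyn_error")
  if (max(image) == min(image)) {
    abort("segment_nucleus(): constant image, Otsu threshold undefined.",
          class = "chromdyn_segmentation_error")
  }
  th <- otsu_threshold(as.vector(image))
  mask <- image > th
  if (!any(mask) || !any(!mask) ||
      mean(image[mask]) < min_contrast * max(mean(image[!mask]), 1e-12)) {
    return(list(mask = mask & FALSE, n_components = 0L, empty = TRUE))
  }
  mask <- EBImage::fillHull(mask * 1) > 0
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  if (length(keep) == 0L) {
    return(list(mask = matrix(FALSE, nrow(image), ncol(image)),
                n_components = 0L, empty = TRUE))
  }
  list(mask = matrix(lab %in% keep, nrow(image), ncol(image)),
       n_components = length(keep), empty = FALSE)
}

#' Count Sobel edge pixels inside a nuclear mask
#'
#' Computes the 3x3 Sobel gradient magnitude and classifies as "edges" the
#' in-mask pixels whose magnitude exceeds an Otsu threshold computed on the
#' within-mask magnitudes, making the edge count invariant to global
#' intensity scaling. The mask is first eroded by the Sobel reach
#' (`erode_px`) so the nuclear boundary itself is never counted: the
#' compaction parameter measures internal texture, and a uniform disk yields
#' an edge count of exactly zero.
#'
#' @param image numeric matrix (chromatin channel).
#' @param mask logical matrix (from [segment_nucleus()]).
#' @param erode_px erosion radius in pixels before edge counting (default 2,
#'   matching the Sobel reach after 2x upsampling).
#' @param threshold optional fixed gradient threshold; when `NULL` (default)
#'   Otsu's method on within-mask magnitudes is used.
#' @return list with `edge_count` (integer) and `edge_map` (logical matrix).
#' @export
count_edges <- function(image, mask, erode_px = 2L, threshold = NULL) {
  if (!any(mask)) abort("count_edges(): empty mask.", class = "chromdyn_error")
  core <- erode_box(mask, erode_px)
  mag <- sobel_magnitude(image)
  vals <- mag[core]
  if (length(vals) == 0L || max(vals) == min(vals)) {
    return(list(edge_count = 0L, edge_map = core & FALSE))
  }
  th <- threshold %||% otsu_threshold(vals)
  edge_map <- core & (mag > th)
  list(edge_count = sum(edge_map), edge_map = edge_map)
}

#' Measure one time-lapse frame
#'
#' Composes the per-frame measurement chain: z-projection, upsampling by the
#' pixel factor, Otsu segmentation of the chromatin channel, Sobel edge
#' counting, and reporter intensity. The chromatin compaction parameter (CCP)
#' is the number of edge pixels divided by the mask area, so
#' `ccp * area == edge_count` holds exactly for every frame.
#'
#' @param h2b chromatin channel: matrix or `planes x rows x cols` array.
#' @param nucview caspase-reporter channel, same shape as `h2b`.
#' @param pixel_factor integer upsampling factor (default 2).
#' @param z_method projection method, see [z_project()].
#' @param min_size,sobel_threshold passed to [segment_nucleus()] and
#'   [count_edges()].
#' @param erode_px erosion before edge counting; the default
#'   `2 * pixel_factor + 1` covers the Sobel reach plus the bicubic
#'   interpolation transition at the mask boundary, so a uniform disk
#'   measures `ccp = 0` through the full chain.
#' @return a one-row tibble: `area`, `edge_count`, `ccp`, `nucview_mean`,
#'   `h2b_mean`, `n_components`, `valid`. `valid` is `FALSE` when the ROI
#'   holds more or fewer than one nucleus.
#' @export
measure_frame <- function(h2b, nucview, pixel_factor = 2L, z_method = "max",
                          min_size = 50L, erode_px = NULL, sobel_threshold = NULL) {
  erode_px <- erode_px %||% (2L * as.integer(pixel_factor) + 1L)
  h2b_p <- z_project(h2b, z_method)
  nv_p <- z_project(nucview, z_method)
  if (!all(dim(h2b_p) == dim(nv_p))) {
    abort("measure_frame(): channels must share shape.", class = "chromdyn_error")
  }
  h2b_u <- upsample(h2b_p, pixel_factor)
  nv_u <- upsample(nv_p, pixel_factor)
  seg <- segment_nucleus(h2b_u, min_size = min_size)
  if (seg$empty) {
    return(tibble(area = 0L, edge_count = 0L, ccp = NA_real_,
                  nucview_mean = NA_real_, h2b_mean = NA_real_,
                  n_components = 0L, valid = FALSE))
  }
  ec <- count_edges(h2b_u, seg$mask, erode_px = erode_px, threshold = sobel_threshold)
  area <- sum(seg$mask)
  tibble(
    area = as.integer(area),
    edge_count = as.integer(ec$edge_count),
    ccp = ec$edge_count / area,
    nucview_mean = mean(nv_u[seg$mask]),
    h2b_mean = mean(h2b_u[seg$mask]),
    n_components = as.integer(seg$n_components),
    valid = seg$n_components == 1L
  )
}

#' Measure every frame of a time-lapse stack
#'
#' @param stack a `timelapse_stack` (see [generate_timelapse()]) or a list
#'   with numeric arrays `h2b` and `nucview` of shape
#'   `frames x rows x cols` (or `frames x planes x rows x cols`) and a
#'   `frame_interval_min` element.
#' @param ... passed to [measure_frame()].
#' @return tibble with one row per frame: `frame`, `time_min`, plus the
#'   [measure_frame()] columns.
#' @export
measure_stack <- function(stack, ...) {
  h2b <- stack$h2b
  nv <- stack$nucview
  nd <- length(dim(h2b))
  if (!nd %in% c(3L, 4L)) {
    abort("measure_stack(): expected frames x [planes x] rows x cols arrays.",
          class = "chromdyn_error")
  }
  n_frames <- dim(h2b)[1]
  dt <- stack$frame_interval_min %||% 10
  take <- function(a, f) {
    if (length(dim(a)) == 3L) a[f, , ] else a[f, , , ]
  }
  rows <- lapply(seq_len(n_frames), function(f) {
    measure_frame(take(h2b, f), take(nv, f), ...)
  })
  out <- bind_rows(rows)
  out$frame <- seq_len(n_frames)
  out$time_min <- (out$frame - 1L) * dt
  select(out, "frame", "time_min", dplyr::everything())
}

#' Baseline-normalize a per-frame trajectory
#'
#' Divides each measured series by the mean of its first `n_baseline` frames
#' (the pre-treatment baseline), adding `area_norm`, `edge_norm`, `ccp_norm`
#' and `nucview_norm` columns. By construction the mean of each normalized
#' series over the baseline frames is 1 to machine precision.
#'
#' @param traj tibble from [measure_stack()] (columns `area`, `edge_count`,
#'   `ccp`, `nucview_mean`).
#' @param n_baseline number of baseline frames (default 3).
#' @return the input tibble with `*_norm` columns appended.
#' @export
normalize_trajectory <- function(traj, n_baseline = 3L) {
  if (nrow(traj) < n_baseline) {
    abort(sprintf("normalize_trajectory(): need >= %d frames.", n_baseline),
          class = "chromdyn_error")
  }
  pairs <- c(area = "area", edge_count = "edge", ccp = "ccp", nucview_mean = "nucview")
  for (col in names(pairs)) {
    b <- mean(traj[[col]][seq_len(n_baseline)])
    if (!is.finite(b) || b <= 0) {
      abort(sprintf("normalize_trajectory(): baseline mean of `%s` is not positive.", col),
            class = "chromdyn_normalization_error")
    }
    traj[[paste0(pairs[[col]], "_norm")]] <- traj[[col]] / b
  }
  traj
}
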
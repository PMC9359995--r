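# Small image fixtures built in code.

disk_image <- function(n_px, radius, centre = (n_px + 1) / 2,
                       fg = 200, bg = 10) {
  xs <- matrix(rep(seq_len(n_px), each = n_px), n_px)
  ys <- matrix(rep(seq_len(n_px), times = n_px), n_px)
  img <- matrix(bg, n_px, n_px)
  img[(xs - centre)^2 + (ys - centre)^2 <= radius^2] <- fg
  img
}

# direct 3x3 Sobel convolution with replicate padding, written as plain loops
sobel_magnitude_loop <- function(img) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # column gradient
  ky <- t(kx)
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      gx <- 0; gy <- 0
      for (di in -1:1) {
        for (dj in -1:1) {
          ii <- min(max(i + di, 1), n)
          jj <- min(max(j + dj, 1), m)
          gx <- gx + img[ii, jj] * kx[di + 2, dj + 2]
          gy <- gy + img[ii, jj] * ky[di + 2, dj + 2]
        }
      }
      out[i, j] <- sqrt(gx^2 + gy^2)
    }
  }
  out
}

# tiny localization table builder
loc_table <- function(frame, x, y, sigma = 60, intensity = 1) {
  tibble::tibble(frame = frame, x_nm = x, y_nm = y,
                 sigma_nm = rep_len(sigma, length(frame)),
                 intensity_photons = rep_len(intensity, length(frame)))
}

# measure + normalize a list of stacks into one trajectory table
measure_culture <- function(stacks) {
  out <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    tr <- normalize_trajectory(measure_stack(stacks[[i]]))
    tr$cell_id <- i
    out[[i]] <- tr
  }
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
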
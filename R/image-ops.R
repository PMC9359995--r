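#' Maximum-intensity z-projection
#'
#' Collapses a stack of z-planes onto a single image. The default maximum
#' projection preserves the contrast of bright chromatin granules across
#' planes; a mean projection is available for integrating dim signals.
#'
#' @param stack numeric array `planes x rows x cols`, or a single matrix
#'   (returned unchanged).
#' @param method `"max"` (default) or `"mean"`.
#' @return a `rows x cols` numeric matrix.
#' @export
z_project <- function(stack, method = c("max", "mean")) {
  method <- match.arg(method)
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[1] < 1L) {
    abort("z_project() expects a planes x rows x cols array with >= 1 plane.",
          class = "chromdyn_error")
  }
  planes <- lapply(seq_len(dim(stack)[1]), function(p) stack[p, , ])
  if (method == "max") {
    out <- Reduce(pmax, planes)
  } else {
    out <- Reduce(`+`, planes) / length(planes)
  }
  matrix(out, nrow = dim(stack)[2], ncol = dim(stack)[3])
}

# Catmull-Rom cubic interpolation kernel (a = -1/2); reproduces constants and
# linear ramps exactly, which anchors the upsampling tests.
cubic_kernel <- function(t) {
  t <- abs(t)
  ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
         ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
}

# Interpolation weight matrix mapping n input samples to n*factor outputs.
cubic_weights <- function(n, factor) {
  n_out <- n * factor
  # output pixel centres in input coordinates
  x <- (seq_len(n_out) - 0.5) / factor + 0.5
  base <- floor(x)
  w <- matrix(0, n_out, n)
  for (k in -1:2) {
    j <- base + k
    jc <- pmin(pmax(j, 1L), n) # replicate-pad at the borders
    wt <- cubic_kernel(x - j)
    w[cbind(seq_len(n_out), jc)] <- w[cbind(seq_len(n_out), jc)] + wt
  }
  w
}

#' Upsample an image by an integer factor (bicubic)
#'
#' Enlarges an image with separable bicubic (Catmull-Rom) interpolation.
#' The compaction pipeline upsamples by a pixel factor of 2 before edge
#' detection so that single-pixel intensity transitions are resolved by the
#' 3x3 Sobel operator.
#'
#' @param image numeric matrix.
#' @param factor integer >= 1; 1 returns the input unchanged.
#' @return a `nrow(image)*factor x ncol(image)*factor` matrix.
#' @export
upsample <- function(image, factor = 2L) {
  if (!is.matrix(image)) abort("upsample() expects a matrix.", class = "chromdyn_error")
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) {
    abort("`factor` must be an integer >= 1.", class = "chromdyn_error")
  }
  if (factor == 1L) return(image)
  wr <- cubic_weights(nrow(image), factor)
  wc <- cubic_weights(ncol(image), factor)
  wr %*% image %*% t(wc)
}

#' Sobel gradient magnitude
#'
#' 3x3 Sobel gradient magnitude with replicate padding at the image border.
#'
#' @param image numeric matrix.
#' @return matrix of `sqrt(gx^2 + gy^2)` of the same size.
#' @export
sobel_magnitude <- function(image) {
  if (!is.matrix(image)) abort("sobel_magnitude() expects a matrix.", class = "chromdyn_error")
  n <- nrow(image); m <- ncol(image)
  p <- matrix(0, n + 2L, m + 2L)
  p[2:(n + 1L), 2:(m + 1L)] <- image
  p[1L, ] <- p[2L, ]; p[n + 2L, ] <- p[n + 1L, ]
  p[, 1L] <- p[, 2L]; p[, m + 2L] <- p[, m + 1L]
  s <- function(di, dj) p[(1L + di):(n + di), (1L + dj):(m + dj)]
  gx <- (s(0L, 2L) + 2 * s(1L, 2L) + s(2L, 2L)) -
        (s(0L, 0L) + 2 * s(1L, 0L) + s(2L, 0L))
  gy <- (s(2L, 0L) + 2 * s(2L, 1L) + s(2L, 2L)) -
        (s(0L, 0L) + 2 * s(0L, 1L) + s(0L, 2L))
  sqrt(gx^2 + gy^2)
}

# Merge 4-connected labels that touch diagonally, yielding 8-connected
# components (EBImage::bwlabel is 4-connected).
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  repeat {
    n <- nrow(lab); m <- ncol(lab)
    a1 <- lab[-n, -m]; b1 <- lab[-1, -1]   # down-right diagonal
    a2 <- lab[-n, -1]; b2 <- lab[-1, -m]   # down-left diagonal
    pairs <- rbind(
      cbind(a1[a1 > 0L & b1 > 0L & a1 != b1], b1[a1 > 0L & b1 > 0L & a1 != b1]),
      cbind(a2[a2 > 0L & b2 > 0L & a2 != b2], b2[a2 > 0L & b2 > 0L & a2 != b2])
    )
    if (nrow(pairs) == 0L) break
    pairs <- unique(t(apply(pairs, 1L, sort)))
    for (i in seq_len(nrow(pairs))) {
      lab[lab == pairs[i, 2L]] <- pairs[i, 1L]
    }
  }
  # compact label ids
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) lab <- matrix(match(lab, c(0L, ids), nomatch = 0L) - 1L, nrow(lab))
  lab
}

# Binary erosion by a (2r+1) x (2r+1) box, so that every retained pixel has a
# full Sobel neighbourhood strictly inside the mask.
erode_box <- function(mask, r = 2L) {
  if (r < 1L) return(mask)
  m <- mask
  out <- mask
  n <- nrow(m); mm <- ncol(m)
  for (di in -r:r) {
    ri <- pmin(pmax(seq_len(n) + di, 1L), n)
    for (dj in -r:r) {
      cj <- pmin(pmax(seq_len(mm) + dj, 1L), mm)
      out <- out & m[ri, cj, drop = FALSE]
    }
  }
  # border pixels can never have a full interior neighbourhood
  out[seq_len(r), ] <- FALSE; out[(n - r + 1L):n, ] <- FALSE
  out[, seq_len(r)] <- FALSE; out[, (mm - r + 1L):mm] <- FALSE
  out
}
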
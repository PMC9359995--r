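#' Polygon area by Gauss's (shoelace) formula
#'
#' Area of a simple polygon from its ordered vertices:
#' `0.5 * |sum(x_i * y_{i+1} - x_{i+1} * y_i)|`.
#'
#' @param x,y vertex coordinates in order (either orientation).
#' @return the enclosed area.
#' @examples
#' shoelace_area(c(0, 1, 1, 0), c(0, 0, 1, 1)) # unit square
#' @export
shoelace_area <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y)) {
    abort("shoelace_area() needs >= 3 paired vertices.", class = "chromdyn_validation_error")
  }
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  0.5 * abs(sum(x * yn - xn * y))
}

# Circumcenters of triangles (p1, p2, p3), vectorized over rows.
circumcenters <- function(x1, y1, x2, y2, x3, y3) {
  d <- 2 * (x1 * (y2 - y3) + x2 * (y3 - y1) + x3 * (y1 - y2))
  s1 <- x1^2 + y1^2; s2 <- x2^2 + y2^2; s3 <- x3^2 + y3^2
  ux <- (s1 * (y2 - y3) + s2 * (y3 - y1) + s3 * (y1 - y2)) / d
  uy <- (s1 * (x3 - x2) + s2 * (x1 - x3) + s3 * (x2 - x1)) / d
  cbind(ux, uy)
}

#' Per-localization Voronoi densities
#'
#' Computes the planar Voronoi tessellation of the localization positions and
#' assigns to every localization the inverse area of its Voronoi cell as its
#' local density. Cell polygons are assembled from the circumcenters of the
#' incident Delaunay triangles (ordered around the generator) and their areas
#' are computed with Gauss's area formula ([shoelace_area()]). Generators on
#' the convex hull own unbounded cells; they are flagged
#' `boundary_excluded` and carry no density. Exactly duplicated coordinates
#' are perturbed by at most 1e-6 nm (with a warning) because the tessellation
#' requires distinct generators.
#'
#' @param table localization tibble with `x_nm`, `y_nm` (>= 4 non-collinear
#'   points).
#' @return the input tibble with `cell_area_nm2`, `raw_density`
#'   (`1/cell_area_nm2`), `boundary_excluded` and `n_loc` (the localization
#'   count of the nucleus, used downstream for count normalization); the
#'   number of excluded localizations is reported in the `n_excluded`
#'   attribute.
#' @export
voronoi_density <- function(table) {
  n <- nrow(table)
  if (n < 4L) {
    abort("voronoi_density() needs >= 4 localizations.", class = "chromdyn_validation_error")
  }
  x <- as.double(table$x_nm); y <- as.double(table$y_nm)
  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    warn(sprintf("voronoi_density(): %d duplicated coordinate(s) perturbed by <= 1e-6 nm.",
                 sum(dup)))
    i <- which(dup)
    x[i] <- x[i] + 1e-6 * cos(2.399963 * i)  # deterministic golden-angle offsets
    y[i] <- y[i] + 1e-6 * sin(2.399963 * i)
  }
  tm <- tryCatch(
    interp::tri.mesh(x, y),
    error = function(e) abort(paste("Voronoi tessellation failed:", conditionMessage(e)),
                              class = "chromdyn_tessellation_error")
  )
  tri <- interp::triangles(tm)
  if (is.null(dim(tri)) || nrow(tri) == 0L) {
    abort("Voronoi tessellation degenerate (collinear input?).",
          class = "chromdyn_tessellation_error")
  }
  hull <- interp::convex.hull(tm)
  on_hull <- rep(FALSE, n)
  on_hull[hull$i] <- TRUE

  cc <- circumcenters(x[tri[, 1]], y[tri[, 1]],
                      x[tri[, 2]], y[tri[, 2]],
                      x[tri[, 3]], y[tri[, 3]])
  # one record per (triangle, vertex) incidence
  v <- c(tri[, 1], tri[, 2], tri[, 3])
  ccx <- rep(cc[, 1], 3L)
  ccy <- rep(cc[, 2], 3L)
  keep <- !on_hull[v]
  v <- v[keep]; ccx <- ccx[keep]; ccy <- ccy[keep]
  # order each generator's circumcenters by angle -> convex cell polygon
  ang <- atan2(ccy - y[v], ccx - x[v])
  ord <- order(v, ang)
  v <- v[ord]; ccx <- ccx[ord]; ccy <- ccy[ord]
  # wrap-around "next vertex" index within each generator's block
  grp_start <- which(c(TRUE, v[-1L] != v[-length(v)]))
  grp_len <- diff(c(grp_start, length(v) + 1L))
  nxt <- seq_along(v) + 1L
  nxt[grp_start + grp_len - 1L] <- grp_start
  cross <- ccx * ccy[nxt] - ccx[nxt] * ccy
  area2 <- rowsum(cross, v, reorder = TRUE)
  gen_ids <- as.integer(rownames(area2))
  areas <- rep(NA_real_, n)
  areas[gen_ids] <- 0.5 * abs(area2[, 1])

  out <- table
  out$cell_area_nm2 <- areas
  out$raw_density <- 1 / areas
  out$boundary_excluded <- on_hull
  out$n_loc <- n
  attr(out, "n_excluded") <- sum(on_hull)
  out
}

#' Count-normalize and log-transform Voronoi densities
#'
#' Raw Voronoi densities are confounded by the number of localizations of the
#' nucleus, so each density is divided by that count (`n_loc`); a base-10 log
#' is then applied. Units of the normalized density are nm^-2 per
#' localization; for a uniform nucleus of radius R the mean is close to
#' `-log10(pi * R^2)`.
#'
#' @param result a [voronoi_density()] result (or any tibble with
#'   `raw_density` and `n_loc`).
#' @return the input with `norm_density` and `log10_norm_density` appended.
#' @export
normalize_log <- function(result) {
  if (is.null(result[["raw_density"]]) || is.null(result[["n_loc"]])) {
    abort("normalize_log() expects `raw_density` and `n_loc` columns.",
          class = "chromdyn_validation_error")
  }
  if (any(result$n_loc <= 0)) {
    abort("n_loc must be > 0.", class = "chromdyn_validation_error")
  }
  mutate(result,
         norm_density = .data$raw_density / .data$n_loc,
         log10_norm_density = log10(.data$norm_density))
}

# shared binning helper: counts per bin with out-of-range values clipped into
# the edge bins (count-conserving)
.bin_clip <- function(v, edges) {
  nb <- length(edges) - 1L
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > nb] <- nb
  tabulate(idx, nbins = nb)
}

#' 1D probability-density histogram of log densities
#'
#' Histograms the count-normalized log10 Voronoi densities of one or more
#' groups on shared bins and scales each group's histogram so that the area
#' under it is 1 (a probability density), making groups with very different
#' localization counts comparable. Values outside the limits are clipped
#' into the edge bins.
#'
#' @param data tibble with a `log10_norm_density` column (rows with `NA`,
#'   e.g. boundary-excluded localizations, are dropped).
#' @param group optional column name distinguishing groups (e.g. stage).
#' @param bins number of bins (default 50).
#' @param limits histogram range (default `c(-10, -5)` log10(nm^-2)).
#' @return tibble of class `density_histogram`: `group`, `bin_lo`, `bin_hi`,
#'   `bin_mid`, `density`; for every group
#'   `sum(density * (bin_hi - bin_lo)) == 1`.
#' @export
density_pdf <- function(data, group = NULL, bins = 50L, limits = c(-10, -5)) {
  v_all <- data[["log10_norm_density"]]
  if (is.null(v_all)) {
    abort("density_pdf() expects a `log10_norm_density` column.",
          class = "chromdyn_validation_error")
  }
  g_all <- if (!is.null(group)) as.character(data[[group]]) else rep("all", nrow(data))
  keep <- !is.na(v_all)
  v_all <- v_all[keep]; g_all <- g_all[keep]
  edges <- seq(limits[1], limits[2], length.out = bins + 1L)
  width <- diff(edges)
  out <- lapply(unique(g_all), function(g) {
    v <- v_all[g_all == g]
    if (length(v) == 0L) {
      warn(sprintf("density_pdf(): empty group '%s' omitted.", g))
      return(NULL)
    }
    counts <- .bin_clip(v, edges)
    tibble(group = g, bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
           bin_mid = (edges[-1L] + edges[-length(edges)]) / 2,
           density = counts / (sum(counts) * width))
  })
  out <- bind_rows(out)
  class(out) <- c("density_histogram", class(out))
  out
}

#' 2D radius-by-density probability histogram
#'
#' Joint probability-density histogram of polar radius (from the nuclear
#' centre of mass) against count-normalized log10 Voronoi density,
#' volume-normalized to 1. Out-of-limit values are clipped into the edge
#' bins. The conventional display clips the color scale to
#' `[1e-5, 1e-3]`; that range is recorded as render metadata
#' (`attr(, "color_clip")`), not applied to the data.
#'
#' @param data tibble with `r_nm` and `log10_norm_density` columns (rows with
#'   `NA` density dropped).
#' @param r_limits radius range in nm (default `c(0, 8000)`).
#' @param d_limits log-density range (default `c(-10, -5)`).
#' @param r_bins,d_bins bin counts (default 80 x 50).
#' @param color_clip display clipping recorded as metadata.
#' @return tibble of class `radius_density_histogram`: `r_lo`, `r_hi`,
#'   `d_lo`, `d_hi`, `density`, with total volume 1.
#' @export
radius_density_pdf <- function(data, r_limits = c(0, 8000), d_limits = c(-10, -5),
                               r_bins = 80L, d_bins = 50L,
                               color_clip = c(1e-5, 1e-3)) {
  if (is.null(data[["r_nm"]]) || is.null(data[["log10_norm_density"]])) {
    abort("radius_density_pdf() expects `r_nm` and `log10_norm_density`.",
          class = "chromdyn_validation_error")
  }
  keep <- !is.na(data$log10_norm_density) & !is.na(data$r_nm)
  r <- data$r_nm[keep]; d <- data$log10_norm_density[keep]
  if (length(r) == 0L) {
    abort("radius_density_pdf(): no usable rows.", class = "chromdyn_validation_error")
  }
  re <- seq(r_limits[1], r_limits[2], length.out = r_bins + 1L)
  de <- seq(d_limits[1], d_limits[2], length.out = d_bins + 1L)
  ri <- findInterval(r, re, rightmost.closed = TRUE)
  ri[ri < 1L] <- 1L; ri[ri > r_bins] <- r_bins
  di <- findInterval(d, de, rightmost.closed = TRUE)
  di[di < 1L] <- 1L; di[di > d_bins] <- d_bins
  counts <- matrix(tabulate((di - 1L) * r_bins + ri, nbins = r_bins * d_bins),
                   r_bins, d_bins)
  cell_vol <- diff(re)[1] * diff(de)[1]
  dens <- counts / (sum(counts) * cell_vol)
  out <- tibble(
    r_lo = rep(re[-length(re)], times = d_bins),
    r_hi = rep(re[-1L], times = d_bins),
    d_lo = rep(de[-length(de)], each = r_bins),
    d_hi = rep(de[-1L], each = r_bins),
    density = as.vector(dens)
  )
  attr(out, "color_clip") <- color_clip
  class(out) <- c("radius_density_histogram", class(out))
  out
}

#' Pooled summary of a density group
#'
#' Mean and SD of the count-normalized log10 Voronoi densities pooled over
#' all included (non-boundary) localizations, with localization and nucleus
#' counts.
#'
#' @param result tibble with `log10_norm_density` (e.g. from
#'   [normalize_log()]), optionally a `nucleus_id` column.
#' @param group optional grouping column name.
#' @return tibble: `group` (if any), `mean_log10_density`,
#'   `sd_log10_density`, `n_localizations`, `n_nuclei`.
#' @export
summarize_group <- function(result, group = NULL) {
  if (is.null(result[["log10_norm_density"]])) {
    abort("summarize_group() expects `log10_norm_density`.",
          class = "chromdyn_validation_error")
  }
  df <- filter(result, !is.na(.data$log10_norm_density))
  if (nrow(df) == 0L) {
    abort("summarize_group(): no included localizations.",
          class = "chromdyn_validation_error")
  }
  if (!is.null(group)) df <- group_by(df, .data[[group]])
  summarise(df,
            mean_log10_density = mean(.data$log10_norm_density),
            sd_log10_density = if (n() > 1) sd(.data$log10_norm_density) else 0,
            n_localizations = n(),
            n_nuclei = if ("nucleus_id" %in% names(df)) {
              length(unique(.data$nucleus_id))
            } else 1L,
            .groups = "drop")
}
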
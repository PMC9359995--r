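test_that("shoelace_area matches fan triangulation on random convex polygons", {
  set.seed(61)
  for (i in 1:25) {
    pts <- matrix(rnorm(24), ncol = 2)
    hull <- chull(pts) # ordered convex hull vertices (base R oracle)
    x <- pts[hull, 1]; y <- pts[hull, 2]
    # fan triangulation from the first vertex
    fan <- 0
    for (k in 2:(length(x) - 1)) {
      fan <- fan + 0.5 * abs((x[k] - x[1]) * (y[k + 1] - y[1]) -
                             (x[k + 1] - x[1]) * (y[k] - y[1]))
    }
    expect_equal(shoelace_area(x, y), fan, tolerance = 1e-9)
  }
  expect_equal(shoelace_area(c(0, 1, 1, 0), c(0, 0, 1, 1)), 1)
  expect_error(shoelace_area(c(0, 1), c(0, 1)), class = "chromdyn_validation_error")
})

test_that("the 5-point hand-constructed tessellation is exact", {
  tab <- loc_table(1:5, c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5))
  vd <- voronoi_density(tab)
  expect_equal(vd$boundary_excluded, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # centre cell: square with vertices (0.5,0),(1,0.5),(0.5,1),(0,0.5)
  expect_equal(vd$cell_area_nm2[5], 0.5, tolerance = 1e-12)
  expect_equal(vd$raw_density[5], 2, tolerance = 1e-12)
  expect_true(all(is.na(vd$cell_area_nm2[1:4])))
  expect_equal(attr(vd, "n_excluded"), 4L)
})

test_that("interior cells of a regular grid have area s^2 and density 1/s^2", {
  s <- 3
  g <- expand.grid(x = seq_len(12), y = seq_len(12))
  vd <- voronoi_density(loc_table(seq_len(nrow(g)), g$x * s, g$y * s))
  inner <- !vd$boundary_excluded
  expect_true(any(inner))
  expect_equal(vd$cell_area_nm2[inner], rep(s^2, sum(inner)), tolerance = 1e-9)
  expect_equal(vd$raw_density[inner], rep(1 / s^2, sum(inner)), tolerance = 1e-9)
})

test_that("cell areas agree with the deldir tessellation oracle", {
  skip_if_not_installed("deldir")
  set.seed(67)
  n <- 300
  x <- runif(n, 0, 1000); y <- runif(n, 0, 1000)
  vd <- voronoi_density(loc_table(seq_len(n), x, y))
  dd <- deldir::deldir(x, y, rw = c(-2000, 3000, -2000, 3000))
  ref <- dd$summary$dir.area
  # compare cells deldir did not clip at its window (near-hull cells can
  # extend beyond any finite window and are clipped there)
  sg <- dd$dirsgs
  clipped <- unique(c(sg$ind1[sg$bp1 | sg$bp2], sg$ind2[sg$bp1 | sg$bp2]))
  b <- which(!vd$boundary_excluded)
  b <- setdiff(b, clipped)
  expect_gt(length(b), 200)
  expect_equal(vd$cell_area_nm2[b], ref[b], tolerance = 1e-8)
})

test_that("bounded cell areas match Monte-Carlo nearest-generator integration", {
  set.seed(99)
  n <- 200
  x <- runif(n); y <- runif(n)
  vd <- voronoi_density(loc_table(seq_len(n), x, y))
  # stratified (jittered-grid) integration over an enlarged box; valid for
  # cells wholly inside it, i.e. generators away from the hull
  G <- 2600L; lo <- -0.5; hi <- 1.5; h <- (hi - lo) / G
  set.seed(1)
  gx <- rep(lo + (seq_len(G) - 0.5) * h, times = G) + runif(G * G, -h / 2, h / 2)
  gy <- rep(lo + (seq_len(G) - 0.5) * h, each = G) + runif(G * G, -h / 2, h / 2)
  nn <- FNN::get.knnx(cbind(x, y), cbind(gx, gy), k = 1)$nn.index
  mc_area <- tabulate(nn, nbins = n) * h^2
  central <- !vd$boundary_excluded & x > 0.15 & x < 0.85 & y > 0.15 & y < 0.85
  expect_gt(sum(central), 80)
  rel <- abs(mc_area[central] - vd$cell_area_nm2[central]) / vd$cell_area_nm2[central]
  expect_lt(max(rel), 0.005)
})

test_that("disjoint interior cells never over-cover their box", {
  set.seed(71)
  x <- runif(400, 0, 50); y <- runif(400, 0, 50)
  vd <- voronoi_density(loc_table(1:400, x, y))
  # cells are pairwise disjoint; those of interior generators stay local, so
  # their total area cannot exceed the sampling box
  interior <- !vd$boundary_excluded & x > 5 & x < 45 & y > 5 & y < 45
  expect_lte(sum(vd$cell_area_nm2[interior]), 50 * 50)
  # and they cover most of the inner region they tile
  expect_gte(sum(vd$cell_area_nm2[interior]), 0.8 * 40 * 40)
})

test_that("degenerate inputs are rejected or repaired", {
  expect_error(voronoi_density(loc_table(1:3, 1:3, 1:3)),
               class = "chromdyn_validation_error")
  expect_error(voronoi_density(loc_table(1:5, 1:5, 2 * (1:5))),
               class = "chromdyn_tessellation_error")
  tab <- loc_table(1:6, c(0, 1, 1, 0, 0.5, 0.5), c(0, 0, 1, 1, 0.5, 0.5))
  expect_warning(vd <- voronoi_density(tab), "duplicated")
  expect_equal(nrow(vd), 6L)
})

test_that("count normalization and base-10 log are exact arithmetic", {
  res <- tibble::tibble(raw_density = c(1e-3, 1), n_loc = c(1e5, 1))
  out <- normalize_log(res)
  expect_equal(out$log10_norm_density, c(-8, 0))
  expect_error(normalize_log(tibble::tibble(raw_density = 1, n_loc = 0)),
               class = "chromdyn_validation_error")
})

test_that("uniform-disk mean log density matches the independent scipy oracle", {
  # frozen oracle: scipy.spatial.Voronoi + shoelace on identical points
  # (20000 uniform points, disk R = 4000 nm, R seed 123) gives -7.648793
  set.seed(123)
  n <- 20000; R <- 4000
  th <- runif(n, 0, 2 * pi); r <- R * sqrt(runif(n))
  vd <- normalize_log(voronoi_density(loc_table(seq_len(n), r * cos(th), r * sin(th))))
  expect_equal(mean(vd$log10_norm_density, na.rm = TRUE), -7.648793,
               tolerance = 1e-5)
})

test_that("probability-density histograms integrate to one", {
  set.seed(73)
  df <- tibble::tibble(log10_norm_density = rnorm(5000, -7.7, 0.4),
                       grp = rep(c("a", "b"), 2500))
  pdf1 <- density_pdf(df, group = "grp")
  for (g in c("a", "b")) {
    sub <- dplyr::filter(pdf1, group == g)
    expect_equal(sum(sub$density * (sub$bin_hi - sub$bin_lo)), 1, tolerance = 1e-6)
  }
  # all values in one bin: that bin's value is 1/width
  one <- density_pdf(tibble::tibble(log10_norm_density = rep(-7.51, 100)), bins = 50)
  w <- one$bin_hi[1] - one$bin_lo[1]
  expect_equal(max(one$density), 1 / w, tolerance = 1e-9)
  expect_equal(sum(one$density > 0), 1L)
  # equal distributions in different-sized groups give matching histograms
  set.seed(74)
  big <- rnorm(20000, -7.6, 0.3)
  df2 <- tibble::tibble(
    log10_norm_density = c(big, big[1:5000]),
    grp = c(rep("big", 20000), rep("small", 5000))
  )
  pdf2 <- density_pdf(df2, group = "grp", bins = 25)
  wide <- tidyr::pivot_wider(pdf2, id_cols = "bin_mid", names_from = "group",
                             values_from = "density")
  expect_lt(max(abs(wide$big - wide$small)), 0.12)
  # out-of-limit values are clipped into edge bins, conserving counts
  clip <- density_pdf(tibble::tibble(log10_norm_density = c(-12, -7.5, -3)), bins = 10)
  expect_equal(sum(clip$density * (clip$bin_hi - clip$bin_lo)), 1, tolerance = 1e-9)
  expect_gt(clip$density[1], 0)
  expect_gt(clip$density[10], 0)
})

test_that("the 2D radius-density histogram is volume-normalized and ring-peaked", {
  set.seed(79)
  nloc <- 4000
  ring_r <- 4000 + rnorm(nloc, 0, 150)
  df <- tibble::tibble(r_nm = ring_r,
                       log10_norm_density = rnorm(nloc, -7.6, 0.3))
  h2 <- radius_density_pdf(df)
  vol <- sum(h2$density * (h2$r_hi - h2$r_lo) * (h2$d_hi - h2$d_lo))
  expect_equal(vol, 1, tolerance = 1e-6)
  marg <- h2 |>
    dplyr::group_by(.data$r_lo) |>
    dplyr::summarise(p = sum(density), .groups = "drop")
  mode_r <- marg$r_lo[which.max(marg$p)]
  expect_lt(abs(mode_r - 4000), 150)
  expect_equal(attr(h2, "color_clip"), c(1e-5, 1e-3))
  # clipping conserves total probability
  df2 <- tibble::tibble(r_nm = c(9000, 100), log10_norm_density = c(-11, -4))
  h3 <- radius_density_pdf(df2)
  expect_equal(sum(h3$density * (h3$r_hi - h3$r_lo) * (h3$d_hi - h3$d_lo)), 1,
               tolerance = 1e-6)
})

test_that("group summaries pool localizations correctly", {
  expect_equal(summarize_group(tibble::tibble(log10_norm_density = -7.2))$sd_log10_density, 0)
  s <- summarize_group(tibble::tibble(log10_norm_density = c(-8, -7)))
  expect_equal(s$mean_log10_density, -7.5)
  set.seed(83)
  v <- rnorm(500, -7.5, 0.5)
  df <- tibble::tibble(log10_norm_density = v, nucleus_id = rep(1:5, 100))
  s2 <- summarize_group(df)
  expect_equal(s2$mean_log10_density, sum(v) / 500)
  expect_equal(s2$sd_log10_density, sd(v))
  expect_equal(s2$n_nuclei, 5L)
  expect_error(summarize_group(tibble::tibble(log10_norm_density = NA_real_)),
               class = "chromdyn_validation_error")
})
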
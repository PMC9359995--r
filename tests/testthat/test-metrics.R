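test_that("segmentation recovers programmed disk areas within 5%", {
  for (r in c(20, 40, 60, 80)) {
    img <- disk_image(200, r)
    seg <- segment_nucleus(img)
    expect_equal(seg$n_components, 1L)
    expect_lt(abs(sum(seg$mask) - pi * r^2) / (pi * r^2), 0.05)
  }
})

test_that("multi-nucleus ROIs and empty fields are flagged", {
  img <- disk_image(120, 18, centre = 35) # first disk
  xs <- matrix(rep(1:120, each = 120), 120)
  ys <- matrix(rep(1:120, times = 120), 120)
  img[(xs - 88)^2 + (ys - 88)^2 <= 18^2] <- 200 # second disk
  seg <- segment_nucleus(img)
  expect_equal(seg$n_components, 2L)
  m <- measure_frame(img, img * 0 + 1)
  expect_false(m$valid)
  expect_equal(m$n_components, 2L)

  set.seed(5)
  noise <- matrix(rnorm(100 * 100, 10, 1), 100, 100) # background only
  seg2 <- segment_nucleus(noise)
  expect_true(seg2$empty)
  expect_error(segment_nucleus(matrix(5, 20, 20)),
               class = "chromdyn_segmentation_error")
})

test_that("a uniform disk has zero edge count and zero CCP", {
  img <- disk_image(80, 25)
  seg <- segment_nucleus(img)
  ec <- count_edges(img, seg$mask)
  expect_identical(ec$edge_count, 0L)
  m <- measure_frame(img, img)
  expect_equal(m$ccp, 0)
  expect_error(count_edges(img, matrix(FALSE, 80, 80)), class = "chromdyn_error")
})

test_that("edge pixels of a single intensity step flank the step (hand oracle)", {
  img <- matrix(10, 8, 8)
  img[, 5:8] <- 100 # vertical step between columns 4 and 5
  mask <- matrix(TRUE, 8, 8)
  ec <- count_edges(img, mask, erode_px = 2L)
  # oracle: direct convolution, Otsu over the same eroded core
  core <- matrix(FALSE, 8, 8); core[3:6, 3:6] <- TRUE
  mag <- sobel_magnitude_loop(img)
  th <- otsu_threshold(mag[core])
  expect_identical(ec$edge_count, sum(core & mag > th))
  # only the two columns flanking the step carry gradient
  expect_true(all(which(ec$edge_map, arr.ind = TRUE)[, "col"] %in% 4:5))
  expect_identical(ec$edge_count, 8L) # 4 rows x 2 columns in the core
})

test_that("CCP is definitional and invariant to global intensity scaling", {
  prog <- fate_program("apoptosis")
  st <- generate_timelapse(prog, seed = 7)
  f <- 20L
  m <- measure_frame(st$h2b[f, , ], st$nucview[f, , ])
  expect_equal(m$ccp * m$area, m$edge_count, tolerance = 1e-12)
  m2 <- measure_frame(st$h2b[f, , ] * 3.7, st$nucview[f, , ])
  expect_equal(m2$edge_count, m$edge_count)
  expect_equal(m2$area, m$area)
})

test_that("granulated texture raises the edge count over its smooth base", {
  base <- disk_image(96, 28, fg = 140, bg = 8)
  prog <- fate_program("granulating")
  st <- generate_timelapse(prog, seed = 11)
  smooth_ec <- measure_frame(base, base)$edge_count
  gran_ec <- measure_frame(st$h2b[42, , ], st$nucview[42, , ])$edge_count
  expect_gt(gran_ec, smooth_ec)
})

test_that("measured CCP is nondecreasing along the granule activation ramp", {
  # noiseless frames rendered at increasing active-site counts
  geom <- timelapse_geometry()
  set.seed(13)
  th <- runif(60, 0, 2 * pi); rr <- 0.9 * sqrt(runif(60))
  sites <- cbind(rr * cos(th), rr * sin(th))
  ccp <- vapply(c(5, 15, 25, 35, 45), function(k) {
    img <- chromdyn:::render_nucleus_frame(96, 48.5, 48.5, 28, 140, sites, k,
                                           0.8, 1.6, mottle = NULL)
    measure_frame(img, img * 0 + 1)$ccp
  }, numeric(1))
  expect_true(all(diff(ccp) >= 0))
})

test_that("CCP ratio at the granulation plateau tracks the programmed ratio", {
  prog <- fate_program("apoptosis", event_time_min = 240)
  st <- generate_timelapse(prog, seed = 17)
  tr <- normalize_trajectory(measure_stack(st))
  plateau <- mean(tr$ccp_norm[tr$time_min >= 150 & tr$time_min <= 230])
  expect_lt(abs(plateau - prog$granulation_ccp_ratio) / prog$granulation_ccp_ratio,
            0.15)
})

test_that("baseline normalization is exact and validates its inputs", {
  traj <- tibble::tibble(area = c(2, 2, 2, 4), edge_count = c(1, 1, 1, 3),
                         ccp = c(0.5, 0.5, 0.5, 0.75),
                         nucview_mean = c(10, 10, 10, 20))
  out <- normalize_trajectory(traj)
  expect_equal(out$area_norm, c(1, 1, 1, 2))
  expect_equal(out$nucview_norm, c(1, 1, 1, 2))
  expect_equal(mean(out$ccp_norm[1:3]), 1, tolerance = 1e-15)
  expect_error(normalize_trajectory(traj[1:2, ]), class = "chromdyn_error")
  traj0 <- traj; traj0$area <- 0
  expect_error(normalize_trajectory(traj0), class = "chromdyn_normalization_error")
})

test_that("normalized series of a measured control stack have unit baseline mean", {
  st <- generate_timelapse(fate_program("control"), seed = 19)
  tr <- normalize_trajectory(measure_stack(st))
  for (col in c("area_norm", "edge_norm", "ccp_norm", "nucview_norm")) {
    expect_equal(mean(tr[[col]][1:3]), 1, tolerance = 1e-12)
  }
})
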
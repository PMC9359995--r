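test_that("localization CSV round-trips through the ThunderSTORM dialect", {
  tab <- generate_localizations(stage_profile(2), 300, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_localization_csv(tab, path)
  header <- readLines(path, n = 1)
  expect_match(header, "x \\[nm\\]")
  expect_match(header, "intensity \\[photon\\]")
  back <- read_localization_csv(path)
  expect_equal(back$x_nm, tab$x_nm, tolerance = 1e-9)
  expect_equal(back$sigma_nm, tab$sigma_nm, tolerance = 1e-9)
  expect_equal(back$frame, tab$frame)
  expect_true("molecule_id" %in% names(back)) # extra columns preserved
})

test_that("reader handles fixtures, header-only files and bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('"frame","x [nm]","y [nm]","sigma [nm]","intensity [photon]","uncertainty [nm]"',
               "1,100.5,200.25,55,800,9.1",
               "2,110,210,60,750,8.5",
               "5,120,220,65,900,7.9"), path)
  tab <- read_localization_csv(path)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$x_nm, c(100.5, 110, 120))
  expect_true("uncertainty [nm]" %in% names(tab))

  writeLines('"frame","x [nm]","y [nm]","sigma [nm]","intensity [photon]"', path)
  expect_equal(nrow(read_localization_csv(path)), 0L)

  writeLines(c('"frame","x [nm]","sigma [nm]","intensity [photon]"', "1,1,2,3"), path)
  expect_error(read_localization_csv(path), "y \\[nm\\]",
               class = "chromdyn_format_error")

  writeLines(c('"frame","x [nm]","y [nm]","sigma [nm]","intensity [photon]"',
               "1,100,200,55,800", "2,oops,210,60,750"), path)
  expect_error(read_localization_csv(path), "line 2",
               class = "chromdyn_format_error")
})

test_that("FWHM filtering keeps [65, 225] nm and drops strictly outside", {
  fac <- 2 * sqrt(2 * log(2))
  tab <- loc_table(1:5, 1:5, 1:5, sigma = c(64, 65, 150, 225, 226) / fac)
  out <- filter_by_fwhm(tab)
  expect_equal(out$frame, c(2L, 3L, 4L))
})

test_that("blinking merge honors the 20 nm / 1-off-frame linking contract", {
  p <- filter_merge_params()
  # 15 nm apart in consecutive frames: one molecule
  m1 <- merge_blinking(loc_table(c(1, 2), c(0, 15), c(0, 0)), p)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$n_events, 2L)
  # gap of 2 dark frames exceeds max off frames = 1: two molecules
  m2 <- merge_blinking(loc_table(c(1, 4), c(0, 15), c(0, 0)), p)
  expect_equal(nrow(m2), 2L)
  # gap of exactly 1 dark frame merges
  m2b <- merge_blinking(loc_table(c(1, 3), c(0, 15), c(0, 0)), p)
  expect_equal(nrow(m2b), 1L)
  # 25 nm exceeds the distance bound
  m3 <- merge_blinking(loc_table(c(1, 2), c(0, 25), c(0, 0)), p)
  expect_equal(nrow(m3), 2L)
  # unlimited frames per molecule: a 50-frame chain stays one molecule
  m4 <- merge_blinking(loc_table(1:50, rep(0, 50), rep(0, 50)), p)
  expect_equal(nrow(m4), 1L)
  expect_equal(m4$n_events, 50L)
  expect_equal(m4$frame, 1)
  # a finite frames-per-molecule cap splits it
  p5 <- filter_merge_params(frames_per_molecule = 5)
  expect_equal(nrow(merge_blinking(loc_table(1:50, rep(0, 50), rep(0, 50)), p5)), 10L)
})

test_that("merged position and intensity are intensity-weighted and summed", {
  tab <- loc_table(c(1, 2), c(0, 4), c(0, 0), intensity = c(1, 3))
  m <- merge_blinking(tab)
  expect_equal(m$x_nm, 3) # (0*1 + 4*3) / 4
  expect_equal(m$intensity_photons, 4)
})

test_that("merge is deterministic, order-conserving and idempotent", {
  tab <- generate_localizations(stage_profile(1), 2000, seed = 12)
  p <- filter_merge_params()
  m1 <- merge_blinking(tab, p)
  expect_lte(nrow(m1), nrow(tab))
  m2 <- merge_blinking(m1, p)
  expect_equal(nrow(m2), nrow(m1))
  expect_equal(m2$x_nm, m1$x_nm, tolerance = 1e-12)
  # unsorted input is sorted with a notice, result unchanged
  shuf <- tab[sample.int(nrow(tab)), ]
  expect_message(m3 <- merge_blinking(shuf, p), "not sorted")
  expect_equal(nrow(m3), nrow(m1))
  expect_equal(sort(m3$x_nm), sort(m1$x_nm), tolerance = 1e-9)
})

test_that("cropping uses closed intervals and matches a loop filter", {
  tab <- loc_table(1:3, c(0, 5, 10), c(0, 5, 10))
  out <- crop_to_nucleus(tab, c(0, 5), c(0, 5))
  expect_equal(nrow(out), 2L) # boundary point (5, 5) retained
  set.seed(47)
  tab2 <- loc_table(1:500, runif(500, -100, 100), runif(500, -100, 100))
  out2 <- crop_to_nucleus(tab2, c(-50, 50), c(-20, 80))
  keep <- logical(500)
  for (i in 1:500) {
    keep[i] <- tab2$x_nm[i] >= -50 && tab2$x_nm[i] <= 50 &&
      tab2$y_nm[i] >= -20 && tab2$y_nm[i] <= 80
  }
  expect_equal(out2, tab2[keep, ])
  expect_warning(crop_to_nucleus(tab, c(900, 1000), c(900, 1000)))
})

test_that("polar transform uses the centre of mass as origin", {
  single <- to_polar(loc_table(1, 5, 7))
  expect_equal(single$r_nm, 0)

  a <- 10
  four <- to_polar(loc_table(1:4, c(a, -a, 0, 0), c(0, 0, a, -a)))
  expect_equal(four$r_nm, rep(a, 4))
  expect_equal(unname(attr(four, "origin")), c(0, 0))

  set.seed(53)
  cloud <- to_polar(loc_table(1:300, rnorm(300, 50), rnorm(300, -20)))
  org <- attr(cloud, "origin")
  xr <- org["x"] + cloud$r_nm * cos(cloud$theta)
  yr <- org["y"] + cloud$r_nm * sin(cloud$theta)
  expect_equal(xr, cloud$x_nm, tolerance = 1e-9)
  expect_equal(mean(xr - org["x"]), 0, tolerance = 1e-9)
  expect_equal(mean(yr - org["y"]), 0, tolerance = 1e-9)
  expect_error(to_polar(loc_table(integer(), numeric(), numeric())),
               class = "chromdyn_validation_error")
})
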
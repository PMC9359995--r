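flat_traj <- function(n = 10, ccp_last = 1, area_last = 1, nucview = NULL) {
  tibble::tibble(
    ccp_norm = c(rep(1, n - 1), ccp_last),
    area_norm = c(rep(1, n - 1), area_last),
    nucview_norm = nucview %||% rep(1, n)
  )
}

test_that("nucview_gradient is the finite-difference series", {
  expect_equal(nucview_gradient(rep(2, 5)), rep(0, 4))
  expect_equal(nucview_gradient(c(1, 1, 15)), c(0, 14))
  set.seed(31)
  v <- runif(20)
  g <- numeric(19)
  for (i in 1:19) g[i] <- v[i + 1] - v[i]
  expect_equal(nucview_gradient(v), g)
  expect_error(nucview_gradient(1), class = "chromdyn_validation_error")
})

test_that("vitality labelling follows the step-1 gradient rules", {
  expect_identical(label_vitality(rep(1, 20)), "surviving")
  v_dying <- c(rep(1, 18), 1, 1.9) # gradient 0.9 at the final step
  expect_identical(label_vitality(v_dying), "dying")
  v_spike <- c(rep(1, 9), 1.5, rep(1.5, 10)) # mid-recording 0.5 jump, flat tail
  expect_identical(label_vitality(v_spike), "unlabeled")
  # negative drift never violates the signed surviving rule
  expect_identical(label_vitality(seq(2, 1, length.out = 10)), "surviving")
  expect_identical(label_vitality(seq(2, 1, length.out = 10),
                                  classifier_thresholds(gradient_mode = "absolute")),
                   "unlabeled")
})

test_that("fate assignment reproduces the canonical step-5 cases", {
  dying_nv <- c(rep(1, 8), 1, 2) # end gradient 1.0 -> dying
  t1 <- flat_traj(10, ccp_last = 0.8, area_last = 0.3, nucview = dying_nv)
  expect_identical(classify_fate(t1)$fate, "apoptotic")

  unl_nv <- c(rep(1, 4), 1.5, rep(1.5, 5)) # unlabeled
  t2 <- flat_traj(10, ccp_last = 2.0, area_last = 0.6, nucview = unl_nv)
  expect_identical(classify_fate(t2)$fate, "necrotic")

  t3 <- flat_traj(10, ccp_last = 1.7, area_last = 0.9)
  expect_identical(classify_fate(t3)$fate, "granulating")

  t4 <- flat_traj(10)
  expect_identical(classify_fate(t4)$fate, "no_change")

  # dying but granulated chromatin at the end: not apoptotic, shrank -> necrotic
  t5 <- flat_traj(10, ccp_last = 2.0, area_last = 0.5, nucview = dying_nv)
  expect_identical(classify_fate(t5)$fate, "necrotic")
})

test_that("every trajectory gets exactly one fate, by precedence (brute-force oracle)", {
  set.seed(37)
  thr <- classifier_thresholds()
  for (i in 1:200) {
    n <- sample(5:20, 1)
    traj <- tibble::tibble(
      ccp_norm = c(1, pmax(0.05, 1 + cumsum(rnorm(n - 1, 0, 0.3)))),
      area_norm = c(1, pmax(0.05, 1 + cumsum(rnorm(n - 1, 0, 0.15)))),
      nucview_norm = c(1, pmax(0, 1 + cumsum(rnorm(n - 1, 0, sample(c(0.01, 0.5), 1)))))
    )
    lab <- classify_fate(traj, thr)
    expect_true(lab$fate %in% c("apoptotic", "necrotic", "granulating", "no_change"))
    # independent restatement of the precedence
    expected <- if (lab$vitality == "dying" && lab$step2_apoptotic) {
      "apoptotic"
    } else if (lab$step3_necrotic && lab$vitality != "surviving") {
      "necrotic"
    } else if (lab$step4_granulating) "granulating" else "no_change"
    expect_identical(lab$fate, expected)
    if (lab$fate == "apoptotic") expect_identical(lab$vitality, "dying")
  }
})

test_that("the 14-fold event rule is strict and finds the first crossing", {
  v <- c(1, 5, 15, 20, 10)
  ev <- detect_apoptotic_event(v)
  expect_true(ev$event)
  expect_identical(ev$frame, 3L)
  expect_false(detect_apoptotic_event(c(1, 13, 13))$event)
  expect_false(detect_apoptotic_event(c(1, 14, 14))$event) # boundary: not surpassed
  # equivalence with a brute-force max over random series
  set.seed(41)
  for (i in 1:50) {
    v <- runif(30, 0, 20)
    expect_identical(detect_apoptotic_event(v)$event, max(v) > 14)
  }
})

test_that("alignment finds the first persistent size change", {
  traj <- tibble::tibble(
    cell_id = 1,
    frame = 1:8, time_min = (0:7) * 10,
    area_norm = c(1, 1, 1, 0.5, 0.3, 0.3, 0.3, 0.3)
  )
  al <- align_to_size_change(traj)
  expect_identical(al$t0$t0_frame, 4L)
  expect_identical(al$t0$direction, "shrinkage")
  expect_equal(al$trajectories$rel_time_min, ((1:8) - 4) * 10)

  # control jitter within +/-0.05 never crosses; cell is excluded
  set.seed(43)
  ctrl <- tibble::tibble(cell_id = 2, frame = 1:20, time_min = (0:19) * 10,
                         area_norm = 1 + runif(20, -0.05, 0.05))
  al2 <- align_to_size_change(ctrl)
  expect_true(is.na(al2$t0$t0_frame))
  expect_true(all(is.na(al2$trajectories$rel_time_min)))

  # an isolated one-frame excursion fails the 2-frame persistence rule
  blip <- tibble::tibble(cell_id = 3, frame = 1:10, time_min = (0:9) * 10,
                         area_norm = c(1, 1, 1, 0.8, 1, 1, 1, 1, 1, 1))
  expect_true(is.na(align_to_size_change(blip)$t0$t0_frame))
})

test_that("culture summaries reproduce printed percentages", {
  labels <- tibble::tibble(
    fate = c(rep("apoptotic", 6), rep("no_change", 454)),
    nucview_event = c(rep(TRUE, 6), rep(FALSE, 454))
  )
  s <- summarize_culture(labels, n_cultures = 9)
  expect_equal(s$fates$percent[s$fates$fate == "apoptotic"], 1.3)
  expect_equal(s$nucview$pooled_percent, 1.3)
  expect_equal(s$n_cells, 460L)

  labels2 <- tibble::tibble(fate = c(rep("apoptotic", 58), rep("granulating", 100),
                                     rep("no_change", 360)))
  s2 <- summarize_culture(labels2, n_cultures = 9)
  expect_equal(s2$fates$percent[s2$fates$fate == "apoptotic"], 11.2)

  s3 <- summarize_culture(tibble::tibble(fate = rep("no_change", 50),
                                         nucview_event = rep(FALSE, 50)))
  expect_equal(s3$nucview$pooled_percent, 0)
  expect_equal(sum(s3$fates$percent), 100)
  expect_error(summarize_culture(tibble::tibble(fate = character())),
               class = "chromdyn_validation_error")
})

test_that("stage summaries are descriptive means with SEM edge cases", {
  df <- tibble::tibble(stage = c(1, 1, 2, 3, 3, 3),
                       area = c(10, 10, 8, 5, 6, 7),
                       edge_count = c(3, 5, 2, 9, 9, 9))
  expect_warning(s <- summarize_by_stage(df, vars = c("area", "edge_count")),
                 "stage")
  one <- dplyr::filter(s, stage == 2, variable == "area")
  expect_equal(one$sem, 0)
  expect_false(one$sem_defined)
  two <- dplyr::filter(s, stage == 1, variable == "area")
  expect_equal(two$sem, 0) # identical cells
  expect_true(two$sem_defined)
  three <- dplyr::filter(s, stage == 3, variable == "area")
  expect_equal(three$mean, mean(c(5, 6, 7)))
  expect_equal(three$sem, sd(c(5, 6, 7)) / sqrt(3))
})
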
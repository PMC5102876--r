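# three-frame fixture with hand-computed errors
make_fixture <- function() {
  gt <- tibble::tibble(
    frame_id = 0:2,
    left_x = c(100, 100, 100), left_y = c(100, 100, 100),
    right_x = c(140, 140, 140), right_y = c(100, 100, 100),
    center_x = c(120, 120, 120), center_y = c(60, 60, 60),
    shaft_x = c(120, 120, 120), shaft_y = c(20, 20, 20),
    present = 1L, state = "open")
  # frame 0: exact; frame 1: left off by 10 px, shaft direction off by 10 deg;
  # frame 2: left off by 30, center off by 25, shaft direction off by 30 deg
  pred <- gt
  pred$left_x <- c(100, 110, 130)
  pred$center_x[3] <- 145
  ang <- function(deg, ctr_x) {
    # rotate the gt shaft direction (0, -40), anchored at the predicted center
    th <- deg * pi / 180
    c(ctr_x + 40 * sin(th), 60 - 40 * cos(th))
  }
  s1 <- ang(10, 120); s2 <- ang(30, 145)
  pred$shaft_x <- c(120, s1[1], s2[1])
  pred$shaft_y <- c(20, s1[2], s2[2])
  pred$center_x <- c(120, 120, 145)
  list(gt = gt, pred = pred)
}

test_that("the error table carries hand-computed joint and angular errors", {
  f <- make_fixture()
  err <- joint_error_table(f$pred, f$gt)
  expect_equal(err$left_err, c(0, 10, 30))
  expect_equal(err$center_err, c(0, 0, 25))
  expect_equal(err$right_err, c(0, 0, 0))
  expect_equal(err$angular_err_deg[1], 0, tolerance = 1e-9)
  expect_equal(err$angular_err_deg[2], 10, tolerance = 1e-6)
  expect_error(joint_error_table(dplyr::mutate(f$pred, frame_id = frame_id + 10), f$gt),
               "share no frame_id")
})

test_that("accuracy-threshold curves count strict threshold exceedances", {
  f <- make_fixture()
  err <- joint_error_table(f$pred, f$gt)
  # all-zero errors: 1.0 at every positive threshold
  curve0 <- accuracy_threshold_curve(err, "right", c(1, 20, 50))
  expect_equal(curve0$fraction, c(1, 1, 1))
  # errors {0, 10, 30} at thresholds {20, 40} -> {2/3, 1}
  curve <- accuracy_threshold_curve(err, "left", c(20, 40))
  expect_equal(curve$fraction, c(2 / 3, 1))
  # strict "<": error 10 does not clear threshold 10
  expect_equal(accuracy_threshold_curve(err, "left", 10)$fraction, 1 / 3)
  # monotone in the threshold over the default 20-80 grid
  full <- accuracy_threshold_curve(err, "center")
  expect_equal(full$threshold[1], 20)
  expect_equal(full$threshold[nrow(full)], 80)
  expect_true(all(diff(full$fraction) >= 0))
})

test_that("strict PCP requires both endpoints within alpha times part length", {
  f <- make_fixture()
  # gt left part length: |(100,100)-(120,60)| = sqrt(400+1600) = 44.7
  # alpha 0.5 -> tol 22.36; frame 1 left err 10 ok, frame 2 left err 30 fails
  # (and center err 25 fails too); right part fails on frame 2 center error
  pcp <- strict_pcp(f$pred, f$gt, alpha = 0.5)
  expect_equal(pcp$pcp[pcp$part == "left"], 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(pcp$pcp[pcp$part == "right"], 100 * 2 / 3, tolerance = 1e-9)
  # exact predictions: 100 for both parts
  perfect <- strict_pcp(f$gt, f$gt, alpha = 0.5)
  expect_equal(perfect$pcp, c(100, 100))
  # one of two frames with a tip displaced by 2 * alpha * length -> 50
  gt2 <- f$gt[1:2, ]
  pred2 <- gt2
  pred2$left_x[2] <- gt2$left_x[2] + 2 * 0.5 * sqrt(20^2 + 40^2)
  expect_equal(strict_pcp(pred2, gt2, 0.5)$pcp, c(50, 100))
})

test_that("strict PCP is translation- and scale-invariant", {
  f <- make_fixture()
  shift <- function(df, dx, dy) dplyr::mutate(df,
    dplyr::across(dplyr::ends_with("_x"), ~ .x + dx),
    dplyr::across(dplyr::ends_with("_y"), ~ .x + dy))
  scale2 <- function(df) dplyr::mutate(df,
    dplyr::across(dplyr::ends_with("_x") | dplyr::ends_with("_y"), ~ .x * 2))
  base <- strict_pcp(f$pred, f$gt, 0.5)
  expect_equal(strict_pcp(shift(f$pred, 7, -3), shift(f$gt, 7, -3), 0.5)$pcp, base$pcp)
  expect_equal(strict_pcp(scale2(f$pred), scale2(f$gt), 0.5)$pcp, base$pcp)
})

test_that("angular-threshold curves use the undirected deviation", {
  f <- make_fixture()
  err <- joint_error_table(f$pred, f$gt)
  # deviations {0, 10, 30} at thresholds {5, 15, 35} -> {1/3, 2/3, 1}
  curve <- angular_threshold_curve(err, c(5, 15, 35))
  expect_equal(curve$fraction, c(1 / 3, 2 / 3, 1))
  expect_equal(angular_threshold_curve(err)$threshold, seq(3, 24, by = 3))
  # a reversed shaft direction is the same undirected orientation
  pred_flip <- f$gt
  pred_flip$shaft_y <- 2 * pred_flip$center_y - pred_flip$shaft_y
  err_flip <- joint_error_table(pred_flip, f$gt)
  expect_equal(err_flip$angular_err_deg, rep(0, 3), tolerance = 1e-9)
})

test_that("missing predictions count as failures, not exclusions", {
  f <- make_fixture()
  pred <- f$pred
  pred$present[2] <- 0L
  err <- joint_error_table(pred, f$gt)
  expect_true(is.infinite(err$left_err[2]))
  curve <- accuracy_threshold_curve(err, "right", 50)
  expect_equal(curve$fraction, 2 / 3)
  ang <- angular_threshold_curve(err, 45)
  expect_equal(ang$fraction, 2 / 3)
  # frames absent from the ground truth are excluded and reported
  gt <- f$gt; gt$present[3] <- 0L
  err2 <- joint_error_table(f$pred, gt)
  expect_identical(sum(err2$evaluable), 2L)
  expect_identical(attr(accuracy_threshold_curve(err2, "left", 20), "n_excluded"), 1L)
})
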
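test_that("logistic midpoints of both branches are exact", {
  low_mid <- predict_ln_tsh(7.0)
  expect_equal(low_mid$ln_tsh, 1.4 + 3.5 / 2, tolerance = 1e-12)
  expect_equal(low_mid$tsh, exp(3.15), tolerance = 1e-12)
  expect_identical(low_mid$branch, "low_ft4")
  high_mid <- predict_ln_tsh(20.6)
  expect_equal(high_mid$ln_tsh, -3.7 + 5.3 / 2, tolerance = 1e-12)
  expect_identical(high_mid$branch, "high_ft4")
})

test_that("predicted TSH at a typical euthyroid FT4 matches the curve", {
  # frozen from direct evaluation of the high branch at FT4 = 16.3
  p <- predict_ln_tsh(16.3)
  expect_equal(p$ln_tsh, 0.5793268291921461, tolerance = 1e-12)
  expect_equal(p$tsh, 1.7848365264056343, tolerance = 1e-12)
})

test_that("the branch boundary keeps its published discontinuity", {
  # low-branch limit at FT4 -> 12- vs high-branch value at 12
  left <- logistic_branch(12, tsh_curve_params()$low)
  at12 <- predict_ln_tsh(12)
  expect_equal(left, 1.423424978234997, tolerance = 1e-12)
  expect_equal(at12$ln_tsh, 1.314721337323083, tolerance = 1e-12)
  expect_identical(at12$branch, "high_ft4")
  expect_true(abs(left - at12$ln_tsh) > 0.1) # not smoothed away
})

test_that("each branch is strictly decreasing within its stated bounds", {
  low_grid <- seq(0.5, 11.99, length.out = 200)
  high_grid <- seq(12, 40, length.out = 200)
  low <- predict_ln_tsh(low_grid)
  high <- predict_ln_tsh(high_grid)
  expect_true(all(diff(low$ln_tsh) < 0))
  expect_true(all(diff(high$ln_tsh) < 0))
  expect_true(all(low$ln_tsh > 1.4 & low$ln_tsh < 4.9))
  expect_true(all(high$ln_tsh > -3.7 & high$ln_tsh < 1.6))
  expect_equal(low$tsh, exp(low$ln_tsh))
})

test_that("predicted GT composes the curve with the capacity formula", {
  ft4 <- c(9.5, 12, 16.3, 21)
  expect_equal(predict_gt(ft4), compute_gt(predict_tsh(ft4), ft4))
  # frozen composition at 16.3
  expect_equal(predict_gt(16.3), 3.1438043308439156, tolerance = 1e-12)
})

test_that("predicted GT depends on FT4 only, never on measured TSH", {
  subjects <- tibble::tibble(tsh = c(1.2, 9.8), ft4 = c(16.3, 16.3))
  aug <- augment_spina(subjects)
  expect_equal(aug$gt_predicted_pmol_s[1], aug$gt_predicted_pmol_s[2])
  expect_equal(aug$tsh_predicted[1], aug$tsh_predicted[2])
})

test_that("a subject above the predicted curve has actual GT below predicted", {
  set.seed(7)
  ft4 <- runif(500, 10.5, 24)
  pred <- predict_tsh(ft4)
  tsh <- pred * exp(runif(500, -1, 1)) # scatter around the curve
  gt_actual <- compute_gt(tsh, ft4)
  gt_pred <- compute_gt(pred, ft4)
  above <- tsh > pred
  expect_true(all(gt_actual[above] < gt_pred[above]))
  expect_true(all(gt_actual[!above] >= gt_pred[!above]))
})

test_that("non-positive FT4 raises a domain error", {
  expect_error(predict_ln_tsh(0), "ft4")
  expect_error(predict_ln_tsh(c(16, -1)), "ft4")
})
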
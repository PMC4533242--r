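test_that("circular-arc curvature reproduces the calibrated critical
           curvatures at beta = 90 degrees", {
  expect_equal(signif(rho_from_width(0.6), 3), 3.33)
  expect_equal(signif(rho_from_width(1.29), 3), 1.55)
  expect_equal(signif(rho_from_width(2.64), 3), 0.758)
  expect_equal(rho_from_width(5, beta = 0), 0)
  expect_error(rho_from_width(0), "positive")
})

test_that("critical width returns calibration points exactly, decreases
           with cycle length, and refuses out-of-range cycle lengths", {
  cal <- rate_block_calibration()
  expect_equal(critical_width(cal, 200), 0.6)
  expect_equal(critical_width(cal, 150), 1.29)
  expect_equal(critical_width(cal, 117), 2.64)
  cls <- seq(117, 200, by = 1)
  expect_true(all(diff(critical_width(cal, cls)) < 0))
  expect_error(critical_width(cal, 300), "outside calibration range")
  # extrapolation modes
  expect_equal(critical_width(cal, 300, extrapolate = "clamp"), 0.6)
  w300 <- critical_width(cal, 300, extrapolate = "loglinear")
  expect_lt(w300, 0.6)
  cls_all <- seq(100, 320, by = 5)
  expect_true(all(diff(critical_width(cal, cls_all,
                                      extrapolate = "loglinear")) < 0))
})

test_that("the critical space step reproduces the printed transition
           distances for the three calibrated rates", {
  cal <- rate_block_calibration()
  ratio <- (1440 - 231) / 231
  expect_equal(round(critical_space_step(ratio, 200, cal), 1), 1.6)
  expect_equal(round(critical_space_step(ratio, 150, cal), 1), 3.4)
  expect_equal(round(critical_space_step(ratio, 117, cal), 1), 6.9)
  expect_error(critical_space_step(-1, 150, cal), "positive")
})

test_that("will_block compares the transition length against the critical
           space step and never blocks a flat medium", {
  cal <- rate_block_calibration()
  expect_false(will_block(5.23, 2, 200, cal))  # 2 mm > 1.6 mm at VT rate
  expect_true(will_block(5.23, 2, 150, cal))   # 2 mm <= 3.4 mm premature
  expect_false(will_block(5.23, 7, 117, cal))  # just beyond 6.9 mm
  expect_true(will_block(5.23, 6.9, 117, cal))
  expect_false(will_block(0, 1, 150, cal))
  expect_false(will_block(-2, 1, 150, cal))
})

test_that("block is monotone in cycle length: anything blocked at a long
           cycle is blocked at any shorter one", {
  cal <- rate_block_calibration()
  set.seed(7)
  for (i in 1:50) {
    ratio <- runif(1, 0.5, 8)
    len <- runif(1, 0.5, 10)
    cls <- sort(runif(2, 117, 200))
    if (will_block(ratio, len, cls[2], cal))
      expect_true(will_block(ratio, len, cls[1], cal))
  }
})

test_that("calibration rejects non-monotone or degenerate points", {
  expect_error(rate_block_calibration(data.frame(cl = c(117, 150),
                                                 w = c(1, 2))),
               "strictly decrease")
  expect_error(rate_block_calibration(data.frame(cl = c(150, 150),
                                                 w = c(2, 1))),
               "distinct")
  expect_error(rate_block_calibration(data.frame(cl = 150, w = 1)),
               "two calibration points")
})
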
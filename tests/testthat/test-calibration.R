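test_that("two-point and degenerate calibrations fit as expected", {
  cur <- fit_calibration(data.frame(command = c(0, 100), response = c(0, 5)),
                         kind = "pump")
  expect_equal(cur$slope, 0.05)
  expect_equal(cur$intercept, 0)
  expect_equal(cur$r2, 1)
  # identical responses at all commands: zero slope, r2 reported as 0
  flat <- fit_calibration(data.frame(command = c(0, 50, 100),
                                     response = rep(2, 3)), kind = "pump")
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)
  expect_error(fit_calibration(data.frame(command = c(1, 1),
                                          response = c(2, 3)), "pump"),
               "distinct command")
})

test_that("noisy calibration recovers the true slope within 3 SE", {
  set.seed(123)
  cmd <- rep(seq(0, 100, by = 10), each = 3)
  pts <- data.frame(command = cmd,
                    response = 0.04 * cmd + rnorm(length(cmd), 0, 0.01))
  cur <- fit_calibration(pts, kind = "pump")
  se_slope <- cur$residual_sd / sqrt(sum((cmd - mean(cmd))^2))
  expect_lt(abs(cur$slope - 0.04), 3 * se_slope)
  # order of points does not matter
  cur2 <- fit_calibration(pts[sample(nrow(pts)), ], kind = "pump")
  expect_equal(cur2$slope, cur$slope)
  expect_equal(cur2$r2, cur$r2)
})

test_that("through-origin pump fits have zero intercept", {
  pts <- data.frame(command = c(10, 50, 100),
                    response = c(0.55, 2.4, 5.1))
  cur <- fit_calibration(pts, kind = "pump", through_origin = TRUE)
  expect_equal(cur$intercept, 0)
  expect_equal(apply_calibration(cur, 0), 0)
})

test_that("apply and invert are mutual inverses off zero slope", {
  cur <- fit_calibration(data.frame(command = c(0, 100), response = c(0, 5)),
                         kind = "pressure_sensor")
  expect_equal(apply_calibration(cur, 100), 5)
  expect_equal(invert_calibration(cur, 5), 100)
  for (cmd in c(-20, 0, 13.7, 250)) {
    expect_equal(invert_calibration(cur, apply_calibration(cur, cmd)), cmd)
  }
  flat <- fit_calibration(data.frame(command = c(0, 50, 100),
                                     response = rep(2, 3)), kind = "pump")
  expect_error(invert_calibration(flat, 2), "zero slope")
})
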
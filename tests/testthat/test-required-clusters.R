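test_that("a symmetric bracket interpolates to its midpoint", {
  curve <- data.frame(c_actual = c(20, 40), power = c(0.7, 0.9))
  req <- interpolate_required(curve)
  expect_equal(req$c_hat, 30)
  expect_equal(req$status, "ok")
  expect_equal(unname(req$bracket_low), c(20, 0.7))
  expect_equal(unname(req$bracket_high), c(40, 0.9))
  # the fitted line passes through the target at c_hat, to machine precision
  expect_equal(req$slope * req$c_hat + req$intercept, 0.8, tolerance = 1e-12)
})

test_that("interpolation is exact on affine power curves", {
  set.seed(12)
  for (i in 1:25) {
    a <- runif(1, 0.005, 0.05)
    b <- runif(1, -0.5, 0.3)
    cc <- sort(sample(5:120, 5))
    pw <- a * cc + b
    keep <- pw > 0 & pw < 1
    if (sum(keep) < 2 || !any(pw[keep] < 0.8) || !any(pw[keep] >= 0.8)) next
    req <- interpolate_required(data.frame(c_actual = cc[keep],
                                           power = pw[keep]))
    expect_equal(req$c_hat, (0.8 - b) / a, tolerance = 1e-10)
  }
})

test_that("points outside the bracketing interval do not move c_hat", {
  base <- data.frame(c_actual = c(40, 60), power = c(0.75, 0.85))
  padded <- data.frame(c_actual = c(5, 10, 40, 60, 100, 120),
                       power = c(0.1, 0.3, 0.75, 0.85, 0.97, 0.99))
  expect_equal(interpolate_required(padded)$c_hat,
               interpolate_required(base)$c_hat)
})

test_that("curves without a crossing return a direction flag, not a number", {
  all_above <- data.frame(c_actual = c(10, 20), power = c(0.85, 0.95))
  req <- interpolate_required(all_above)
  expect_equal(req$status, "all_above")
  expect_true(is.na(req$c_hat))
  all_below <- data.frame(c_actual = c(10, 20), power = c(0.2, 0.5))
  expect_equal(interpolate_required(all_below)$status, "all_below")
})

test_that("noisy curves warn and use the first upward crossing", {
  wiggly <- data.frame(c_actual = c(10, 20, 30, 40),
                       power = c(0.7, 0.82, 0.78, 0.9))
  expect_warning(req <- interpolate_required(wiggly), "crossings")
  expect_equal(req$bracket_low[["c_actual"]], 10)
  expect_equal(req$bracket_high[["c_actual"]], 20)
  dipping <- data.frame(c_actual = c(10, 20, 30), power = c(0.5, 0.3, 0.9),
                        mc_se = c(0.01, 0.01, 0.01))
  expect_warning(interpolate_required(dipping), "non-monotone")
})

test_that("the target power is adjustable", {
  curve <- data.frame(c_actual = c(10, 30), power = c(0.5, 0.7))
  req <- interpolate_required(curve, target = 0.6)
  expect_equal(req$c_hat, 20)
  expect_error(interpolate_required(curve, target = 1.2))
})

test_that("malformed curves are refused", {
  expect_error(interpolate_required(data.frame(c_actual = 10, power = 0.5)))
  expect_error(interpolate_required(
    data.frame(c_actual = c(20, 10), power = c(0.5, 0.7))), "increasing")
  expect_error(interpolate_required(data.frame(x = 1:3)))
})

test_that("percent change matches its defining ratio", {
  expect_equal(round(percent_change(79.82, 60), 1), 33.0)
  expect_equal(percent_change(60, 60), 0)
  expect_equal(percent_change(58.78, 60), -2.0333, tolerance = 1e-4)
  expect_error(percent_change(50, 0))
})
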
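test_that("residual variance follows the ICC identity", {
  expect_equal(derive_residual_variance(icc = 0.006, bcv = 0.1),
               16.5667, tolerance = 1e-4)
  expect_equal(derive_residual_variance(icc = 0.5, bcv = 1.0), 1.0)
  expect_equal(derive_residual_variance(icc = 0.2, bcv = 0.01), 0.04)
  # strictly decreasing in icc for fixed bcv
  iccs <- seq(0.01, 0.99, by = 0.07)
  vals <- vapply(iccs, derive_residual_variance, numeric(1), bcv = 0.5)
  expect_true(all(diff(vals) < 0))
})

test_that("residual variance rejects out-of-domain inputs", {
  expect_error(derive_residual_variance(0, 1))
  expect_error(derive_residual_variance(1, 1))
  expect_error(derive_residual_variance(1.2, 1))
  expect_error(derive_residual_variance(0.5, 0))
  expect_error(derive_residual_variance(0.5, -1))
})

test_that("effect-size calibration reproduces the reference value 0.417", {
  d <- calibrate_effect_size(alpha = 0.05, beta = 0.2, mu = 75, icc = 0.006,
                             bcv = 0.1, c80 = 60)
  expect_equal(round(d, 3), 0.417)
})

test_that("effect-size calibration matches an independent hand evaluation", {
  # step-by-step arithmetic, frozen: sigma_eps^2 = 1*(1-0.2)/0.2 = 4;
  # t_{0.025,8} = 2.3060041, t_{0.2,8} = 0.8888895;
  # Delta = sqrt(4*(4 + 20*1)*(3.1948936)^2/(20*10)) = 2.2134873
  d <- calibrate_effect_size(alpha = 0.05, beta = 0.2, mu = 20, icc = 0.2,
                             bcv = 1, c80 = 10)
  expect_equal(d, 2.2134873, tolerance = 1e-6)
})

test_that("Delta scales as sqrt(kappa) when both variance components scale", {
  base <- calibrate_effect_size(mu = 50, icc = 0.03, bcv = 0.1, c80 = 20)
  for (kappa in c(0.25, 4, 9)) {
    scaled <- calibrate_effect_size(mu = 50, icc = 0.03, bcv = 0.1 * kappa,
                                    c80 = 20)
    # same icc means sigma_eps^2 rescales with bcv, so Delta^2 is linear in kappa
    expect_equal(scaled, base * sqrt(kappa), tolerance = 1e-12)
  }
})

test_that("Delta decreases as c80 or mu increases", {
  d_c <- vapply(c(10, 20, 40, 60), function(c80)
    calibrate_effect_size(mu = 50, icc = 0.03, bcv = 0.1, c80 = c80),
    numeric(1))
  expect_true(all(diff(d_c) < 0))
  d_mu <- vapply(c(20, 50, 75, 100, 125), function(mu)
    calibrate_effect_size(mu = mu, icc = 0.03, bcv = 0.1, c80 = 20),
    numeric(1))
  expect_true(all(diff(d_mu) < 0))
})

test_that("calibrated Delta satisfies the power relation it was solved from", {
  # plugging Delta back into the t-based power relation returns 1 - beta
  p <- crt_params(mu = 75, icc = 0.006, bcv = 0.1, c80 = 60)
  df <- p$c80 - 2
  se <- sqrt(4 * (p$sigma_eps_sq + p$mu * p$bcv) / (p$mu * p$c80))
  t_beta <- p$delta / se - qt(1 - p$alpha / 2, df)
  expect_equal(pt(t_beta, df), 1 - p$beta, tolerance = 1e-12)
})

test_that("parameter sets carry consistent derived quantities", {
  p <- crt_params(mu = 20, icc = 0.03, bcv = 1, c80 = 40)
  expect_s3_class(p, "crt_params")
  expect_gt(p$delta, 0)
  # icc recovered from the variance components to machine precision
  expect_equal(p$bcv / (p$bcv + p$sigma_eps_sq), p$icc, tolerance = 1e-15)
  expect_error(crt_params(mu = 20, icc = 0.03, bcv = 1, c80 = 3))
  expect_error(crt_params(alpha = 1.2, mu = 20, icc = 0.03, bcv = 1, c80 = 10))
  expect_output(print(p), "effect size")
})
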
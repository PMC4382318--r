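test_that("the default grid expands to 420 parameter sets and 3255 points", {
  cfg <- experiment_config()
  params <- expand_parameter_grid(cfg)
  expect_equal(nrow(params), 420)
  expect_equal(nrow(unique(params[, c("mu", "icc", "bcv", "c80")])), 420)
  jobs <- expand_jobs(cfg)
  expect_equal(nrow(jobs), 3255)
})

test_that("cluster-count expansion rules depend on c80", {
  cfg <- experiment_config()
  jobs <- expand_jobs(cfg)
  per_c80 <- table(jobs$c80) / table(expand_parameter_grid(cfg)$c80)
  # 6 counts for small trials, 7 when c80 > 10, 9 when c80 > 20
  expect_equal(as.numeric(per_c80[c("10", "20", "40", "60")]), c(6, 7, 9, 9))
  expect_false(any(jobs$c_actual == 80 & jobs$c80 <= 10))
  expect_false(any(jobs$c_actual >= 100 & jobs$c80 <= 20))
})

test_that("degenerate single-value grids expand to a single parameter set", {
  cfg <- experiment_config(mu = 20, icc = 0.05, bcv = 0.1, c80 = 10,
                           c_actual = c(6, 10, 16))
  expect_equal(nrow(expand_parameter_grid(cfg)), 1)
  expect_equal(nrow(expand_jobs(cfg)), 3)
  expect_error(experiment_config(mu = numeric(0)))
})

test_that("parameter expansion carries correctly calibrated deltas", {
  cfg <- experiment_config(mu = 75, icc = 0.006, bcv = 0.1, c80 = 60)
  params <- expand_parameter_grid(cfg)
  expect_equal(round(params$delta, 3), 0.417)
  expect_equal(params$sigma_eps_sq, 16.5667, tolerance = 1e-4)
})

test_that("a reduced study runs end to end and is seed-deterministic", {
  cfg <- experiment_config(mu = 20, icc = 0.05, bcv = 0.1, c80 = 10,
                           c_actual = c(6, 10, 16), cv = c(0.5, 1.5),
                           n_sims_fixed = 80, n_sets = 80, seed = 123)
  st1 <- run_study(cfg)
  st2 <- run_study(cfg)
  expect_identical(st1$power_table, st2$power_table)
  expect_identical(st1$required_table, st2$required_table)
  expect_s3_class(st1, "crt_study")
  # one power row per (cv level, cluster count); one required row per cv level
  expect_equal(nrow(st1$power_table), 3 * 3)
  expect_equal(nrow(st1$required_table), 3)
  expect_setequal(unique(st1$power_table$cv_label), c(0, 0.5, 1.5))
  # rows without a crossing are flagged, never dropped
  expect_true(all(st1$required_table$status %in%
                  c("ok", "all_above", "all_below")))
})

test_that("study tables persist as schema-versioned plain text", {
  cfg <- experiment_config(mu = 20, icc = 0.05, bcv = 0.1, c80 = 10,
                           c_actual = c(6, 12), cv = 1.0,
                           n_sims_fixed = 40, n_sets = 40, seed = 5)
  dir <- withr::local_tempdir()
  run_study(cfg, output_dir = dir)
  f <- file.path(dir, "power_table.tsv")
  expect_true(file.exists(f))
  expect_match(readLines(f, n = 1), "schema v1")
  tab <- read.delim(f, comment.char = "#")
  expect_equal(nrow(tab), 4)
  expect_true(file.exists(file.path(dir, "required_table.tsv")))
  expect_true(file.exists(file.path(dir, "comparison_summary.txt")))
})

test_that("comparison summaries aggregate a known required-clusters table", {
  rt <- data.frame(
    theta_id = rep(1:3, each = 4),
    cv_label = rep(c(0, 0.5, 1.0, 1.5), 3),
    c80 = rep(c(10, 20, 40), each = 4),
    c_hat = c(10.5, 11, 12, 14,   20.4, 21, 24, 28,   41, 43, 48, 56),
    pct_change = NA, status = "ok")
  rt$pct_change <- percent_change(rt$c_hat, rt$c80)
  s <- summarize_study(rt)
  expect_s3_class(s, "comparison_summary")
  expect_equal(s$fixed_vs_formula$n, 3)
  expect_gt(s$fixed_vs_formula$correlation, 0.999)
  expect_equal(s$fixed_vs_formula$mean_diff, mean(c(0.5, 0.4, 1)))
  # medians of the percent inflation increase with cv
  expect_true(all(diff(s$pct_change$median) > 0))
  expect_equal(s$n_excluded, 0)
  # non-crossing rows are excluded and counted
  rt$status[2] <- "all_below"
  expect_equal(summarize_study(rt)$n_excluded, 1)
  expect_output(print(s), "correlation")
})
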
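## Orchestration of the five-step simulation study: expand the design grid,
## estimate fixed-size power curves, estimate variable-size power curves at
## each coefficient of variation, interpolate the required cluster counts,
## and summarize how cluster-size variability inflates them.

#' Configure a cluster-size variability study
#'
#' Collects the design grid and execution settings for [run_study()]. The
#' defaults are the full study grid: 5 mean cluster sizes x 7 ICCs x 3
#' between-cluster variances x 4 values of `c80` (420 parameter sets), with
#' actual cluster counts 5-120 subject to the expansion rules (80 is used
#' only when `c80 > 10`; 100 and 120 only when `c80 > 20`), variability
#' levels cv = 0.5, 1.0, 1.5, and 5000 fixed / 2000 variable replicates per
#' point. The full grid is a large computation; pass reduced grids and
#' replicate counts for exploratory runs.
#'
#' @param mu Mean cluster sizes.
#' @param icc Intraclass correlation coefficients.
#' @param bcv Between-cluster variances.
#' @param c80 Cluster counts giving 80% power at fixed sizes.
#' @param c_actual Actual cluster counts over which power curves are traced.
#' @param cv Coefficients of variation of cluster sizes.
#' @param n_sims_fixed Replicates per fixed-size power point (default 5000).
#' @param n_sets Variable size sets (one trial each) per variable-size point
#'   (default 2000).
#' @param alpha,beta Type-I and type-II error probabilities.
#' @param seed Master seed; all job-level substreams derive from it.
#' @param method Test method, `"mixed"` or `"cluster-means"`.
#' @param target_power Power level at which required clusters are read off.
#' @param min_size Minimum cluster size for variable draws.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(mu = c(20, 50, 75, 100, 125),
                              icc = c(0.001, 0.002, 0.006, 0.01, 0.03, 0.08, 0.2),
                              bcv = c(0.01, 0.1, 1),
                              c80 = c(10, 20, 40, 60),
                              c_actual = c(5, 10, 15, 20, 40, 60, 80, 100, 120),
                              cv = c(0.5, 1.0, 1.5),
                              n_sims_fixed = 5000,
                              n_sets = 2000,
                              alpha = 0.05, beta = 0.2,
                              seed = 1,
                              method = c("mixed", "cluster-means"),
                              target_power = 0.8,
                              min_size = 3) {
  method <- match.arg(method)
  for (nm in c("mu", "icc", "bcv", "c80", "c_actual", "cv")) {
    v <- get(nm)
    if (length(v) == 0 || !is.numeric(v))
      stop(sprintf("grid '%s' must be a non-empty numeric vector", nm),
           call. = FALSE)
  }
  out <- list(mu = sort(unique(mu)), icc = sort(unique(icc)),
              bcv = sort(unique(bcv)), c80 = sort(unique(c80)),
              c_actual = sort(unique(c_actual)), cv = sort(unique(cv)),
              n_sims_fixed = n_sims_fixed, n_sets = n_sets,
              alpha = alpha, beta = beta, seed = seed, method = method,
              target_power = target_power, min_size = min_size)
  class(out) <- "experiment_config"
  out
}

#' Expand the design grid into calibrated parameter sets
#'
#' Forms the Cartesian product of the `mu`, `icc`, `bcv` and `c80` grids and
#' calibrates each combination's residual variance and effect size. The full
#' default grid yields 420 parameter sets.
#'
#' @param config An [experiment_config()].
#' @return A data frame with one row per parameter set: `theta_id`, `mu`,
#'   `icc`, `bcv`, `c80`, `sigma_eps_sq`, `delta`.
#' @examples
#' nrow(expand_parameter_grid(experiment_config()))   # 420
#' @export
expand_parameter_grid <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  g <- expand.grid(c80 = config$c80, bcv = config$bcv, icc = config$icc,
                   mu = config$mu, KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$mu, g$icc, g$bcv, g$c80), c("mu", "icc", "bcv", "c80")]
  rownames(g) <- NULL
  g$theta_id <- seq_len(nrow(g))
  g$sigma_eps_sq <- mapply(derive_residual_variance, g$icc, g$bcv)
  g$delta <- mapply(function(mu, icc, bcv, c80)
    calibrate_effect_size(config$alpha, config$beta, mu, icc, bcv, c80),
    g$mu, g$icc, g$bcv, g$c80)
  g[, c("theta_id", "mu", "icc", "bcv", "c80", "sigma_eps_sq", "delta")]
}

#' Expand the grid into (parameter set, cluster count) simulation points
#'
#' Crosses every parameter set with the `c_actual` grid, applying the
#' expansion rules: `c_actual = 80` is included only when `c80 > 10`, and
#' `c_actual >= 100` only when `c80 > 20` (small trials reach power 1 well
#' before such counts). The full default grid yields 3,255 points.
#'
#' @param config An [experiment_config()].
#' @return A data frame with one row per (`theta_id`, `c_actual`) point,
#'   carrying the parameter-set columns of [expand_parameter_grid()].
#' @examples
#' nrow(expand_jobs(experiment_config()))   # 3255
#' @export
expand_jobs <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  params <- expand_parameter_grid(config)
  rows <- lapply(seq_len(nrow(params)), function(i) {
    ca <- admissible_c_actual(config$c_actual, params$c80[i])
    cbind(params[rep(i, length(ca)), ], c_actual = ca, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

admissible_c_actual <- function(c_actual, c80) {
  keep <- !(c_actual == 80 & c80 <= 10) & !(c_actual >= 100 & c80 <= 20)
  c_actual[keep]
}

#' Run the cluster-size variability study
#'
#' Executes the full pipeline for every parameter set in the configuration:
#' fixed-size power curve, variable-size power curves at each cv,
#' interpolated required cluster counts, and the fixed-vs-formula and
#' cv-effect summaries. Deterministic for a given master seed: each
#' (parameter set, variability level) job runs in its own substream, so
#' results do not depend on execution order. Non-crossing power curves are
#' retained with a status flag and excluded (with a count) from summaries,
#' never dropped silently.
#'
#' @param config An [experiment_config()].
#' @param output_dir Optional directory; when given, the three result tables
#'   are written there as tab-separated text with a schema header
#'   (`power_table.tsv`, `required_table.tsv`, `comparison_summary.txt`).
#' @return A list of class `"crt_study"`: `power_table` (one row per
#'   `theta_id`, `cv_label`, `c_actual`), `required_table` (one row per
#'   `theta_id`, `cv_label`), `comparison` (see [summarize_study()]) and
#'   `config`.
#' @examples
#' cfg <- experiment_config(mu = 20, icc = 0.05, bcv = 0.1, c80 = 10,
#'                          c_actual = c(6, 10, 16), n_sims_fixed = 100,
#'                          n_sets = 100, seed = 7)
#' st <- run_study(cfg)
#' st$required_table
#' @export
run_study <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  params <- expand_parameter_grid(config)
  cv_levels <- c(0, config$cv)
  n_jobs <- nrow(params) * length(cv_levels)
  job_seeds <- matrix(substream_seeds(config$seed, n_jobs),
                      nrow = nrow(params))

  power_rows <- list()
  required_rows <- list()
  for (i in seq_len(nrow(params))) {
    th <- params[i, ]
    ps <- crt_params(config$alpha, config$beta, th$mu, th$icc, th$bcv, th$c80)
    ca <- admissible_c_actual(config$c_actual, th$c80)
    for (j in seq_along(cv_levels)) {
      cv <- cv_levels[j]
      n_rep <- if (cv == 0) config$n_sims_fixed else config$n_sets
      curve <- power_curve(ps, ca, cv = cv, n_sims = n_rep,
                           seed = job_seeds[i, j],
                           min_size = config$min_size,
                           method = config$method)
      power_rows[[length(power_rows) + 1L]] <-
        cbind(theta_id = th$theta_id, curve)
      req <- interpolate_required(curve, target = config$target_power)
      required_rows[[length(required_rows) + 1L]] <- data.frame(
        theta_id = th$theta_id, cv_label = cv, c80 = th$c80,
        c_hat = req$c_hat,
        bracket_low_c = if (req$status == "ok") req$bracket_low[["c_actual"]] else NA_real_,
        bracket_high_c = if (req$status == "ok") req$bracket_high[["c_actual"]] else NA_real_,
        slope = req$slope, intercept = req$intercept,
        pct_change = percent_change(req$c_hat, th$c80),
        status = req$status)
    }
  }
  power_table <- do.call(rbind, power_rows)
  rownames(power_table) <- NULL
  class(power_table) <- "data.frame"
  required_table <- do.call(rbind, required_rows)
  rownames(required_table) <- NULL

  out <- list(power_table = power_table, required_table = required_table,
              comparison = summarize_study(required_table), config = config)
  class(out) <- "crt_study"
  if (!is.null(output_dir)) write_study(out, output_dir)
  out
}

#' Summarize the effect of cluster-size variability on required clusters
#'
#' Rebuilds the comparison summary from a required-clusters table: agreement
#' between the simulated fixed-size requirement and the formula value
#' (correlation, paired mean difference with CI), the paired increments
#' between successive variability levels, and the distribution (median,
#' range) of the percent change relative to `c80` at each cv. Rows without a
#' valid target-power crossing are excluded pairwise and counted.
#'
#' @param required_table The `required_table` of a [run_study()] result (or
#'   a data frame with columns `theta_id`, `cv_label`, `c80`, `c_hat`,
#'   `pct_change`, `status`).
#' @return A list of class `"comparison_summary"`: `fixed_vs_formula`
#'   (n, correlation, mean difference, CI), `cv_increments` (paired mean
#'   differences between successive cv levels), `pct_change` (per-cv median
#'   and range) and `n_excluded` (non-crossing curves).
#' @export
summarize_study <- function(required_table) {
  rt <- required_table
  ok <- rt[rt$status == "ok", ]
  n_excluded <- nrow(rt) - nrow(ok)

  paired <- function(a, b) {
    # mean of a - b over theta_ids present in both, with t CI when possible
    ids <- intersect(a$theta_id, b$theta_id)
    if (length(ids) == 0)
      return(list(n = 0L, estimate = NA_real_, ci = c(NA_real_, NA_real_)))
    d <- a$c_hat[match(ids, a$theta_id)] - b$c_hat[match(ids, b$theta_id)]
    if (length(d) >= 2 && stats::sd(d) > 0) {
      tt <- stats::t.test(d)
      list(n = length(d), estimate = unname(tt$estimate),
           ci = unname(tt$conf.int))
    } else {
      list(n = length(d), estimate = mean(d), ci = c(NA_real_, NA_real_))
    }
  }

  fixed <- ok[ok$cv_label == 0, ]
  fvf <- list(n = nrow(fixed), correlation = NA_real_,
              mean_diff = NA_real_, ci = c(NA_real_, NA_real_))
  if (nrow(fixed) >= 2 && stats::sd(fixed$c80) > 0)
    fvf$correlation <- stats::cor(fixed$c_hat, fixed$c80)
  if (nrow(fixed) >= 1) {
    d <- fixed$c_hat - fixed$c80
    fvf$mean_diff <- mean(d)
    if (length(d) >= 2 && stats::sd(d) > 0)
      fvf$ci <- unname(stats::t.test(d)$conf.int)
  }

  cvs <- sort(unique(ok$cv_label[ok$cv_label > 0]))
  increments <- list()
  prev <- fixed
  prev_label <- "fixed"
  for (cv in cvs) {
    cur <- ok[ok$cv_label == cv, ]
    # first positive cv is compared against the formula value c80
    if (prev_label == "fixed") {
      ids <- cur$theta_id
      d <- cur$c_hat - cur$c80
      inc <- if (length(d) >= 2 && stats::sd(d) > 0) {
        tt <- stats::t.test(d)
        list(n = length(d), estimate = unname(tt$estimate),
             ci = unname(tt$conf.int))
      } else list(n = length(d),
                  estimate = if (length(d)) mean(d) else NA_real_,
                  ci = c(NA_real_, NA_real_))
      increments[[sprintf("cv%s_vs_c80", format(cv))]] <- inc
    } else {
      increments[[sprintf("cv%s_vs_cv%s", format(cv), prev_label)]] <-
        paired(cur, prev)
    }
    prev <- cur
    prev_label <- format(cv)
  }

  pct <- lapply(cvs, function(cv) {
    v <- ok$pct_change[ok$cv_label == cv]
    data.frame(cv = cv, n = length(v),
               median = if (length(v)) stats::median(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_)
  })
  pct <- if (length(pct)) do.call(rbind, pct) else
    data.frame(cv = numeric(), n = integer(), median = numeric(),
               min = numeric(), max = numeric())

  structure(list(fixed_vs_formula = fvf, cv_increments = increments,
                 pct_change = pct, n_excluded = n_excluded),
            class = "comparison_summary")
}

write_study <- function(study, output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  write_tsv <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# crtpowersim results, schema v1", con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(study$power_table, file.path(output_dir, "power_table.tsv"))
  write_tsv(study$required_table, file.path(output_dir, "required_table.tsv"))
  con <- file(file.path(output_dir, "comparison_summary.txt"), "w")
  sink(con)
  print(study$comparison)
  sink()
  close(con)
  invisible(output_dir)
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat("Fixed-size simulation vs formula (C_hat^F vs C80):\n")
  cat(sprintf("  n = %d, correlation = %s, mean difference = %s, CI = (%s, %s)\n",
              x$fixed_vs_formula$n,
              fmt(x$fixed_vs_formula$correlation, 4),
              fmt(x$fixed_vs_formula$mean_diff, 2),
              fmt(x$fixed_vs_formula$ci[1], 2), fmt(x$fixed_vs_formula$ci[2], 2)))
  cat("Paired increments in required clusters:\n")
  for (nm in names(x$cv_increments)) {
    inc <- x$cv_increments[[nm]]
    cat(sprintf("  %s: n = %d, estimate = %s, CI = (%s, %s)\n", nm, inc$n,
                fmt(inc$estimate, 2), fmt(inc$ci[1], 2), fmt(inc$ci[2], 2)))
  }
  cat("Percent change vs C80 by cv:\n")
  if (nrow(x$pct_change)) {
    for (i in seq_len(nrow(x$pct_change)))
      cat(sprintf("  cv = %g: median %s%%, range %s%% to %s%% (n = %d)\n",
                  x$pct_change$cv[i], fmt(x$pct_change$median[i], 2),
                  fmt(x$pct_change$min[i], 2), fmt(x$pct_change$max[i], 2),
                  x$pct_change$n[i]))
  } else cat("  (none)\n")
  cat(sprintf("Curves without a valid crossing (excluded): %d\n", x$n_excluded))
  invisible(x)
}

fmt <- function(v, digits) {
  if (is.null(v) || length(v) == 0 || is.na(v)) "NA" else
    formatC(v, digits = digits, format = "f")
}

#' @export
print.crt_study <- function(x, ...) {
  cat(sprintf("CRT cluster-size variability study: %d parameter sets, cv levels %s\n",
              length(unique(x$power_table$theta_id)),
              paste(c(0, x$config$cv), collapse = ", ")))
  cat(sprintf("  power table: %d points; required table: %d rows\n",
              nrow(x$power_table), nrow(x$required_table)))
  print(x$comparison)
  invisible(x)
}
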
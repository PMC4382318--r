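## Monte-Carlo power estimation: the rejection fraction over replicate
## simulated trials, under fixed cluster sizes or under freshly drawn
## variable cluster-size sets (one simulated trial per size set, so size-set
## variability and outcome variability are averaged jointly).

# Deterministic per-replicate substream seeds. Seeding a replicate with its
# own 31-bit seed makes any single trial replayable in isolation and makes
# results invariant to how replicates are scheduled across workers.
substream_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2147483646L, n, replace = FALSE)
}

run_power_sims <- function(params, c_actual, cv, n_sims, seed, min_size,
                           method, alpha = params$alpha) {
  seeds <- substream_seeds(seed, n_sims)
  rej <- 0L
  n_fallback <- 0L
  for (s in seq_len(n_sims)) {
    set.seed(seeds[s])
    sizes <- draw_cluster_sizes(params$mu, cv, c_actual, min_size)
    arms <- assign_arms(c_actual)
    trial <- simulate_trial(params, sizes, arms)
    res <- test_treatment_effect(trial, alpha = alpha, method = method)
    rej <- rej + res$reject
    n_fallback <- n_fallback + (res$converged == 0L)
  }
  p <- rej / n_sims
  structure(list(power = p, n_sims = n_sims,
                 mc_se = sqrt(p * (1 - p) / n_sims),
                 c_actual = c_actual, cv_label = cv,
                 n_fallback = n_fallback),
            class = "power_estimate")
}

#' Estimate power with fixed (equal) cluster sizes
#'
#' Simulates `n_sims` independent trials in which every one of `c_actual`
#' clusters has exactly `mu` participants, tests each for a treatment effect,
#' and returns the rejection fraction — the Monte-Carlo power estimate —
#' with its binomial standard error `sqrt(p(1-p)/n)`.
#'
#' @param params A [crt_params()] parameter set.
#' @param c_actual Actual number of clusters in each simulated trial (>= 4).
#' @param n_sims Number of replicate trials (default 5000).
#' @param seed Master seed for this estimate; per-replicate substreams are
#'   derived from it so any replicate can be replayed in isolation.
#' @param method Test passed to [test_treatment_effect()].
#' @return A `"power_estimate"`: `power`, `n_sims`, `mc_se`, `c_actual`,
#'   `cv_label` (0 here) and `n_fallback` (trials tested by the fallback).
#' @examples
#' p <- crt_params(mu = 20, icc = 0.05, bcv = 0.1, c80 = 10)
#' estimate_power_fixed(p, c_actual = 10, n_sims = 200, seed = 1)
#' @export
estimate_power_fixed <- function(params, c_actual, n_sims = 5000,
                                 seed = NULL, method = "mixed") {
  stopifnot(inherits(params, "crt_params"))
  if (c_actual < 4) stop("'c_actual' must be at least 4", call. = FALSE)
  if (n_sims < 1) stop("'n_sims' must be at least 1", call. = FALSE)
  run_power_sims(params, c_actual, cv = 0, n_sims = n_sims, seed = seed,
                 min_size = 3, method = method)
}

#' Estimate power with variable cluster sizes
#'
#' For each of `n_sets` replicates, draws a fresh negative-binomial
#' cluster-size set at coefficient of variation `cv` (minimum size enforced
#' by the shift rule of [draw_cluster_sizes()]), simulates one trial on it,
#' and tests for a treatment effect. The returned power is the mean rejection
#' indicator over the `n_sets` (size set, trial) replicates.
#'
#' @inheritParams estimate_power_fixed
#' @param cv Coefficient of variation of cluster sizes (0 reduces to the
#'   fixed-size case).
#' @param n_sets Number of variable cluster-size sets, one trial each
#'   (default 2000).
#' @param min_size Minimum cluster size (default 3).
#' @return A `"power_estimate"` (see [estimate_power_fixed()]), with
#'   `cv_label = cv`.
#' @examples
#' p <- crt_params(mu = 20, icc = 0.05, bcv = 0.1, c80 = 10)
#' estimate_power_variable(p, c_actual = 10, cv = 1.5, n_sets = 100, seed = 1)
#' @export
estimate_power_variable <- function(params, c_actual, cv, n_sets = 2000,
                                    seed = NULL, min_size = 3,
                                    method = "mixed") {
  stopifnot(inherits(params, "crt_params"))
  if (c_actual < 4) stop("'c_actual' must be at least 4", call. = FALSE)
  if (n_sets < 1) stop("'n_sets' must be at least 1", call. = FALSE)
  run_power_sims(params, c_actual, cv = cv, n_sims = n_sets, seed = seed,
                 min_size = min_size, method = method)
}

#' Trace a power curve over the number of clusters
#'
#' Estimates power at each value of `c_values` for one parameter set and one
#' cluster-size variability level, producing the points of a power curve.
#' Each point receives its own substream seed derived from `seed`.
#'
#' @inheritParams estimate_power_variable
#' @param c_values Increasing vector of actual cluster counts.
#' @param cv Coefficient of variation of cluster sizes (0 = fixed sizes).
#' @param n_sims Replicates per point.
#' @return A data frame of class `"power_curve"` with columns `c_actual`,
#'   `power`, `n_sims`, `mc_se`, `cv_label`, `n_fallback`, ordered by
#'   `c_actual`.
#' @examples
#' p <- crt_params(mu = 20, icc = 0.05, bcv = 0.1, c80 = 10)
#' power_curve(p, c_values = c(6, 10, 16), cv = 0, n_sims = 100, seed = 1)
#' @export
power_curve <- function(params, c_values, cv = 0, n_sims = 2000, seed = NULL,
                        min_size = 3, method = "mixed") {
  stopifnot(inherits(params, "crt_params"))
  c_values <- sort(unique(as.numeric(c_values)))
  point_seeds <- substream_seeds(seed, length(c_values))
  rows <- lapply(seq_along(c_values), function(i) {
    est <- run_power_sims(params, c_values[i], cv, n_sims, point_seeds[i],
                          min_size, method)
    data.frame(c_actual = est$c_actual, power = est$power,
               n_sims = est$n_sims, mc_se = est$mc_se,
               cv_label = est$cv_label, n_fallback = est$n_fallback)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Replay one simulated trial from a power estimate
#'
#' Re-runs the `replicate`-th trial of a power estimate produced with master
#' seed `seed`, returning the drawn sizes, arm assignment, trial data and
#' test result. Because replicates run in independent substreams, the replay
#' is byte-identical to the original trial.
#'
#' @inheritParams estimate_power_variable
#' @param replicate Index of the replicate to replay (1-based).
#' @param n_sims Replicate count of the original run (needed to regenerate
#'   the substream seed table).
#' @return A list with `sizes`, `arms`, `trial`, `test` and `sub_seed`.
#' @export
replay_trial <- function(params, c_actual, cv, replicate, n_sims, seed,
                         min_size = 3, method = "mixed") {
  stopifnot(inherits(params, "crt_params"), replicate >= 1,
            replicate <= n_sims)
  seeds <- substream_seeds(seed, n_sims)
  set.seed(seeds[replicate])
  sizes <- draw_cluster_sizes(params$mu, cv, c_actual, min_size)
  arms <- assign_arms(c_actual)
  trial <- simulate_trial(params, sizes, arms)
  res <- test_treatment_effect(trial, alpha = params$alpha, method = method)
  list(sizes = sizes, arms = arms, trial = trial, test = res,
       sub_seed = seeds[replicate])
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf(
    "Power estimate: %.4f (mc se %.4f) at C_A = %g, cv = %g, %d sims",
    x$power, x$mc_se, x$c_actual, x$cv_label, x$n_sims))
  if (x$n_fallback > 0)
    cat(sprintf(" [%d fallback tests]", x$n_fallback))
  cat("\n")
  invisible(x)
}
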
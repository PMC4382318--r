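#' Randomly assign clusters to two equal arms
#'
#' Produces a per-cluster binary treatment indicator with exactly
#' `floor(n/2)` clusters in one arm and `ceiling(n/2)` in the other, in
#' uniformly random order. For odd `n` the arm receiving the extra cluster
#' is itself chosen at random.
#'
#' @param n_clusters Number of clusters (>= 2).
#' @return Integer vector of 0s (control) and 1s (treatment), length
#'   `n_clusters`.
#' @examples
#' set.seed(1)
#' table(assign_arms(60))
#' @export
assign_arms <- function(n_clusters) {
  if (!is.numeric(n_clusters) || length(n_clusters) != 1L || n_clusters < 2)
    stop("'n_clusters' must be at least 2", call. = FALSE)
  n <- as.integer(n_clusters)
  n_trt <- n %/% 2L
  if (n %% 2L == 1L && stats::runif(1) < 0.5) n_trt <- n_trt + 1L
  sample(rep.int(c(1L, 0L), c(n_trt, n - n_trt)))
}

#' Simulate individual-level outcomes for one CRT
#'
#' Generates outcomes from the two-level normal model
#' \deqn{Y_{jk} = \eta_k + \Delta X_k + \epsilon_{jk}, \quad
#'   \eta_k \sim N(0, \sigma^2_\eta), \ \epsilon_{jk} \sim N(0, \sigma^2_\epsilon)}{
#'   Y_jk = eta_k + Delta*X_k + eps_jk}
#' where `eta_k` is a cluster-level random intercept shared by everyone in
#' cluster `k` (variance = the between-cluster variance `bcv`) and `eps_jk`
#' is individual noise (variance = the derived residual variance). Cluster
#' intercepts are drawn before individual errors, in cluster-index order, so
#' a trial is byte-reproducible from its seed.
#'
#' @param params A [crt_params()] parameter set (supplies `delta`, `bcv`,
#'   `sigma_eps_sq`).
#' @param sizes Integer vector of per-cluster sizes (e.g. from
#'   [draw_cluster_sizes()]).
#' @param arms Per-cluster binary assignment of the same length as `sizes`
#'   (e.g. from [assign_arms()]).
#' @return A `data.frame` of class `"crt_trial"` with one row per individual
#'   and columns `cluster` (integer index), `arm` (0/1) and `outcome`.
#' @examples
#' p <- crt_params(mu = 20, icc = 0.05, bcv = 0.1, c80 = 10)
#' set.seed(1)
#' tr <- simulate_trial(p, draw_cluster_sizes(20, 0, 10), assign_arms(10))
#' head(tr)
#' @export
simulate_trial <- function(params, sizes, arms) {
  stopifnot(inherits(params, "crt_params"))
  if (length(sizes) != length(arms))
    stop("'sizes' and 'arms' must have equal length", call. = FALSE)
  k <- length(sizes)
  eta <- stats::rnorm(k, 0, sqrt(params$bcv))
  cl <- rep.int(seq_len(k), sizes)
  n_tot <- length(cl)
  y <- eta[cl] + params$delta * arms[cl] +
    stats::rnorm(n_tot, 0, sqrt(params$sigma_eps_sq))
  out <- data.frame(cluster = cl, arm = arms[cl], outcome = y)
  class(out) <- c("crt_trial", "data.frame")
  out
}

#' Write one simulated trial as tidy text
#'
#' @param trial A `"crt_trial"` data frame from [simulate_trial()].
#' @param file Path of the tab-separated file to write (columns: cluster,
#'   arm, outcome).
#' @return Invisibly, the path written.
#' @export
write_trial <- function(trial, file) {
  stopifnot(inherits(trial, "crt_trial"))
  utils::write.table(trial, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
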
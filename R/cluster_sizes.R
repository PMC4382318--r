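#' Negative-binomial dispersion for a target coefficient of variation
#'
#' For cluster sizes drawn from a negative binomial with mean `mu` and
#' dispersion (size) parameter `r`, the variance is `mu + mu^2/r`. Fixing the
#' coefficient of variation at `cv` (so the variance is `(mu*cv)^2`) and
#' solving for the dispersion gives
#' \deqn{r = \frac{\mu}{\mu \cdot cv^2 - 1}}{r = mu / (mu * cv^2 - 1)}
#' The generalized (gamma-Poisson) negative binomial is intended: `r` is
#' typically non-integer.
#'
#' @param mu Target mean cluster size, > 0.
#' @param cv Target coefficient of variation of cluster sizes; requires
#'   `mu * cv^2 > 1`, otherwise the requested cv is unattainable under this
#'   parameterization.
#' @return The dispersion parameter `r` (> 0).
#' @examples
#' nb_size_parameter(20, 1.5)   # 20/44
#' nb_size_parameter(20, 0.5)   # 5
#' @export
nb_size_parameter <- function(mu, cv) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("'mu' must be a single positive number", call. = FALSE)
  if (!is.numeric(cv) || length(cv) != 1L || cv <= 0)
    stop("'cv' must be a single positive number", call. = FALSE)
  if (mu * cv^2 <= 1)
    stop(sprintf(
      "coefficient of variation %g is unattainable for mean %g: need mu*cv^2 > 1",
      cv, mu), call. = FALSE)
  mu / (mu * cv^2 - 1)
}

#' Draw one set of cluster sizes
#'
#' Generates the per-cluster participant counts for one simulated trial.
#' With `cv = 0` every cluster has exactly `mu` participants (the fixed-size
#' case). With `cv > 0`, sizes are `min_size` plus a draw from a negative
#' binomial with mean `mu - min_size`, so a minimum size of `min_size` is
#' guaranteed and the long-run mean stays at `mu`. The dispersion is computed
#' by [nb_size_parameter()] from the pre-shift mean `mu - min_size` and the
#' nominal `cv`; the realized cv of the shifted sizes is therefore slightly
#' below nominal (the shift adds a constant without adding spread).
#'
#' @param mu Target mean cluster size; must exceed `min_size` when `cv > 0`.
#' @param cv Nominal coefficient of variation (0 for fixed sizes).
#' @param n_clusters Number of clusters to draw sizes for.
#' @param min_size Minimum cluster size enforced by the shift (default 3).
#' @return Integer vector of `n_clusters` sizes, each `>= min_size` (each
#'   exactly `mu` when `cv = 0`), with attributes `cv_label` and
#'   `target_mean`.
#' @examples
#' set.seed(1)
#' draw_cluster_sizes(20, 1.5, 10)
#' draw_cluster_sizes(20, 0, 4)
#' @export
draw_cluster_sizes <- function(mu, cv, n_clusters, min_size = 3) {
  if (!is.numeric(n_clusters) || length(n_clusters) != 1L || n_clusters < 1)
    stop("'n_clusters' must be a positive count", call. = FALSE)
  if (!is.numeric(cv) || length(cv) != 1L || cv < 0)
    stop("'cv' must be a single non-negative number", call. = FALSE)
  if (cv == 0) {
    sizes <- rep.int(as.integer(round(mu)), n_clusters)
  } else {
    pre_mu <- mu - min_size
    if (pre_mu <= 0)
      stop("'mu' must exceed 'min_size' for variable cluster sizes",
           call. = FALSE)
    r <- nb_size_parameter(pre_mu, cv)
    sizes <- min_size + stats::rnbinom(n_clusters, size = r, mu = pre_mu)
  }
  structure(as.integer(sizes), cv_label = cv, target_mean = mu)
}

#' Write cluster-size sets as plain text
#'
#' Emits one row per trial with the comma-separated sizes of that trial's
#' clusters, for audit and replay of the size draws.
#'
#' @param sets A list of integer vectors (one per trial), e.g. from repeated
#'   calls to [draw_cluster_sizes()].
#' @param file Path of the text file to write.
#' @return Invisibly, the path written.
#' @export
write_size_sets <- function(sets, file) {
  if (!is.list(sets)) sets <- list(sets)
  lines <- vapply(sets, function(s) paste(s, collapse = ","), character(1))
  writeLines(lines, file)
  invisible(file)
}
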
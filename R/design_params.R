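#' Residual (within-cluster) variance implied by the ICC
#'
#' In the two-level normal model the intraclass correlation coefficient is
#' ICC = sigma^2_eta / (sigma^2_eta + sigma^2_eps), where sigma^2_eta is the
#' between-cluster variance (BCV) and sigma^2_eps the residual variance.
#' Solving for the residual variance gives
#' sigma^2_eps = BCV * (1 - ICC) / ICC.
#'
#' @param icc Intraclass correlation coefficient, in (0, 1).
#' @param bcv Between-cluster variance sigma^2_eta, > 0.
#' @return The residual variance sigma^2_eps (outcome-variance units).
#' @examples
#' derive_residual_variance(icc = 0.006, bcv = 0.1)
#' @export
derive_residual_variance <- function(icc, bcv) {
  if (!is.numeric(icc) || length(icc) != 1L || !is.finite(icc) ||
      icc <= 0 || icc >= 1)
    stop("'icc' must be a single number strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(bcv) || length(bcv) != 1L || !is.finite(bcv) || bcv <= 0)
    stop("'bcv' must be a single positive number", call. = FALSE)
  bcv * (1 - icc) / icc
}

#' Calibrate the treatment effect size for 80% power at fixed cluster sizes
#'
#' Computes the non-standardized effect size Delta such that an equal-armed
#' CRT with `c80` clusters of exactly `mu` participants each has power
#' 1 - beta at two-sided level alpha, using the cluster-level t-based
#' sample-size relation
#' \deqn{\Delta^2 = \frac{4 (\sigma^2_\epsilon + \mu \cdot BCV)
#'   (t_{\alpha/2} + t_\beta)^2}{\mu \cdot C^{80}}}{
#'   Delta^2 = 4 (sigma2_eps + mu*BCV) (t_{alpha/2} + t_beta)^2 / (mu * C80)}
#' with both t-quantiles on `c80 - 2` degrees of freedom, the cluster-level
#' degrees of freedom of the two-sample comparison of cluster means.
#'
#' @param alpha Two-sided type-I error probability, in (0, 1).
#' @param beta Type-II error probability, in (0, 1); power is 1 - beta.
#' @param mu Mean cluster size (participants per cluster).
#' @param icc Intraclass correlation coefficient, in (0, 1).
#' @param bcv Between-cluster variance sigma^2_eta, > 0.
#' @param c80 Number of clusters giving 80% power at fixed sizes; must be
#'   at least 4 so the t degrees of freedom are positive.
#' @return The calibrated effect size Delta (outcome units), > 0.
#' @examples
#' # the worked reference scenario: Delta = 0.417
#' calibrate_effect_size(alpha = 0.05, beta = 0.2, mu = 75,
#'                       icc = 0.006, bcv = 0.1, c80 = 60)
#' @export
calibrate_effect_size <- function(alpha = 0.05, beta = 0.2, mu, icc, bcv, c80) {
  for (nm in c("alpha", "beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stop(sprintf("'%s' must be a single probability in (0, 1)", nm),
           call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("'mu' must be a single positive number", call. = FALSE)
  if (!is.numeric(c80) || length(c80) != 1L || c80 < 4)
    stop("'c80' must be at least 4 (degrees of freedom c80 - 2 >= 2)",
         call. = FALSE)
  sigma_eps_sq <- derive_residual_variance(icc, bcv)
  df <- c80 - 2
  tq <- stats::qt(1 - alpha / 2, df) + stats::qt(1 - beta, df)
  sqrt(4 * (sigma_eps_sq + mu * bcv) * tq^2 / (mu * c80))
}

#' Construct a calibrated CRT design parameter set
#'
#' Bundles the design parameters of one hypothetical equal-armed CRT with the
#' derived quantities that the simulation modules need: the residual variance
#' implied by the ICC and between-cluster variance, and the effect size Delta
#' calibrated so that `c80` equal-sized clusters give `1 - beta` power.
#'
#' @inheritParams calibrate_effect_size
#' @return An object of class `"crt_params"`: a list with elements `alpha`,
#'   `beta`, `mu`, `icc`, `bcv`, `c80`, `sigma_eps_sq` and `delta`.
#' @examples
#' p <- crt_params(mu = 75, icc = 0.006, bcv = 0.1, c80 = 60)
#' p$delta   # 0.417 to 3 dp
#' @export
crt_params <- function(alpha = 0.05, beta = 0.2, mu, icc, bcv, c80) {
  delta <- calibrate_effect_size(alpha, beta, mu, icc, bcv, c80)
  out <- list(alpha = alpha, beta = beta, mu = mu, icc = icc, bcv = bcv,
              c80 = c80,
              sigma_eps_sq = derive_residual_variance(icc, bcv),
              delta = delta)
  class(out) <- "crt_params"
  out
}

#' @export
print.crt_params <- function(x, ...) {
  cat("CRT design parameter set\n")
  cat(sprintf("  alpha = %g, beta = %g (power %g)\n",
              x$alpha, x$beta, 1 - x$beta))
  cat(sprintf("  mean cluster size mu   = %g\n", x$mu))
  cat(sprintf("  ICC                    = %g\n", x$icc))
  cat(sprintf("  between-cluster var    = %g\n", x$bcv))
  cat(sprintf("  residual var (derived) = %g\n", x$sigma_eps_sq))
  cat(sprintf("  C80 (clusters at 80%% power, fixed sizes) = %g\n", x$c80))
  cat(sprintf("  calibrated effect size Delta = %.4f\n", x$delta))
  invisible(x)
}
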
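#' Interpolate the number of clusters required for target power
#'
#' Scans a power curve left-to-right for the first adjacent pair of points
#' straddling the target power (strictly below, then at or above), fits the
#' line through those two points
#' \deqn{\hat{P} = \hat{a} C + \hat{b}}{P = a*C + b}
#' and solves `target = a*C + b` for the required cluster count `C_hat`.
#' Raw points are interpolated as-is — no smoothing or isotonic adjustment —
#' and a warning is issued when the curve is non-monotone by more than twice
#' the Monte-Carlo standard error. If the curve starts at or above the target
#' or never reaches it, no extrapolation is attempted: the result carries a
#' status flag instead of a crossing.
#'
#' @param curve A `"power_curve"` data frame from [power_curve()], or any
#'   data frame with columns `c_actual` and `power` (strictly increasing
#'   `c_actual`, at least two rows).
#' @param target Target power (default 0.8).
#' @return An object of class `"required_clusters"`: a list with `c_hat`
#'   (interpolated cluster count, `NA` when no crossing), `bracket_low` and
#'   `bracket_high` (named vectors `c(c_actual, power)`), `slope`,
#'   `intercept`, `target`, and `status` (`"ok"`, `"all_above"` when the
#'   curve starts at/above target, `"all_below"` when it never reaches it).
#' @examples
#' curve <- data.frame(c_actual = c(20, 40), power = c(0.7, 0.9))
#' interpolate_required(curve)$c_hat   # 30
#' @export
interpolate_required <- function(curve, target = 0.8) {
  if (!is.data.frame(curve) || !all(c("c_actual", "power") %in% names(curve)))
    stop("'curve' must have columns 'c_actual' and 'power'", call. = FALSE)
  cc <- curve$c_actual
  pp <- curve$power
  if (length(cc) < 2) stop("need at least two curve points", call. = FALSE)
  if (any(diff(cc) <= 0))
    stop("'c_actual' values must be strictly increasing", call. = FALSE)
  if (!is.numeric(target) || length(target) != 1L || target <= 0 || target >= 1)
    stop("'target' must be a probability in (0, 1)", call. = FALSE)

  if ("mc_se" %in% names(curve)) {
    dips <- diff(pp) < -2 * utils::head(curve$mc_se, -1)
    if (any(dips))
      warning(sprintf(
        "power curve is non-monotone beyond 2*mc_se at c_actual = %s",
        paste(cc[which(dips)], collapse = ", ")), call. = FALSE)
  }

  blank <- list(c_hat = NA_real_, bracket_low = NULL, bracket_high = NULL,
                slope = NA_real_, intercept = NA_real_, target = target)
  if (pp[1] >= target) {
    blank$status <- "all_above"
    class(blank) <- "required_clusters"
    return(blank)
  }
  cross <- which(pp[-length(pp)] < target & pp[-1] >= target)
  if (length(cross) == 0) {
    blank$status <- "all_below"
    class(blank) <- "required_clusters"
    return(blank)
  }
  if (length(cross) > 1)
    warning("multiple target crossings; using the first", call. = FALSE)
  i <- cross[1]
  slope <- (pp[i + 1] - pp[i]) / (cc[i + 1] - cc[i])
  intercept <- pp[i] - slope * cc[i]
  out <- list(c_hat = (target - intercept) / slope,
              bracket_low = c(c_actual = cc[i], power = pp[i]),
              bracket_high = c(c_actual = cc[i + 1], power = pp[i + 1]),
              slope = slope, intercept = intercept, target = target,
              status = "ok")
  class(out) <- "required_clusters"
  out
}

#' Percent change in required clusters relative to the formula value
#'
#' Expresses an interpolated required cluster count as a percent change
#' relative to the formula-based `C80`:
#' `100 * (c_hat - c80) / c80`.
#'
#' @param c_hat_cv Interpolated required cluster count (e.g. under variable
#'   sizes).
#' @param c80 Formula-based cluster count for 80% power at fixed sizes.
#' @return Percent change (positive = more clusters needed).
#' @examples
#' percent_change(79.82, 60)   # 33.0
#' @export
percent_change <- function(c_hat_cv, c80) {
  if (!is.numeric(c80) || any(c80 <= 0))
    stop("'c80' must be positive", call. = FALSE)
  100 * (c_hat_cv - c80) / c80
}

#' @export
print.required_clusters <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("Required clusters: no %.2f crossing (%s)\n",
                x$target, x$status))
    return(invisible(x))
  }
  cat(sprintf("Required clusters for power %.2f: C_hat = %.2f\n",
              x$target, x$c_hat))
  cat(sprintf("  bracket: (%g, %.4f) -- (%g, %.4f); slope %.5f, intercept %.4f\n",
              x$bracket_low["c_actual"], x$bracket_low["power"],
              x$bracket_high["c_actual"], x$bracket_high["power"],
              x$slope, x$intercept))
  invisible(x)
}
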
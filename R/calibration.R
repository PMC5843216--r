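#' Fit a linear calibration curve
#'
#' Peristaltic pumps (dispensed volume vs. commanded velocity) and pressure
#' sensors (software reading vs. manometer reference) are calibrated with a
#' straight line before use. Sensors are fitted with an intercept; pump
#' curves may be constrained through the origin (`through_origin = TRUE`),
#' since zero velocity dispenses zero volume.
#'
#' @param points data.frame with columns `command` and `response` (at least
#'   2 distinct command values).
#' @param kind `"pump"` or `"pressure_sensor"`.
#' @param through_origin force the intercept to zero (pumps only by
#'   convention, but allowed for any kind).
#' @return an object of class `calibration_curve`: `slope`, `intercept`,
#'   `r2`, `residual_sd`, `n_points`, `kind`. When the responses carry no
#'   variance, `r2` is reported as 0.
#' @examples
#' fit_calibration(data.frame(command = c(0, 100), response = c(0, 5)),
#'                 kind = "pump")
#' @export
fit_calibration <- function(points, kind = c("pump", "pressure_sensor"),
                            through_origin = FALSE) {
  kind <- match.arg(kind)
  points <- as.data.frame(points)
  if (!all(c("command", "response") %in% names(points))) {
    stopf("`points` needs columns `command` and `response`")
  }
  if (length(unique(points$command)) < 2L) {
    stopf("calibration needs at least 2 distinct command values")
  }
  fit <- if (through_origin) {
    stats::lm(response ~ 0 + command, data = points)
  } else {
    stats::lm(response ~ command, data = points)
  }
  cf <- stats::coef(fit)
  slope <- unname(cf[["command"]])
  intercept <- if (through_origin) 0 else unname(cf[["(Intercept)"]])
  sst <- sum((points$response - mean(points$response))^2)
  if (sst == 0 && !through_origin) slope <- 0  # constant response
  ssr <- sum(stats::residuals(fit)^2)
  r2 <- if (sst > 0) max(0, 1 - ssr / sst) else 0
  structure(
    list(slope = slope, intercept = intercept, r2 = r2,
         residual_sd = stats::sigma(fit), n_points = nrow(points),
         kind = kind),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: response = %.5g + %.5g * command (r2 %.4f, n = %d)\n",
              x$kind, x$intercept, x$slope, x$r2, x$n_points))
  invisible(x)
}

#' Apply or invert a calibration curve
#'
#' `apply_calibration()` predicts the response for a command;
#' `invert_calibration()` recovers the command that would produce a
#' response. For any curve with nonzero slope the two are mutual inverses.
#'
#' @param curve a [fit_calibration()] result.
#' @param command,response numeric values (vectorized).
#' @return predicted response / recovered command.
#' @export
apply_calibration <- function(curve, command) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$intercept + curve$slope * command
}

#' @rdname apply_calibration
#' @export
invert_calibration <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stopf("cannot invert a calibration with zero slope")
  (response - curve$intercept) / curve$slope
}
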
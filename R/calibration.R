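#' Ratiometric sensor calibration constants
#'
#' Holds the constants of the standard ratiometric equation
#' \deqn{[Ca^{2+}] = K (R - R_{min}) / (R_{max} - R)}
#' for a dual-wavelength Ca2+ sensor: FURA-2 (R = F340/F380, cytosol) or
#' D1ER (R = F_Citrine/F_CFP, ER lumen). K is the system-specific apparent
#' Ca2+ dissociation constant; R_min and R_max are the ratios at zero and
#' saturating Ca2+.
#'
#' The defaults are *placeholders for demonstration only*: calibration
#' constants are rig-specific and must be supplied from an instrument
#' calibration. They are not physiological measurements.
#'
#' @param sensor_id `"fura2"` or `"d1er"`.
#' @param K apparent dissociation constant (uM), > 0. Placeholder defaults:
#'   0.22 uM (fura2), 60 uM (d1er).
#' @param R_min,R_max limiting ratios, `0 < R_min < R_max`. Placeholder
#'   defaults 0.5 and 5.
#' @return An object of class `calibration_params`.
#' @examples
#' cal <- calibration_params("fura2", K = 0.2, R_min = 0.5, R_max = 5)
#' ratio_to_concentration(1, cal)
#' @export
calibration_params <- function(sensor_id = c("fura2", "d1er"),
                               K = NULL, R_min = 0.5, R_max = 5) {
  sensor_id <- match.arg(sensor_id)
  if (is.null(K)) K <- switch(sensor_id, fura2 = 0.22, d1er = 60)
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0) {
    stop("K must be a single positive finite number (uM)")
  }
  if (!(is.finite(R_min) && is.finite(R_max) && R_min > 0 && R_min < R_max)) {
    stop("require 0 < R_min < R_max")
  }
  structure(list(sensor_id = sensor_id, K = K, R_min = R_min, R_max = R_max),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat(sprintf("<calibration_params> %s: K = %g uM, R_min = %g, R_max = %g\n",
              x$sensor_id, x$K, x$R_min, x$R_max))
  invisible(x)
}

#' Convert sensor ratios to Ca2+ concentrations
#'
#' Applies the standard ratiometric equation
#' `K * (R - R_min) / (R_max - R)`. The map is strictly increasing on
#' `[R_min, R_max)` and equals 0 at `R = R_min`. Ratios at or above `R_max`
#' (or below `R_min`) are rejected rather than clipped -- silent clipping
#' would distort peak amplitudes; pre-clip explicitly if that is intended.
#'
#' @param R numeric vector of dimensionless ratios.
#' @param cal a [calibration_params()].
#' @return Concentrations (uM), same length as `R`.
#' @export
ratio_to_concentration <- function(R, cal) {
  stopifnot(inherits(cal, "calibration_params"))
  R <- as.numeric(R)
  bad <- which(R < cal$R_min | R >= cal$R_max)
  if (length(bad)) {
    stop(sprintf(
      "ratio out of calibration range [R_min, R_max) at sample index %d (R = %g)",
      bad[1], R[bad[1]]))
  }
  cal$K * (R - cal$R_min) / (cal$R_max - R)
}

#' Convert Ca2+ concentrations to sensor ratios
#'
#' Algebraic inverse of [ratio_to_concentration()]:
#' `R = (R_min * K + R_max * C) / (K + C)`. Maps 0 to `R_min` and approaches
#' `R_max` from below as C grows. Used by the synthetic-data generator to
#' emit raw-ratio traces.
#'
#' @param C numeric vector of concentrations (uM), all >= 0.
#' @param cal a [calibration_params()].
#' @return Dimensionless ratios in `[R_min, R_max)`.
#' @export
concentration_to_ratio <- function(C, cal) {
  stopifnot(inherits(cal, "calibration_params"))
  C <- as.numeric(C)
  bad <- which(C < 0 | !is.finite(C))
  if (length(bad)) {
    stop(sprintf("negative or non-finite concentration at sample index %d",
                 bad[1]))
  }
  (cal$R_min * cal$K + cal$R_max * C) / (cal$K + C)
}
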
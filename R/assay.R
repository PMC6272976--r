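#' Enzyme activity from a DNS assay reading
#'
#' Converts a 540 nm absorbance from the 3,5-dinitrosalicylic acid
#' reducing-sugar assay into enzyme activity:
#' `EA (U/mL) = (A * slope + intercept) * V * n / (v * T)`, where one unit
#' is 1 ug of d-galactose liberated per minute. The default standard-curve
#' constants (slope 640.5, intercept 13.99) come from a galactose
#' calibration and can be overridden for a different standard curve.
#'
#' @param A Absorbance at 540 nm (>= 0).
#' @param V Total reaction volume, mL (> 0).
#' @param n Dilution factor (>= 1).
#' @param v Enzyme volume, mL (> 0).
#' @param T Digestion time, min (> 0).
#' @param slope,intercept Standard-curve constants.
#' @return Enzyme activity in U/mL; vectorized over all arguments.
#' @examples
#' enzyme_activity(A = 0.35, V = 7, n = 10, v = 1, T = 60)
#' @export
enzyme_activity <- function(A, V, n, v, T, slope = 640.5, intercept = 13.99) {
  stopifnot(is.numeric(A), is.numeric(V), is.numeric(n), is.numeric(v),
            is.numeric(T))
  if (any(A < 0)) stop("invalid reading: absorbance must be >= 0", call. = FALSE)
  if (any(V <= 0)) stop("invalid reading: V must be > 0", call. = FALSE)
  if (any(n < 1)) stop("invalid reading: dilution factor must be >= 1",
                       call. = FALSE)
  if (any(v <= 0) || any(T <= 0)) {
    stop("invalid reading: enzyme volume and digestion time must be > 0",
         call. = FALSE)
  }
  (A * slope + intercept) * V * n / (v * T)
}

#' Viscosity from a rotary-viscometer reading
#'
#' `eta = k * reading`, where `k` is the rotor coefficient of the
#' instrument and `reading` its dial value.
#'
#' @param k Rotor coefficient (> 0).
#' @param reading Instrument reading (>= 0).
#' @return Viscosity; vectorized.
#' @export
viscosity <- function(k, reading) {
  stopifnot(is.numeric(k), is.numeric(reading))
  if (any(k <= 0)) stop("invalid reading: rotor coefficient must be > 0",
                        call. = FALSE)
  if (any(reading < 0)) stop("invalid reading: reading must be >= 0",
                             call. = FALSE)
  k * reading
}
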
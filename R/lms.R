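#' LMS reference parameters
#'
#' Bundle the three parameters of an LMS (lambda-mu-sigma) reference
#' distribution: the Box-Cox skewness power `L`, the median `M` (in the units
#' of the measurement), and the generalized coefficient of variation `S`.
#' Reference curves for DXA lean-mass indices (e.g. the NHANES appendicular
#' lean mass index curves) are published in this parameterization.
#'
#' @param L Unitless skewness power (may be zero or negative).
#' @param M Median of the reference distribution; must be positive.
#' @param S Coefficient of variation; must be positive.
#'
#' @return An object of class `lms_reference`.
#' @examples
#' lms_reference(L = 0.118, M = 3.457, S = 0.147)
#' @export
lms_reference <- function(L, M, S) {
  check_scalar_number(L, "L")
  check_positive(M, "M")
  check_positive(S, "S")
  structure(list(L = L, M = M, S = S), class = "lms_reference")
}

#' @export
print.lms_reference <- function(x, ...) {
  cat(sprintf("<lms_reference> L = %g, M = %g, S = %g\n", x$L, x$M, x$S))
  invisible(x)
}

#' LMS z-score of a measurement against a reference distribution
#'
#' Computes `z = ((X/M)^L - 1) / (L * S)` for `L != 0` and the continuity
#' limit `z = log(X/M) / S` at `L = 0`. The z-score locates a measurement
#' (for example a cohort's mean leg lean-mass index) within a published
#' reference distribution such as the NHANES curves.
#'
#' @param x Measurement value(s), same units as `ref$M`; must be positive.
#' @param ref An [lms_reference()].
#'
#' @return Numeric vector of z-scores, one per element of `x`.
#' @examples
#' ref <- lms_reference(L = 0.118, M = 3.457, S = 0.147)
#' lms_zscore(3.43, ref)
#' @export
lms_zscore <- function(x, ref) {
  if (!inherits(ref, "lms_reference")) {
    stop_field("ref", "must be an `lms_reference` object")
  }
  if (!is.numeric(x) || length(x) < 1L) stop_field("x", "must be numeric")
  if (any(!is.finite(x)) || any(x <= 0)) stop_field("x", "must be finite and > 0")
  if (ref$L == 0) {
    log(x / ref$M) / ref$S
  } else {
    ((x / ref$M)^ref$L - 1) / (ref$L * ref$S)
  }
}
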
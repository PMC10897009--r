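#' Gamma-variate arterial input model
#'
#' Standard bolus-shape model for the arterial concentration during a dynamic
#' susceptibility contrast passage:
#' `C_a(t) = A * (t - t0)^alpha * exp(-(t - t0)/beta)` for `t > t0`, else 0.
#'
#' @param amplitude Positive scale `A`.
#' @param delay Bolus arrival time `t0` in seconds.
#' @param shape Shape exponent `alpha` (> 0).
#' @param scale Time scale `beta` in seconds (> 0).
#'
#' @return An `aif_model` object.
#' @export
aif_model <- function(amplitude = 1, delay = 10, shape = 2.5, scale = 1.5) {
  if (amplitude <= 0 || shape <= 0 || scale <= 0) {
    stop("amplitude, shape and scale must be positive", call. = FALSE)
  }
  structure(list(amplitude = amplitude, delay = delay, shape = shape,
                 scale = scale),
            class = "aif_model")
}

#' Evaluate an AIF model on a time grid
#'
#' @param model An [aif_model()].
#' @param times Numeric vector of times in seconds.
#' @param normalize If `TRUE`, rescale so the trapezoidal integral over
#'   `times` is 1 (unit-dose bolus on this grid).
#' @return Concentration per frame (same length as `times`).
#' @export
evaluate_aif <- function(model, times, normalize = FALSE) {
  u <- times - model$delay
  c_a <- ifelse(u > 0,
                model$amplitude * u^model$shape * exp(-u / model$scale),
                0)
  if (normalize) {
    area <- pracma::trapz(times, c_a)
    if (area <= 0) stop("AIF has zero area on this grid", call. = FALSE)
    c_a <- c_a / area
  }
  c_a
}

#' @export
print.aif_model <- function(x, ...) {
  cat(sprintf("<aif_model> A=%g, t0=%gs, alpha=%g, beta=%gs\n",
              x$amplitude, x$delay, x$shape, x$scale))
  invisible(x)
}
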
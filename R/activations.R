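#' Sigmoidal activation of SC neurons
#'
#' Converts SC membrane potential to firing rate:
#' `h(r) = 2 / (1 + exp(-(slope * r)^2)) - 1` for `r >= 0`, and 0 for `r < 0`.
#' Hyperpolarized (negative) potentials are rectified to rate zero so that
#' inhibition below rest cannot generate activity; without rectification the
#' squared exponent would make `h` symmetric in `r`. Output lies in `[0, 1)`.
#'
#' @param r Membrane potential(s); vector or matrix.
#' @param slope Slope constant (> 0), default 3.4.
#' @return Firing rate(s), same shape as `r`.
#' @export
#' @examples
#' activation_h(0)            # 0
#' activation_h(1)            # ~0.99998
#' activation_h(-0.5)         # 0 (rectified)
activation_h <- function(r, slope = 3.4) {
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0) {
    stop("'slope' must be a single positive number", call. = FALSE)
  }
  rp <- pmax(r, 0)
  2 / (1 + exp(-(slope * rp)^2)) - 1
}

#' Rectified-linear activation with saturation
#'
#' The transfer function of every population except the SC output neurons:
#' `g(x) = 0` for `x < 0`, `min(k * x, 1)` otherwise, i.e. linear with slope
#' `k` clipped into `[0, 1]`. The coincidence-detector pathway uses `k = 2`;
#' all other populations use `k = 1`.
#'
#' @param x Membrane potential(s); vector or matrix.
#' @param k Slope (> 0), default 1.
#' @return Rate(s) in `[0, 1]`, same shape as `x`.
#' @export
#' @examples
#' activation_g(-0.3)      # 0
#' activation_g(2)         # 1 (clipped)
#' activation_g(0.4, k = 2) # 0.8
activation_g <- function(x, k = 1) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("'k' must be a single positive number", call. = FALSE)
  }
  pmin(pmax(k * x, 0), 1)
}
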
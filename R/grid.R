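#' Frequency grid helpers
#'
#' A grid is the shared functional domain on which every curve is evaluated:
#' a strictly increasing numeric vector of length at least 2 (Hz for power
#' spectra, arbitrary units otherwise).
#'
#' @param points numeric vector of grid points.
#' @return The validated grid (invisibly for `validate_grid`).
#' @keywords internal
validate_grid <- function(points) {
  if (!is.numeric(points) || length(points) < 2L)
    stop("grid must be a numeric vector with at least 2 points", call. = FALSE)
  if (anyNA(points) || any(!is.finite(points)))
    stop("grid points must be finite", call. = FALSE)
  if (any(diff(points) <= 0))
    stop("grid points must be strictly increasing", call. = FALSE)
  invisible(points)
}

#' Default power-spectral-density grid
#'
#' The analysis range used for resting-state EEG spectra: 1.5 to 30 Hz in
#' 0.5 Hz steps (58 points), spanning the canonical delta through beta-2
#' bands.
#'
#' @return Numeric vector of frequencies in Hz.
#' @export
#' @examples
#' g <- default_psd_grid()
#' range(g); length(g)
default_psd_grid <- function() {
  seq(1.5, 30, by = 0.5)
}

#' Trapezoidal quadrature weights for a grid
#'
#' Weights `w` such that `sum(w * f)` approximates the integral of `f` over
#' the grid range by the trapezoidal rule. Used for every L2 inner product
#' and distance in the package, so discrete computations are consistent
#' approximations of their functional counterparts.
#'
#' @param grid strictly increasing numeric vector.
#' @return Numeric vector of nonnegative weights, same length as `grid`.
#' @export
#' @examples
#' w <- trapezoid_weights(seq(0, 1, by = 0.25))
#' sum(w)  # length of the interval
trapezoid_weights <- function(grid) {
  validate_grid(grid)
  h <- diff(grid)
  c(h[1] / 2, (h[-length(h)] + h[-1]) / 2, h[length(h)] / 2)
}
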
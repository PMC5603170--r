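#' Circular Gaussian population receptive field
#'
#' A pRF summarizes the region of visual space driving one voxel's aggregate
#' response as an isotropic 2-D Gaussian with center `(x0, y0)` (degrees of
#' visual angle), size `sigma` (the Gaussian standard deviation, degrees), and
#' response amplitude `beta` (arbitrary BOLD units).
#'
#' @param x0,y0 Center of the receptive field, degrees of visual angle.
#' @param sigma Gaussian standard deviation, degrees; must be positive.
#' @param beta Response amplitude scaling the predicted BOLD signal.
#' @return An object of class `prf`.
#' @examples
#' p <- prf(1, -2, 0.8)
#' to_polar(p)
#' @export
prf <- function(x0, y0, sigma, beta = 1) {
  if (!all(is.finite(c(x0, y0, sigma, beta))))
    stop("pRF parameters must be finite")
  if (sigma <= 0) stop("'sigma' must be positive")
  structure(list(x0 = x0, y0 = y0, sigma = sigma, beta = beta),
            class = "prf")
}

#' @export
print.prf <- function(x, ...) {
  cat(sprintf("pRF: center (%.3g, %.3g) deg, sigma %.3g deg, beta %.3g\n",
              x$x0, x$y0, x$sigma, x$beta))
  invisible(x)
}

#' Gaussian pRF weights over a visual-field grid
#'
#' Evaluates the pRF weighting function
#' \deqn{w_i = \exp\left(-\frac{(x_i - x_0)^2 + (y_i - y_0)^2}{2\sigma^2}\right)}
#' at every pixel of the grid.
#'
#' @param prf A [prf()].
#' @param grid A [vf_grid()].
#' @return Matrix of weights in (0, 1], same dimension as the grid.
#' @export
gaussian_weights <- function(prf, grid) {
  stopifnot(inherits(prf, "prf"), inherits(grid, "vf_grid"))
  exp(-((grid$x - prf$x0)^2 + (grid$y - prf$y0)^2) / (2 * prf$sigma^2))
}

#' Polar-coordinate summary of a pRF position
#'
#' @param prf A [prf()].
#' @return List with `polar_angle` (`atan2(y0, x0)`, radians, four-quadrant)
#'   and `eccentricity` (`sqrt(x0^2 + y0^2)`, degrees).
#' @export
to_polar <- function(prf) {
  stopifnot(inherits(prf, "prf"))
  list(polar_angle = atan2(prf$y0, prf$x0),
       eccentricity = sqrt(prf$x0^2 + prf$y0^2))
}
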
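#' Visual-field pixel grid
#'
#' Constructs a square pixel grid over the visual field, in degrees of visual
#' angle, with the origin at fixation. The x axis points rightward and the y
#' axis upward; because image row indices increase downward, the y coordinate
#' of row 1 is the largest (an explicit y-axis flip relative to matrix
#' indexing).
#'
#' @param extent_deg Width (= height) of the square stimulus area, in degrees
#'   of visual angle.
#' @param pixels_per_degree Sampling density of the grid.
#' @return An object of class `vf_grid`: a list with elements `n` (pixels per
#'   side), `extent_deg`, `pixels_per_degree`, `radius_deg` (= extent/2), and
#'   matrices `x`, `y` giving per-pixel visual-field coordinates (degrees).
#' @examples
#' g <- vf_grid(11, 538 / 11)   # the 538 x 538 display grid
#' dim(g$x)
#' @export
vf_grid <- function(extent_deg, pixels_per_degree) {
  if (!is.numeric(extent_deg) || length(extent_deg) != 1L || extent_deg <= 0)
    stop("'extent_deg' must be a positive number")
  if (!is.numeric(pixels_per_degree) || length(pixels_per_degree) != 1L ||
      pixels_per_degree <= 0)
    stop("'pixels_per_degree' must be a positive number")
  n <- round(extent_deg * pixels_per_degree)
  if (n < 1) stop("grid resolves to zero pixels")
  # pixel centers, symmetric about 0
  cc <- (seq_len(n) - (n + 1) / 2) / pixels_per_degree
  g <- list(
    n = as.integer(n),
    extent_deg = extent_deg,
    pixels_per_degree = pixels_per_degree,
    radius_deg = extent_deg / 2,
    x = matrix(cc, n, n, byrow = TRUE),
    y = matrix(rev(cc), n, n, byrow = FALSE)
  )
  class(g) <- "vf_grid"
  g
}

#' @export
print.vf_grid <- function(x, ...) {
  cat(sprintf(
    "Visual-field grid: %d x %d px, %.3g deg extent (%.3g px/deg)\n",
    x$n, x$n, x$extent_deg, x$pixels_per_degree))
  invisible(x)
}

#' Logical mask of pixels inside the circular stimulus area
#'
#' @param grid A [vf_grid()].
#' @param radius_deg Radius of the stimulus circle; defaults to half the grid
#'   extent.
#' @return Logical matrix, `TRUE` inside the circle.
#' @export
stimulus_area <- function(grid, radius_deg = grid$radius_deg) {
  stopifnot(inherits(grid, "vf_grid"))
  grid$x^2 + grid$y^2 <= radius_deg^2
}

# shared check used by several constructors
assert_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$n, b$n)) ||
      !isTRUE(all.equal(a$extent_deg, b$extent_deg)))
    stop("objects are defined on different visual-field grids")
  invisible(TRUE)
}
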
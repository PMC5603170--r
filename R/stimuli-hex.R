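#' Hexagonal-cell layout of the synthetic stimuli
#'
#' The synthetic identification stimuli are built on a fixed hexagonal grid of
#' 60 cells tiling the circular stimulus area. The layout `"hex60"` uses a
#' pointy-top hexagonal lattice with circumradius 0.67 deg; the 61 lattice
#' cells whose centers fall within (radius - cell size) of fixation form five
#' complete rings, and the central cell -- which hosts the fixation dot -- is
#' excluded, leaving exactly 60 cells.
#'
#' @param layout_id Layout identifier; only `"hex60"` is defined.
#' @param radius_deg Stimulus radius, degrees.
#' @return List with `centers` (60 x 2 matrix of cell-center coordinates,
#'   degrees), `cell_size_deg` (hex circumradius), `radius_deg`, `layout_id`,
#'   and `all_centers` (the full lattice neighborhood, used to delimit cell
#'   boundaries when rendering).
#' @export
hex_layout <- function(layout_id = "hex60", radius_deg = 5.5) {
  if (!identical(layout_id, "hex60"))
    stop("unknown hexagon layout: ", layout_id)
  s <- 0.67 * radius_deg / 5.5 # scale with the aperture
  qmax <- ceiling(2 * radius_deg / s)
  g <- expand.grid(q = -qmax:qmax, r = -qmax:qmax)
  x <- s * sqrt(3) * (g$q + g$r / 2)
  y <- s * 1.5 * g$r
  ecc <- sqrt(x^2 + y^2)
  keep <- ecc <= radius_deg - s & ecc > s / 2 # drop the central cell
  centers <- cbind(x = x[keep], y = y[keep])
  centers <- centers[order(-centers[, "y"], centers[, "x"]), , drop = FALSE]
  near <- ecc <= radius_deg + 2 * s
  list(centers = centers, cell_size_deg = s, radius_deg = radius_deg,
       layout_id = layout_id,
       all_centers = cbind(x = x[near], y = y[near]))
}

#' Random hexagonal stimulus pattern
#'
#' Draws one of the 2^60 possible synthetic patterns: each of the 60 cells of
#' the hexagonal layout is independently filled (with binarized bandpass
#' noise, rendered as "on") or left at mean luminance.
#'
#' @param fill_probability Probability that a cell is filled.
#' @param seed Optional RNG seed.
#' @param layout_id Hexagon layout identifier (see [hex_layout()]).
#' @return An object of class `hex_pattern`: integer vector of 60 cell states
#'   in \{0, 1\} with the layout id as an attribute.
#' @export
random_hex_pattern <- function(fill_probability = 0.5, seed = NULL,
                               layout_id = "hex60") {
  if (fill_probability < 0 || fill_probability > 1)
    stop("'fill_probability' must be in [0, 1]")
  states <- with_seed(seed,
    as.integer(stats::runif(60) < fill_probability))
  hex_pattern(states, layout_id)
}

#' @rdname random_hex_pattern
#' @param cell_states Integer vector of 60 values in \{0, 1\}.
#' @export
hex_pattern <- function(cell_states, layout_id = "hex60") {
  cell_states <- as.integer(cell_states)
  if (length(cell_states) != 60L || !all(cell_states %in% c(0L, 1L)))
    stop("a hex pattern has exactly 60 binary cell states")
  structure(cell_states, layout_id = layout_id, class = "hex_pattern")
}

#' @export
print.hex_pattern <- function(x, ...) {
  cat(sprintf("Hex pattern (%s): %d of 60 cells filled\n",
              attr(x, "layout_id"), sum(x)))
  invisible(x)
}

#' Render a hexagonal pattern as a binary stimulus image
#'
#' Pixels inside the circular aperture are assigned to the nearest cell of
#' the hexagonal lattice (the lattice Voronoi cells are the hexagons); pixels
#' in filled cells are set to 1, all others to 0. This is the binary stimulus
#' `S` used by the overlap prediction: 1 where stimulus energy is present, 0
#' at mean luminance.
#'
#' @param pattern A [hex_pattern()].
#' @param grid A [vf_grid()]; must resolve the cells (at least 4 pixels per
#'   cell diameter).
#' @return Binary matrix of the grid's dimension.
#' @export
render_hex_stimulus <- function(pattern, grid) {
  stopifnot(inherits(pattern, "hex_pattern"), inherits(grid, "vf_grid"))
  layout <- hex_layout(attr(pattern, "layout_id"),
                       radius_deg = grid$radius_deg)
  cell_diam <- sqrt(3) * layout$cell_size_deg # width across flats
  if (grid$pixels_per_degree * cell_diam < 4)
    stop("grid too coarse to resolve hexagonal cells ",
         "(need >= 4 pixels per cell diameter)")
  xv <- as.vector(grid$x); yv <- as.vector(grid$y)
  inside <- as.vector(stimulus_area(grid, layout$radius_deg))
  all_c <- layout$all_centers
  # nearest lattice center over the full neighborhood, tracked incrementally
  best_d <- rep(Inf, length(xv)); best_i <- rep(NA_integer_, length(xv))
  for (i in seq_len(nrow(all_c))) {
    d <- (xv - all_c[i, 1])^2 + (yv - all_c[i, 2])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]; best_i[upd] <- i
  }
  # map lattice index -> pattern cell index (0 if not one of the 60)
  cell_of <- integer(nrow(all_c))
  for (k in seq_len(nrow(layout$centers))) {
    j <- which(abs(all_c[, 1] - layout$centers[k, 1]) < 1e-9 &
               abs(all_c[, 2] - layout$centers[k, 2]) < 1e-9)
    cell_of[j] <- k
  }
  cell_idx <- cell_of[best_i]
  on <- inside & cell_idx > 0L & as.integer(pattern)[pmax(cell_idx, 1L)] == 1L
  matrix(as.numeric(on), grid$n, grid$n)
}
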
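#' Moving-bar aperture sequence for pRF mapping
#'
#' Builds the conventional contrast-defined moving-bar mapping stimulus as a
#' sequence of binary aperture masks. A bar of fixed width sweeps across the
#' circular stimulus area in discrete steps; four bar orientations (0, 45, 90,
#' 135 degrees) are each traversed in two opposite directions (8 passes), and
#' a mean-luminance (all-zero) block follows every horizontally or vertically
#' oriented pass, giving 4 blank blocks per run.
#'
#' With the defaults (radius 5.5 deg, 20 steps of 0.55 deg, bar width
#' radius/4 = 1.375 deg, 20-frame blanks) the sequence has
#' 8 x 20 + 4 x 20 = 240 frames of 1.5 s each.
#'
#' @param grid A [vf_grid()] covering the stimulus area.
#' @param radius_deg Stimulus radius, degrees.
#' @param bar_width_deg Bar width (extent along its motion axis), degrees.
#' @param n_steps Bar positions per pass.
#' @param frame_duration_s Seconds per frame (the TR).
#' @param blank_frames Length of each mean-luminance block, frames.
#' @return An object of class `aperture_seq`: list with `frames` (pixels x
#'   time binary matrix, pixels in column-major grid order), `grid`,
#'   `frame_duration_s`, and a per-frame `frame_info` data frame (pass,
#'   orientation, direction, step; NA for blanks).
#' @export
bar_aperture_sequence <- function(grid,
                                  radius_deg = grid$radius_deg,
                                  bar_width_deg = radius_deg / 4,
                                  n_steps = 20,
                                  frame_duration_s = 1.5,
                                  blank_frames = 20) {
  stopifnot(inherits(grid, "vf_grid"))
  step <- 2 * radius_deg / n_steps
  if (bar_width_deg > 2 * radius_deg || step > 2 * radius_deg)
    stop("bar width or step exceeds the stimulus aperture")
  inside <- as.vector(stimulus_area(grid, radius_deg))
  xv <- as.vector(grid$x); yv <- as.vector(grid$y)

  orientations <- c(0, 45, 90, 135, 0, 45, 90, 135)
  directions   <- c(1, 1, 1, 1, -1, -1, -1, -1)
  frames <- list()
  info <- list()
  for (p in seq_along(orientations)) {
    th <- orientations[p] * pi / 180
    # motion axis is perpendicular to the bar's long axis
    proj <- -xv * sin(th) + yv * cos(th)
    offsets <- -radius_deg + (seq_len(n_steps) - 0.5) * step
    if (directions[p] < 0) offsets <- rev(offsets)
    for (k in seq_len(n_steps)) {
      m <- as.numeric(abs(proj - offsets[k]) <= bar_width_deg / 2 & inside)
      frames[[length(frames) + 1L]] <- m
      info[[length(info) + 1L]] <-
        c(pass = p, orientation = orientations[p],
          direction = directions[p], step = k)
    }
    if (orientations[p] %in% c(0, 90)) {
      for (b in seq_len(blank_frames)) {
        frames[[length(frames) + 1L]] <- numeric(length(xv))
        info[[length(info) + 1L]] <-
          c(pass = NA, orientation = NA, direction = NA, step = NA)
      }
    }
  }
  out <- list(
    frames = do.call(cbind, frames),
    grid = grid,
    frame_duration_s = frame_duration_s,
    frame_info = as.data.frame(do.call(rbind, info))
  )
  class(out) <- "aperture_seq"
  out
}

#' Wrap a binary frame matrix as an aperture sequence
#'
#' Low-level constructor for aperture sequences built outside
#' [bar_aperture_sequence()] (e.g. in tests or custom designs).
#'
#' @param frames Pixels x time matrix with values in \{0, 1\} (column-major
#'   grid order).
#' @param grid The [vf_grid()] the frames live on.
#' @param frame_duration_s Seconds per frame.
#' @export
aperture_sequence <- function(frames, grid, frame_duration_s = 1.5) {
  stopifnot(inherits(grid, "vf_grid"))
  frames <- as.matrix(frames)
  if (nrow(frames) != grid$n^2)
    stop("frame matrix does not match the grid (expected ",
         grid$n^2, " pixels per frame)")
  if (!all(frames %in% c(0, 1))) stop("aperture frames must be binary")
  structure(list(frames = frames, grid = grid,
                 frame_duration_s = frame_duration_s, frame_info = NULL),
            class = "aperture_seq")
}

#' @export
print.aperture_seq <- function(x, ...) {
  cat(sprintf(
    "Aperture sequence: %d frames of %.3g s on a %d x %d grid (%.3g deg)\n",
    ncol(x$frames), x$frame_duration_s, x$grid$n, x$grid$n,
    x$grid$extent_deg))
  invisible(x)
}

#' Number of frames in an aperture sequence
#' @param x An `aperture_seq`.
#' @export
n_frames <- function(x) ncol(x$frames)

#' Extract one aperture frame as a grid-shaped matrix
#' @param x An `aperture_seq`.
#' @param t Frame index.
#' @export
aperture_frame <- function(x, t) {
  matrix(x$frames[, t], x$grid$n, x$grid$n)
}
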
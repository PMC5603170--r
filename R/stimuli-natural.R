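#' Raised-cosine circular window
#'
#' Window weights used to fade natural images into the mean-luminance
#' surround: weight 1 inside `radius - edge_width`, a half-cosine ramp to 0
#' at `radius`, and 0 outside.
#'
#' @param grid A [vf_grid()].
#' @param radius_deg Outer radius of the window, degrees.
#' @param edge_width_deg Width of the cosine ramp, degrees.
#' @return Matrix of weights in [0, 1].
#' @export
raised_cosine_mask <- function(grid, radius_deg = grid$radius_deg,
                               edge_width_deg = 0.9) {
  stopifnot(inherits(grid, "vf_grid"))
  r <- sqrt(grid$x^2 + grid$y^2)
  w <- matrix(0, grid$n, grid$n)
  w[r <= radius_deg - edge_width_deg] <- 1
  ramp <- r > radius_deg - edge_width_deg & r <= radius_deg
  w[ramp] <- 0.5 * (1 + cos(pi * (r[ramp] - (radius_deg - edge_width_deg)) /
                              edge_width_deg))
  w
}

# bilinear resampling of a square matrix onto an n x n target
resample_bilinear <- function(img, n_out) {
  n_in <- nrow(img)
  if (n_in == n_out) return(img)
  # map target pixel centers onto source pixel-center coordinates
  pos <- (seq_len(n_out) - 0.5) / n_out * n_in + 0.5
  pos <- pmin(pmax(pos, 1), n_in)
  i0 <- pmin(floor(pos), n_in - 1L); fi <- pos - i0
  out <- matrix(0, n_out, n_out)
  for (j in seq_len(n_out)) {
    c0 <- i0[j]; fc <- fi[j]
    colA <- img[, c0] * (1 - fc) + img[, c0 + 1] * fc
    out[, j] <- colA[i0] * (1 - fi) + colA[i0 + 1] * fi
  }
  out
}

#' Preprocess a natural image for pRF-based prediction
#'
#' Resamples a square (gamma-linearized) luminance matrix to the grid,
#' windows its deviations from mean luminance with a raised-cosine circular
#' mask, and rescales the deviations so that the whole-image RMS contrast --
#' the root-mean-square of `(L - Lmean)/Lmean` -- hits the target (default
#' 50%). The result is clipped to [0, 1]; clipping can shave the achieved
#' contrast, so the rescaling is iterated and a deviation above 2% relative
#' draws a warning. Pixels outside the circle sit exactly at mean luminance.
#'
#' @param raw Square numeric matrix of linear luminance values.
#' @param grid A [vf_grid()].
#' @param edge_width_deg Raised-cosine edge width, degrees.
#' @param target_rms Target whole-image RMS contrast, as a fraction of mean
#'   luminance.
#' @param mean_luminance Display mean luminance on the [0, 1] scale.
#' @return An object of class `natural_image`: list with `luminance` (matrix
#'   in [0, 1]), `mask` (the window weights), `grid`, `achieved_rms`, and
#'   `mean_luminance`.
#' @export
preprocess_natural_image <- function(raw, grid, edge_width_deg = 0.9,
                                     target_rms = 0.5,
                                     mean_luminance = 0.5) {
  stopifnot(inherits(grid, "vf_grid"))
  raw <- as.matrix(raw)
  if (nrow(raw) != ncol(raw)) stop("'raw' must be a square luminance matrix")
  if (stats::sd(raw) == 0)
    stop("constant input image: zero contrast cannot be rescaled")
  img <- resample_bilinear(raw, grid$n)
  mask <- raised_cosine_mask(grid, edge_width_deg = edge_width_deg)
  dev <- (img - mean(img)) * mask
  if (all(dev == 0))
    stop("image is constant inside the window: cannot set contrast")
  lum <- NULL
  achieved <- 0
  scale <- target_rms * mean_luminance / sqrt(mean(dev^2))
  for (iter in 1:3) {
    lum <- pmin(pmax(mean_luminance + scale * dev, 0), 1)
    achieved <- sqrt(mean((lum - mean_luminance)^2)) / mean_luminance
    if (abs(achieved - target_rms) / target_rms < 1e-6) break
    scale <- scale * target_rms / achieved
  }
  if (abs(achieved - target_rms) / target_rms > 0.02)
    warning(sprintf(
      "achieved RMS contrast %.4f deviates from target %.4f by more than 2%% (clipping)",
      achieved, target_rms))
  structure(list(luminance = lum, mask = mask, grid = grid,
                 achieved_rms = achieved, mean_luminance = mean_luminance),
            class = "natural_image")
}

#' @export
print.natural_image <- function(x, ...) {
  cat(sprintf(
    "Natural image: %d x %d px, RMS contrast %.3f (mean luminance %.2f)\n",
    nrow(x$luminance), ncol(x$luminance), x$achieved_rms, x$mean_luminance))
  invisible(x)
}

#' Procedurally generated natural-style test image (synthetic)
#'
#' Produces a synthetic stand-in for a natural photograph: low-pass filtered
#' noise with a spatially varying contrast envelope, passed through
#' [preprocess_natural_image()]. These textures share the key statistics the
#' contrast-energy model is sensitive to (broad luminance spectrum, local
#' contrast variation) but are not real scenes; they exist so the natural
#' image pipeline can be exercised without an external image dataset.
#'
#' @param grid A [vf_grid()].
#' @param seed Optional RNG seed.
#' @param cutoff_cpd Low-pass cutoff of the luminance field, cycles/degree.
#' @inheritParams preprocess_natural_image
#' @return A `natural_image`.
#' @export
simulate_natural_texture <- function(grid, seed = NULL, cutoff_cpd = 2,
                                     edge_width_deg = 0.9, target_rms = 0.5) {
  stopifnot(inherits(grid, "vf_grid"))
  n <- grid$n
  fields <- with_seed(seed, {
    list(base = matrix(stats::rnorm(n * n), n, n),
         env = matrix(stats::rnorm(n * n), n, n))
  })
  f <- fft_freq_grid(n, grid$pixels_per_degree)
  lowpass <- function(w, fc) {
    H <- exp(-f^2 / (2 * fc^2))
    Re(stats::fft(stats::fft(w) * H, inverse = TRUE)) / (n * n)
  }
  base <- lowpass(fields$base, cutoff_cpd)
  env <- lowpass(fields$env, cutoff_cpd / 4)
  env <- 0.2 + 0.8 * (env - min(env)) / (max(env) - min(env))
  raw <- 0.5 + base * env / (4 * stats::sd(base))
  preprocess_natural_image(raw, grid, edge_width_deg = edge_width_deg,
                           target_rms = target_rms)
}
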
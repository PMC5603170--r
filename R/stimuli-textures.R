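# Seeded evaluation without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Per-pixel spatial-frequency magnitude (cycles/degree) in FFT layout.
fft_freq_grid <- function(n, pixels_per_degree) {
  f1 <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) / n *
    pixels_per_degree
  fx <- matrix(f1, n, n, byrow = TRUE)
  fy <- matrix(f1, n, n, byrow = FALSE)
  sqrt(fx^2 + fy^2)
}

#' Binarized bandpass-filtered noise texture
#'
#' Generates the high-contrast carrier texture used in the mapping bars and
#' synthetic patterns: white noise filtered by an annular spatial-frequency
#' band centered on a fundamental frequency (default 1.5 cycles/degree), then
#' binarized at its median so exactly half the pixels are on.
#'
#' @param grid A [vf_grid()].
#' @param fundamental_cpd Center of the spatial-frequency band,
#'   cycles/degree; must lie below the grid Nyquist frequency.
#' @param bandwidth_cpd Gaussian bandwidth (SD) of the annular filter;
#'   defaults to a quarter of the fundamental.
#' @param seed Optional RNG seed for reproducibility.
#' @param binarize If `FALSE`, return the filtered field before median
#'   binarization (useful for inspecting its spectrum).
#' @return Matrix of \{0, 1\} values (or the real-valued field if
#'   `binarize = FALSE`).
#' @export
bandpass_noise <- function(grid, fundamental_cpd = 1.5,
                           bandwidth_cpd = fundamental_cpd / 4,
                           seed = NULL, binarize = TRUE) {
  stopifnot(inherits(grid, "vf_grid"))
  nyquist <- grid$pixels_per_degree / 2
  if (fundamental_cpd >= nyquist)
    stop(sprintf(
      "fundamental (%.3g cpd) is at or above the grid Nyquist frequency (%.3g cpd)",
      fundamental_cpd, nyquist))
  n <- grid$n
  white <- with_seed(seed, matrix(stats::rnorm(n * n), n, n))
  f <- fft_freq_grid(n, grid$pixels_per_degree)
  H <- exp(-(f - fundamental_cpd)^2 / (2 * bandwidth_cpd^2))
  H[1, 1] <- 0 # remove DC
  field <- Re(stats::fft(stats::fft(white) * H, inverse = TRUE)) / (n * n)
  if (!binarize) return(field)
  (field > stats::median(field)) * 1
}
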
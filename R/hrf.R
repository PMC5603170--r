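#' Two-gamma hemodynamic response function parameters
#'
#' Parameterizes the canonical difference-of-gammas impulse response linking
#' neural drive to the BOLD signal: a positive response gamma peaking around
#' 5 s minus a scaled undershoot gamma peaking around 15 s. The kernel is
#' causal (zero at time 0) and truncated to a finite window.
#'
#' @param peak_delay Delay (gamma shape x scale) of the response gamma,
#'   seconds; the kernel peaks at `peak_delay - dispersion`.
#' @param undershoot_delay Delay of the undershoot gamma, seconds.
#' @param dispersion,u_dispersion Dispersion (gamma scale) of the response and
#'   undershoot components, seconds.
#' @param ratio Amplitude of the undershoot relative to the peak.
#' @param tr Sampling interval of the kernel, seconds (the scan TR).
#' @param duration Length of the kernel window, seconds.
#' @return An object of class `hrf_params`.
#' @export
hrf_parameters <- function(peak_delay = 6, undershoot_delay = 16,
                           dispersion = 1, u_dispersion = 1,
                           ratio = 1 / 6, tr = 1.5, duration = 32) {
  if (dispersion <= 0 || u_dispersion <= 0)
    stop("dispersions must be positive")
  if (tr <= 0) stop("'tr' must be positive")
  if (peak_delay <= dispersion)
    stop("'peak_delay' must exceed 'dispersion' for a causal kernel")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 dispersion = dispersion, u_dispersion = u_dispersion,
                 ratio = ratio, tr = tr, duration = duration),
            class = "hrf_params")
}

#' @export
print.hrf_params <- function(x, ...) {
  cat(sprintf(
    "Two-gamma HRF: peak %.3g s, undershoot %.3g s (ratio %.3g), TR %.3g s\n",
    x$peak_delay, x$undershoot_delay, x$ratio, x$tr))
  invisible(x)
}

#' Sampled HRF kernel
#'
#' @param params An [hrf_parameters()] object.
#' @return Numeric vector of kernel samples at times `0, tr, 2 tr, ...` up to
#'   `duration`, normalized to unit peak; attribute `times` holds the sample
#'   times.
#' @export
hrf_kernel <- function(params = hrf_parameters()) {
  stopifnot(inherits(params, "hrf_params"))
  tt <- seq(0, params$duration, by = params$tr)
  h <- stats::dgamma(tt, shape = params$peak_delay / params$dispersion,
                     scale = params$dispersion) -
    params$ratio *
    stats::dgamma(tt, shape = params$undershoot_delay / params$u_dispersion,
                  scale = params$u_dispersion)
  h <- h / max(h)
  attr(h, "times") <- tt
  h
}

# Causal discrete convolution of the columns of a time x k matrix (or a
# vector) with a kernel, truncated to the input length. Direct (matrix)
# convolution rather than FFT, so structural zeros stay exactly zero.
convolve_hrf <- function(x, kernel) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  nt <- nrow(x)
  crossprod(conv_matrix(kernel, nt), x)
}

# nt x nt matrix M with M[s, t] = kernel[t - s + 1], so that for a series
# matrix A (units x time), A %*% M is the causal truncated convolution of
# each row with the kernel.
conv_matrix <- function(kernel, nt) {
  M <- matrix(0, nt, nt)
  for (s in seq_len(nt)) {
    idx <- s:min(nt, s + length(kernel) - 1L)
    M[s, idx] <- kernel[seq_along(idx)]
  }
  M
}
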
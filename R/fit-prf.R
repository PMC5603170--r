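#' Predicted BOLD time series for a pRF
#'
#' Forward model of the mapping experiment: the neural drive at each time
#' frame is the overlap of the pRF weights with the binary aperture
#' (`sum_i w_i * frame_i`), which is convolved with the HRF kernel, truncated
#' to the scan length, and scaled by the pRF amplitude `beta`.
#'
#' @param prf A [prf()].
#' @param apertures An `aperture_seq` on the same grid.
#' @param hrf [hrf_parameters()] for the convolution kernel.
#' @return Numeric vector, one value per frame.
#' @export
predict_bold_timeseries <- function(prf, apertures,
                                    hrf = hrf_parameters(
                                      tr = apertures$frame_duration_s)) {
  stopifnot(inherits(prf, "prf"), inherits(apertures, "aperture_seq"))
  if (ncol(apertures$frames) == 0L) stop("empty aperture sequence")
  w <- as.vector(gaussian_weights(prf, apertures$grid))
  drive <- as.vector(crossprod(apertures$frames, w))
  prf$beta * as.vector(convolve_hrf(drive, hrf_kernel(hrf)))
}

#' Variance explained of a prediction
#'
#' `1 - RSS/TSS`, where RSS is the residual sum of squares of the prediction
#' and TSS the total sum of squares of the measured series about its mean;
#' floored at 0.
#'
#' @param predicted,measured Numeric vectors of equal length.
#' @return Fraction in [0, 1].
#' @export
variance_explained <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("series lengths differ")
  tss <- sum((measured - mean(measured))^2)
  if (tss == 0) stop("measured series is constant")
  max(0, 1 - sum((measured - predicted)^2) / tss)
}

#' Search specification for pRF fitting
#'
#' Coarse-to-fine search settings: candidate centers on a square grid
#' covering +/- `position_factor` times the aperture radius at
#' `position_spacing` degrees, sizes log-spaced over `sigma_range`, followed
#' by derivative-free local refinement from the best grid point.
#'
#' @param position_spacing Grid spacing for candidate centers, degrees.
#' @param position_factor Half-extent of the center grid as a multiple of
#'   the aperture radius (centers slightly outside the aperture are allowed
#'   so border pRFs are not clamped).
#' @param sigma_range Range of candidate sizes, degrees.
#' @param n_sigma Number of log-spaced candidate sizes.
#' @param refine Run local (Nelder-Mead) refinement after the grid stage.
#' @param reltol Relative convergence tolerance on the RSS during refinement.
#' @export
prf_search <- function(position_spacing = 0.25, position_factor = 1.2,
                       sigma_range = c(0.1, 5), n_sigma = 12,
                       refine = TRUE, reltol = 1e-9) {
  structure(list(position_spacing = position_spacing,
                 position_factor = position_factor,
                 sigma_range = sigma_range, n_sigma = n_sigma,
                 refine = refine, reltol = reltol),
            class = "prf_search")
}

# closed-form intercept + amplitude fit of y against drive d:
# returns c(rss, beta, b0); beta = cov(d, y) / var(d)
.beta_fit <- function(d, y) {
  dc <- d - mean(d); yc <- y - mean(y)
  den <- sum(dc^2)
  if (den < .Machine$double.eps) return(c(sum(yc^2), 0, mean(y)))
  beta <- sum(dc * yc) / den
  rss <- sum(yc^2) - beta^2 * den
  c(max(rss, 0), beta, mean(y) - beta * mean(d))
}

#' Fit circular Gaussian pRF models to voxel time series
#'
#' Estimates, for every voxel, the pRF position (x0, y0), size (sigma) and
#' amplitude (beta) that minimize the residual sum of squares between the
#' HRF-convolved overlap prediction and the measured series. Amplitude and a
#' baseline term are solved in closed form for every candidate; position and
#' size are found by a coarse grid search followed by local Nelder-Mead
#' refinement. Fit quality is summarized as variance explained
#' (1 - RSS/TSS).
#'
#' @param series Numeric vector (one voxel) or voxels x frames matrix.
#' @param apertures The mapping stimulus, an `aperture_seq`.
#' @param hrf [hrf_parameters()]; defaults to the canonical two-gamma kernel
#'   sampled at the aperture frame duration.
#' @param search A [prf_search()] specification.
#' @return An object of class `prf_fit`: list with `fits` (data frame, one
#'   row per voxel: x0, y0, sigma, beta, baseline, rss, variance_explained,
#'   polar_angle, eccentricity), plus the call, search spec, hrf and the
#'   aperture sequence used.
#' @examples
#' g <- vf_grid(11, 3)
#' ap <- bar_aperture_sequence(g)
#' hrf <- hrf_parameters(tr = 1.5)
#' y <- predict_bold_timeseries(prf(1, -2, 0.8, beta = 2), ap, hrf)
#' fit <- fit_prf(y, ap, hrf, prf_search(position_spacing = 1, n_sigma = 5))
#' coef(fit)
#' @export
fit_prf <- function(series, apertures,
                    hrf = hrf_parameters(tr = apertures$frame_duration_s),
                    search = prf_search()) {
  stopifnot(inherits(apertures, "aperture_seq"))
  if (is.null(dim(series))) series <- matrix(series, nrow = 1L)
  nt <- ncol(apertures$frames)
  if (nt == 0L || all(apertures$frames == 0))
    stop("aperture sequence carries no stimulus energy")
  if (ncol(series) != nt)
    stop("series length (", ncol(series),
         ") does not match the aperture frame count (", nt, ")")
  sds <- apply(series, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant time series for voxel(s): ",
         paste(which(sds == 0), collapse = ", "))

  grid <- apertures$grid
  kernel <- hrf_kernel(hrf)
  # convolve each pixel's aperture series once; spatial sum and temporal
  # convolution commute
  P <- apertures$frames %*% conv_matrix(kernel, nt) # pixels x time

  b <- search$position_factor * grid$radius_deg
  xs <- seq(-b, b, by = search$position_spacing)
  sig <- exp(seq(log(search$sigma_range[1]), log(search$sigma_range[2]),
                 length.out = search$n_sigma))
  cand <- as.matrix(expand.grid(x0 = xs, y0 = xs))
  xv <- as.vector(grid$x); yv <- as.vector(grid$y)

  nv <- nrow(series)
  Yc <- series - rowMeans(series)
  tssv <- rowSums(Yc^2)
  best_r2 <- rep(-Inf, nv)
  best_par <- matrix(0, nv, 3L)
  for (s in sig) {
    W <- exp(-(outer(cand[, 1], xv, "-")^2 +
                 outer(cand[, 2], yv, "-")^2) / (2 * s^2))
    D <- W %*% P                      # candidates x time
    Dc <- D - rowMeans(D)
    den <- rowSums(Dc^2)
    num <- Dc %*% t(Yc)               # candidates x voxels
    ok <- den > .Machine$double.eps
    r2 <- num^2 / ifelse(ok, den, Inf) # explained SS per candidate/voxel
    top <- max.col(t(r2), ties.method = "first")
    val <- r2[cbind(top, seq_len(nv))]
    upd <- val > best_r2
    best_r2[upd] <- val[upd]
    best_par[upd, ] <- cbind(cand[top[upd], 1], cand[top[upd], 2], s)
  }

  rss_of <- function(par, y) {
    sg <- exp(par[3])
    w <- exp(-((xv - par[1])^2 + (yv - par[2])^2) / (2 * sg^2))
    d <- as.vector(crossprod(P, w))
    .beta_fit(d, y)[1]
  }
  rows <- vector("list", nv)
  for (v in seq_len(nv)) {
    y <- series[v, ]
    par <- c(best_par[v, 1:2], log(best_par[v, 3]))
    if (search$refine) {
      opt <- stats::optim(par, rss_of, y = y, method = "Nelder-Mead",
                          control = list(reltol = search$reltol,
                                         maxit = 2000))
      # keep the refined point only if it did not wander off the aperture
      if (is.finite(opt$value) &&
          sqrt(opt$par[1]^2 + opt$par[2]^2) <= 2 * b) par <- opt$par
    }
    sg <- exp(par[3])
    w <- exp(-((xv - par[1])^2 + (yv - par[2])^2) / (2 * sg^2))
    d <- as.vector(crossprod(P, w))
    bf <- .beta_fit(d, y)
    rows[[v]] <- data.frame(
      voxel = v, x0 = par[1], y0 = par[2], sigma = sg,
      beta = bf[2], baseline = bf[3], rss = bf[1],
      variance_explained = max(0, 1 - bf[1] / tssv[v]),
      polar_angle = atan2(par[2], par[1]),
      eccentricity = sqrt(par[1]^2 + par[2]^2))
  }
  structure(list(fits = do.call(rbind, rows), call = match.call(),
                 search = search, hrf = hrf, apertures = apertures,
                 series = series),
            class = "prf_fit")
}

#' Whole-dataset HRF refit by grid search
#'
#' The mapping analysis defaults to a canonical two-gamma kernel; this
#' optional refinement searches a small grid of peak delays and undershoot
#' ratios for the kernel that minimizes the total residual sum of squares
#' across all fitted voxels, holding the fitted pRF positions and sizes
#' fixed (amplitude and baseline are re-solved in closed form per voxel).
#'
#' @param fit A `prf_fit`.
#' @param peak_delays Candidate peak-delay values, seconds.
#' @param ratios Candidate undershoot ratios.
#' @return The best-fitting [hrf_parameters()], with the achieved total RSS
#'   as attribute `total_rss`.
#' @export
refit_hrf <- function(fit, peak_delays = 4:8,
                      ratios = c(0, 1 / 6, 1 / 3)) {
  stopifnot(inherits(fit, "prf_fit"))
  apertures <- fit$apertures
  grid <- apertures$grid
  xv <- as.vector(grid$x); yv <- as.vector(grid$y)
  f <- fit$fits
  W <- vapply(seq_len(nrow(f)), function(v)
    exp(-((xv - f$x0[v])^2 + (yv - f$y0[v])^2) / (2 * f$sigma[v]^2)),
    numeric(length(xv)))
  drive <- crossprod(apertures$frames, W) # time x voxels, unconvolved
  nt <- nrow(drive)
  best <- NULL; best_rss <- Inf
  for (pd in peak_delays) for (ra in ratios) {
    h <- hrf_parameters(peak_delay = pd, ratio = ra, tr = fit$hrf$tr,
                        undershoot_delay = fit$hrf$undershoot_delay,
                        duration = fit$hrf$duration)
    D <- crossprod(conv_matrix(hrf_kernel(h), nt), drive)
    rss <- sum(vapply(seq_len(nrow(f)), function(v)
      .beta_fit(D[, v], fit$series[v, ])[1], 0))
    if (rss < best_rss) { best_rss <- rss; best <- h }
  }
  attr(best, "total_rss") <- best_rss
  best
}

#' @export
print.prf_fit <- function(x, ...) {
  f <- x$fits
  cat(sprintf("pRF fits for %d voxel(s) (%d frames)\n",
              nrow(f), ncol(x$series)))
  cat(sprintf("  variance explained: median %.3f (range %.3f-%.3f)\n",
              stats::median(f$variance_explained),
              min(f$variance_explained), max(f$variance_explained)))
  cat(sprintf("  eccentricity: median %.2f deg, sigma: median %.2f deg\n",
              stats::median(f$eccentricity), stats::median(f$sigma)))
  invisible(x)
}

#' @export
summary.prf_fit <- function(object, ve_min = 0.55, ...) {
  f <- object$fits
  out <- list(n_voxels = nrow(f),
              n_above_ve = sum(f$variance_explained > ve_min),
              ve_min = ve_min,
              quantiles = apply(
                f[, c("x0", "y0", "sigma", "eccentricity",
                      "variance_explained")],
                2L, stats::quantile,
                probs = c(0.05, 0.25, 0.5, 0.75, 0.95)))
  class(out) <- "summary.prf_fit"
  out
}

#' @export
print.summary.prf_fit <- function(x, ...) {
  cat(sprintf("pRF fit summary: %d voxels, %d with VE > %.2f\n",
              x$n_voxels, x$n_above_ve, x$ve_min))
  print(round(x$quantiles, 3))
  invisible(x)
}

#' @export
coef.prf_fit <- function(object, ...) {
  as.matrix(object$fits[, c("x0", "y0", "sigma", "beta")])
}

#' @export
fitted.prf_fit <- function(object, ...) {
  predict(object)
}

#' @export
predict.prf_fit <- function(object, apertures = object$apertures, ...) {
  f <- object$fits
  out <- matrix(0, nrow(f), ncol(apertures$frames))
  hrf <- object$hrf
  for (v in seq_len(nrow(f))) {
    p <- prf(f$x0[v], f$y0[v], f$sigma[v], f$beta[v])
    out[v, ] <- predict_bold_timeseries(p, apertures, hrf) + f$baseline[v]
  }
  out
}

#' @export
residuals.prf_fit <- function(object, ...) {
  object$series - fitted(object)
}

#' Visual-field coverage plot of fitted pRFs
#'
#' Draws each voxel's pRF center in the visual field, with symbol size
#' proportional to sigma and color mapped to variance explained.
#'
#' @param x A `prf_fit`.
#' @param ve_min Only plot voxels above this variance-explained threshold.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.prf_fit <- function(x, ve_min = 0, ...) {
  f <- x$fits[x$fits$variance_explained >= ve_min, ]
  R <- x$apertures$grid$radius_deg
  pal <- grDevices::hcl.colors(100, "viridis")
  cols <- pal[pmax(1, ceiling(f$variance_explained * 100))]
  graphics::plot(f$x0, f$y0, asp = 1, xlim = c(-R, R), ylim = c(-R, R),
                 pch = 19, col = cols, cex = 0.5 + f$sigma,
                 xlab = "x (deg)", ylab = "y (deg)", ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(R * cos(th), R * sin(th), lty = 2)
  invisible(x)
}
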
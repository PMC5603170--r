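#' Specification of a simulated retinotopic voxel population
#'
#' Describes the ground-truth pRF population the simulator samples: voxel
#' count, eccentricity range, a linear size-eccentricity rule
#' `sigma = slope * ecc + intercept` with Gaussian jitter (pRF sizes grow
#' with eccentricity and, in later areas, with steeper slopes), and a
#' log-normal amplitude distribution.
#'
#' @param n_voxels Number of voxels.
#' @param ecc_range Eccentricity range (degrees); positions are sampled
#'   uniformly over the corresponding annulus.
#' @param sigma_slope,sigma_intercept Linear size-eccentricity rule
#'   (degrees/degree, degrees).
#' @param sigma_jitter_sd SD of additive Gaussian jitter on sigma, degrees.
#' @param beta_meanlog,beta_sdlog Log-normal amplitude parameters.
#' @param roi Label for the simulated region of interest.
#' @export
population_spec <- function(n_voxels = 200, ecc_range = c(0.5, 4.5),
                            sigma_slope = 0.1, sigma_intercept = 0.3,
                            sigma_jitter_sd = 0.05,
                            beta_meanlog = 0, beta_sdlog = 0.2,
                            roi = "V1") {
  if (ecc_range[1] < 0 || ecc_range[2] <= ecc_range[1])
    stop("invalid eccentricity range")
  structure(list(n_voxels = n_voxels, ecc_range = ecc_range,
                 sigma_slope = sigma_slope,
                 sigma_intercept = sigma_intercept,
                 sigma_jitter_sd = sigma_jitter_sd,
                 beta_meanlog = beta_meanlog, beta_sdlog = beta_sdlog,
                 roi = roi),
            class = "population_spec")
}

#' Sample a ground-truth pRF population
#'
#' Positions are area-uniform over the annulus spanned by `ecc_range`,
#' sizes follow the linear eccentricity rule plus jitter (truncated to stay
#' positive), amplitudes are log-normal.
#'
#' @param spec A [population_spec()].
#' @param seed Optional RNG seed.
#' @return List of [prf()] objects.
#' @export
sample_prf_population <- function(spec = population_spec(), seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(seed, {
    n <- spec$n_voxels
    ecc <- sqrt(stats::runif(n, spec$ecc_range[1]^2, spec$ecc_range[2]^2))
    th <- stats::runif(n, 0, 2 * pi)
    sg <- pmax(spec$sigma_slope * ecc + spec$sigma_intercept +
                 stats::rnorm(n, 0, spec$sigma_jitter_sd), 0.05)
    beta <- stats::rlnorm(n, spec$beta_meanlog, spec$beta_sdlog)
    lapply(seq_len(n), function(v)
      prf(ecc[v] * cos(th[v]), ecc[v] * sin(th[v]), sg[v], beta[v]))
  })
}

#' Simulate a pRF mapping run
#'
#' Each voxel's series is its noiseless HRF-convolved overlap prediction
#' ([predict_bold_timeseries()]) plus independent Gaussian noise.
#'
#' @param prfs List of ground-truth [prf()] objects.
#' @param apertures The mapping `aperture_seq`.
#' @param hrf [hrf_parameters()].
#' @param noise_sd Noise standard deviation, BOLD units.
#' @param ar1_rho Lag-1 autocorrelation of the noise; 0 (default) gives
#'   independent Gaussian noise per frame.
#' @param seed Optional RNG seed.
#' @return Voxels x frames matrix.
#' @export
simulate_mapping_run <- function(prfs, apertures,
                                 hrf = hrf_parameters(
                                   tr = apertures$frame_duration_s),
                                 noise_sd = 0, ar1_rho = 0, seed = NULL) {
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  clean <- t(vapply(prfs, predict_bold_timeseries,
                    numeric(ncol(apertures$frames)),
                    apertures = apertures, hrf = hrf))
  with_seed(seed, clean + noise_matrix(nrow(clean), ncol(clean),
                                       noise_sd, ar1_rho))
}

# voxels x frames Gaussian noise, optionally AR(1) along time with the
# requested marginal SD
noise_matrix <- function(nv, nt, noise_sd, ar1_rho = 0) {
  e <- matrix(stats::rnorm(nv * nt, 0, noise_sd), nv, nt)
  if (ar1_rho == 0) return(e)
  if (abs(ar1_rho) >= 1) stop("'ar1_rho' must lie in (-1, 1)")
  e <- e * sqrt(1 - ar1_rho^2)
  e[, 1] <- e[, 1] / sqrt(1 - ar1_rho^2)
  for (t in 2:nt) e[, t] <- e[, t] + ar1_rho * e[, t - 1]
  e
}

#' Simulate an image-presentation session
#'
#' Generates the block-design identification experiment: each image is
#' presented in one block (default 9 s, followed by 12 s mean luminance);
#' every voxel's neural drive during a block is its pRF prediction for that
#' image (overlap for binary stimuli, contrast energy for natural images)
#' scaled by the voxel's amplitude. The drive is boxcar-expanded at the TR,
#' convolved with the HRF, and Gaussian noise is added.
#'
#' @param prfs List of ground-truth [prf()] objects.
#' @param images Named list of stimulus images (binary matrices or
#'   `natural_image` objects).
#' @param grid The shared [vf_grid()].
#' @param mode `"synthetic"` or `"natural"` prediction rule.
#' @param block_s,rest_s Block and rest durations, seconds.
#' @param lead_in_s Mean-luminance lead-in before the first block, seconds.
#' @param tr_s Repetition time, seconds.
#' @param hrf [hrf_parameters()].
#' @param noise_sd Noise SD, BOLD units.
#' @param ar1_rho Lag-1 noise autocorrelation (0 = white noise).
#' @param seed Optional RNG seed.
#' @return A `sim_session`: list with `bold` (voxels x frames), `events`,
#'   `true_profiles` (the generating images x voxels predictions), `prfs`,
#'   `image_ids`, `tr_s`, `noise_sd`, `seed`, `mode`, `grid`.
#' @export
simulate_image_session <- function(prfs, images, grid,
                                   mode = c("synthetic", "natural"),
                                   block_s = 9, rest_s = 12, lead_in_s = 12,
                                   tr_s = 1.5,
                                   hrf = hrf_parameters(tr = tr_s),
                                   noise_sd = 0, ar1_rho = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  n_img <- length(images)
  if (is.null(names(images))) names(images) <- paste0("img", seq_len(n_img))
  events <- data.frame(
    image_id = names(images),
    onset_s = lead_in_s + (seq_len(n_img) - 1) * (block_s + rest_s),
    duration_s = block_s)
  total_s <- lead_in_s + n_img * (block_s + rest_s)
  nt <- ceiling(total_s / tr_s)
  profiles <- build_predicted_profiles(prfs, images, grid, mode = mode)
  amp <- sweep(as.matrix(profiles), 2L,
               vapply(prfs, function(p) p$beta, 0), "*")
  design <- build_block_design(events, nt, tr_s, hrf)
  X <- convolve_hrf(attr(design, "boxcars"), hrf_kernel(hrf))
  clean <- t(X %*% amp)                     # voxels x frames
  bold <- with_seed(seed,
    clean + noise_matrix(nrow(clean), ncol(clean), noise_sd, ar1_rho))
  structure(list(bold = bold, events = events,
                 true_profiles = profiles, prfs = prfs,
                 image_ids = names(images), tr_s = tr_s,
                 noise_sd = noise_sd, seed = seed, mode = mode,
                 grid = grid, hrf = hrf, n_frames = nt),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf(
    "Simulated %s-image session: %d voxels x %d frames, %d images, noise SD %.3g\n",
    x$mode, nrow(x$bold), ncol(x$bold), length(x$image_ids), x$noise_sd))
  invisible(x)
}
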
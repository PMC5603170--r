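#' Block-design GLM design matrix
#'
#' Builds one HRF-convolved boxcar regressor per image from an event table,
#' plus an intercept. Each boxcar is 1 on the frames whose acquisition time
#' falls inside a presentation block of that image and 0 elsewhere, sampled
#' at the TR and convolved with the HRF kernel.
#'
#' @param events Data frame with columns `image_id`, `onset_s`,
#'   `duration_s`.
#' @param n_frames Number of retained time frames in the scan.
#' @param tr_s Repetition time, seconds.
#' @param hrf [hrf_parameters()] used for the convolution (its `tr` should
#'   equal `tr_s`).
#' @return A `design_matrix`: numeric matrix (`n_frames` x regressors) whose
#'   last column is the intercept; attributes `image_ids`, `tr_s` and
#'   `boxcars` (the pre-convolution regressors).
#' @export
build_block_design <- function(events, n_frames, tr_s = 1.5,
                               hrf = hrf_parameters(tr = tr_s)) {
  if (tr_s <= 0) stop("'tr_s' must be positive")
  events <- as.data.frame(events)
  needed <- c("image_id", "onset_s", "duration_s")
  if (!all(needed %in% names(events)))
    stop("events must have columns image_id, onset_s, duration_s")
  scan_end <- n_frames * tr_s
  if (nrow(events) > 0 && any(events$onset_s >= scan_end))
    stop("event onset beyond the end of the scan")
  ids <- unique(as.character(events$image_id))
  frame_t <- (seq_len(n_frames) - 1) * tr_s
  box <- matrix(0, n_frames, length(ids),
                dimnames = list(NULL, ids))
  for (id in ids) {
    ev <- events[as.character(events$image_id) == id, , drop = FALSE]
    o <- order(ev$onset_s)
    if (nrow(ev) > 1 &&
        any(ev$onset_s[o][-1] < (ev$onset_s + ev$duration_s)[o][-nrow(ev)]))
      stop("overlapping blocks for image ", id)
    for (b in seq_len(nrow(ev)))
      box[frame_t >= ev$onset_s[b] &
            frame_t < ev$onset_s[b] + ev$duration_s[b], id] <- 1
  }
  X <- if (length(ids)) convolve_hrf(box, hrf_kernel(hrf)) else
    matrix(0, n_frames, 0)
  X <- cbind(X, intercept = 1)
  colnames(X) <- c(ids, "intercept")
  structure(X, image_ids = ids, tr_s = tr_s, boxcars = box,
            class = c("design_matrix", "matrix"))
}

#' Ordinary least squares GLM per voxel
#'
#' Fits the block design to every voxel's time series by OLS, with
#' homoscedastic per-voxel residual variance, and summarizes each voxel's
#' response to each image by the t-value of its regressor
#' (`t = beta / SE(beta)`). When a voxel's residual variance is numerically
#' zero (noise-free simulations) it is floored at machine epsilon so t-values
#' stay finite; this preserves the profile up to a positive scale.
#'
#' @param ts_matrix Voxels x frames matrix of BOLD series.
#' @param design A `design_matrix` from [build_block_design()].
#' @param ar1 Apply one Cochrane-Orcutt AR(1) prewhitening pass: the lag-1
#'   autocorrelation of the pooled OLS residuals is estimated, data and
#'   design are quasi-differenced, and the model is refit. Off by default
#'   (plain OLS with homoscedastic per-voxel variance).
#' @return A `prf_glm`: list with `beta`, `se`, `t` (voxels x images
#'   matrices), `dof`, and `image_ids`.
#' @export
fit_glm <- function(ts_matrix, design, ar1 = FALSE) {
  stopifnot(inherits(design, "design_matrix"))
  if (is.null(dim(ts_matrix))) ts_matrix <- matrix(ts_matrix, nrow = 1L)
  X <- unclass(design); attributes(X)[c("image_ids", "tr_s", "boxcars")] <- NULL
  nt <- nrow(X); p <- ncol(X)
  if (ncol(ts_matrix) != nt)
    stop("frame counts of data (", ncol(ts_matrix),
         ") and design (", nt, ") differ")
  if (nt <= p) stop("fewer frames than regressors (plus one)")
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  if (ar1) {
    XtXinv0 <- chol2inv(chol(crossprod(X)))
    B0 <- ts_matrix %*% X %*% XtXinv0
    R0 <- ts_matrix - B0 %*% t(X)
    rho <- sum(R0[, -1, drop = FALSE] * R0[, -nt, drop = FALSE]) /
      sum(R0[, -nt, drop = FALSE]^2)
    ts_matrix <- ts_matrix[, -1, drop = FALSE] -
      rho * ts_matrix[, -nt, drop = FALSE]
    X <- X[-1, , drop = FALSE] - rho * X[-nt, , drop = FALSE]
    nt <- nt - 1L
  }
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- ts_matrix %*% X %*% XtXinv            # voxels x regressors
  R <- ts_matrix - B %*% t(X)
  dof <- nt - p
  sigma2 <- pmax(rowSums(R^2) / dof, .Machine$double.eps)
  ids <- attr(design, "image_ids")
  j <- match(ids, colnames(X))
  se <- sqrt(outer(sigma2, diag(XtXinv)[j]))
  beta <- B[, j, drop = FALSE]
  colnames(beta) <- colnames(se) <- ids
  structure(list(beta = beta, se = se, t = beta / se, dof = dof,
                 image_ids = ids),
            class = "prf_glm")
}

#' @export
print.prf_glm <- function(x, ...) {
  cat(sprintf("GLM fit: %d voxel(s) x %d image regressor(s), %d dof\n",
              nrow(x$beta), ncol(x$beta), x$dof))
  invisible(x)
}

#' @export
coef.prf_glm <- function(object, ...) object$beta

#' Measured response profiles from a GLM fit
#'
#' @param glm A `prf_glm`.
#' @param measure `"t"` (default, the paper's profile statistic) or
#'   `"beta"`.
#' @param voxel_ids Optional voxel identifiers.
#' @return A `profile_matrix` (images x voxels).
#' @export
measured_profiles <- function(glm, measure = c("t", "beta"),
                              voxel_ids = NULL) {
  measure <- match.arg(measure)
  m <- t(glm[[measure]])
  rownames(m) <- glm$image_ids
  if (!is.null(voxel_ids)) colnames(m) <- voxel_ids else
    colnames(m) <- paste0("v", seq_len(ncol(m)))
  profile_matrix(m, mode = paste0("measured_", measure))
}

#' Voxel-selection filters for image identification
#'
#' Applies the three inclusion filters to the fitted voxels: positive
#' t-values, pRF eccentricity within a band (default 0.5-4.5 deg), and pRF
#' variance explained above a threshold (default 55%). The t-value rule is
#' configurable because a per-voxel summary is needed: `"localizer"` keeps
#' voxels with a positive t for a designated full-field localizer regressor,
#' `"any_image"` keeps voxels with a positive t for at least one image,
#' `"all_images"` requires all t-values positive, `"none"` disables the t
#' filter.
#'
#' @param fit A `prf_fit` (per-voxel pRF parameters and variance explained).
#' @param glm Optional `prf_glm` supplying t-values.
#' @param ve_min Variance-explained threshold (exclusive).
#' @param ecc_range Inclusive eccentricity bounds, degrees.
#' @param t_rule One of `"localizer"`, `"any_image"`, `"all_images"`,
#'   `"none"`.
#' @param localizer Image id of the full-field localizer regressor (for
#'   `t_rule = "localizer"`).
#' @return A `voxel_selection`: list with `voxels` (integer indices of
#'   retained voxels) and `criteria`.
#' @export
select_voxels <- function(fit, glm = NULL, ve_min = 0.55,
                          ecc_range = c(0.5, 4.5),
                          t_rule = c("any_image", "localizer",
                                     "all_images", "none"),
                          localizer = NULL) {
  stopifnot(inherits(fit, "prf_fit"))
  t_rule <- match.arg(t_rule)
  f <- fit$fits
  keep <- f$variance_explained > ve_min &
    f$eccentricity >= ecc_range[1] & f$eccentricity <= ecc_range[2]
  if (t_rule != "none") {
    if (is.null(glm)) stop("a GLM fit is required for the t-value filter")
    if (nrow(glm$t) != nrow(f))
      stop("GLM and pRF fits cover different voxel sets")
    tkeep <- switch(t_rule,
      any_image = apply(glm$t > 0, 1L, any),
      all_images = apply(glm$t > 0, 1L, all),
      localizer = {
        if (is.null(localizer) || !localizer %in% colnames(glm$t))
          stop("t_rule = 'localizer' needs a localizer image id present in the GLM")
        glm$t[, localizer] > 0
      })
    keep <- keep & tkeep
  }
  if (!any(keep))
    stop(sprintf(
      "no voxels pass the selection filters (VE > %.2f, ecc %.2g-%.2g, t rule '%s')",
      ve_min, ecc_range[1], ecc_range[2], t_rule))
  structure(list(voxels = which(keep),
                 criteria = list(ve_min = ve_min, ecc_range = ecc_range,
                                 t_rule = t_rule, localizer = localizer)),
            class = "voxel_selection")
}

#' @export
print.voxel_selection <- function(x, ...) {
  cat(sprintf(
    "Voxel selection: %d voxel(s) (VE > %.2f, ecc %.2g-%.2g deg, t rule '%s')\n",
    length(x$voxels), x$criteria$ve_min, x$criteria$ecc_range[1],
    x$criteria$ecc_range[2], x$criteria$t_rule))
  invisible(x)
}
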
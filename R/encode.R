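#' Predicted response to a binary synthetic stimulus (pRF overlap)
#'
#' The predicted response of a voxel to a binary stimulus is the pRF-weighted
#' sum of on-pixels, normalized by the total pRF volume over the stimulus
#' area:
#' \deqn{\hat{r} = \frac{\sum_{i} w_i S_i}{\sum_{i} w_i}}
#' where `S_i` is 1 where stimulus energy is present and 0 at mean luminance,
#' and `w_i` are the Gaussian pRF weights. By default both sums run over the
#' full circular stimulus area, so the output lies in [0, 1] and a full-field
#' stimulus maps to exactly 1. A truncated spatial window (pixels within
#' `window_sigma * sigma` of the pRF center, numerator only) reproduces the
#' alternative reading in which the numerator window is narrower than the
#' normalization area.
#'
#' @param prf A [prf()].
#' @param stimulus Binary matrix on the grid (values in \{0, 1\}).
#' @param grid The [vf_grid()] both live on.
#' @param window_sigma Optional truncation radius for the numerator window,
#'   in multiples of sigma; `NULL` (default) uses the full stimulus area.
#' @param radius_deg Radius of the stimulus area; defaults to the grid's.
#' @return Scalar predicted response.
#' @export
predict_synthetic_response <- function(prf, stimulus, grid,
                                       window_sigma = NULL,
                                       radius_deg = grid$radius_deg) {
  stopifnot(inherits(prf, "prf"), inherits(grid, "vf_grid"))
  if (!all(stimulus %in% c(0, 1))) stop("stimulus must be binary")
  w <- gaussian_weights(prf, grid)
  area <- stimulus_area(grid, radius_deg)
  win <- area
  if (!is.null(window_sigma)) {
    win <- area & ((grid$x - prf$x0)^2 + (grid$y - prf$y0)^2 <=
                     (window_sigma * prf$sigma)^2)
  }
  sum(w[win] * stimulus[win]) / sum(w[area])
}

#' Predicted response to a natural image (pRF-weighted contrast energy)
#'
#' Natural images cannot be binarized, so the predicted response is the
#' pRF-weighted local contrast energy:
#' \deqn{\hat{r} = \frac{1}{\sum_i w_i}\sum_i w_i
#'   \frac{(L_i - \bar{L})^2}{\bar{L}^2}}
#' the pRF-weighted mean of squared luminance deviations from the mean
#' luminance, relative to that mean (the squared RMS contrast, weighted by
#' the pRF). `Lbar` is by default the unweighted mean luminance over the
#' spatial window; `weighted_mean = TRUE` uses the pRF-weighted mean
#' instead.
#'
#' @param prf A [prf()].
#' @param image A `natural_image` (or a plain luminance matrix).
#' @param grid The shared [vf_grid()].
#' @param window_sigma Optional truncation radius for the spatial window
#'   (multiples of sigma); `NULL` uses the full stimulus area.
#' @param weighted_mean Use the pRF-weighted mean luminance as `Lbar`.
#' @param radius_deg Radius of the stimulus area.
#' @return Scalar contrast-energy prediction (nonnegative).
#' @export
predict_natural_response <- function(prf, image, grid,
                                     window_sigma = NULL,
                                     weighted_mean = FALSE,
                                     radius_deg = grid$radius_deg) {
  stopifnot(inherits(prf, "prf"), inherits(grid, "vf_grid"))
  L <- if (inherits(image, "natural_image")) image$luminance else
    as.matrix(image)
  w <- gaussian_weights(prf, grid)
  win <- stimulus_area(grid, radius_deg)
  if (!is.null(window_sigma)) {
    win <- win & ((grid$x - prf$x0)^2 + (grid$y - prf$y0)^2 <=
                    (window_sigma * prf$sigma)^2)
  }
  Lw <- L[win]; ww <- w[win]
  Lbar <- if (weighted_mean) sum(ww * Lw) / sum(ww) else mean(Lw)
  if (Lbar == 0) stop("zero mean luminance in the spatial window")
  sum(ww * (Lw - Lbar)^2) / (Lbar^2 * sum(ww))
}

#' Predicted response profiles for a candidate image set
#'
#' Evaluates the per-voxel prediction ([predict_synthetic_response()] or
#' [predict_natural_response()]) for every pRF and candidate image,
#' assembling the images x voxels profile matrix the identification step
#' consumes. Predictions are not convolved with the HRF: that would only
#' rescale whole profiles, leaving the relative amplitudes intact.
#'
#' @param prfs List of [prf()] objects (or a `prf_fit`, whose rows are
#'   converted).
#' @param images List of candidate images: binary matrices in `"synthetic"`
#'   mode, `natural_image` objects (or luminance matrices) in `"natural"`
#'   mode.
#' @param grid The shared [vf_grid()].
#' @param mode `"synthetic"` (overlap) or `"natural"` (contrast energy).
#' @param image_ids,voxel_ids Optional identifier vectors; defaults are
#'   names or indices.
#' @param ... Passed to the per-voxel prediction function.
#' @return A `profile_matrix`: numeric matrix (images x voxels) with
#'   identifier dimnames and a `mode` attribute.
#' @export
build_predicted_profiles <- function(prfs, images, grid,
                                     mode = c("synthetic", "natural"),
                                     image_ids = NULL, voxel_ids = NULL,
                                     ...) {
  mode <- match.arg(mode)
  if (inherits(prfs, "prf_fit")) prfs <- as_prf_list(prfs)
  if (inherits(prfs, "prf")) prfs <- list(prfs)
  if (length(prfs) == 0L) stop("empty voxel list")
  if (length(images) == 0L) stop("empty image list")
  if (is.null(image_ids))
    image_ids <- if (!is.null(names(images))) names(images) else
      paste0("img", seq_along(images))
  if (is.null(voxel_ids)) voxel_ids <- paste0("v", seq_along(prfs))
  extra <- list(...)
  if (length(extra) == 0L) {
    # default full-area window: both prediction rules are pRF-weighted
    # averages, so the whole profile matrix is one matrix product
    inside <- as.vector(stimulus_area(grid))
    W <- vapply(prfs, function(p)
      as.vector(gaussian_weights(p, grid))[inside],
      numeric(sum(inside)))                       # pixels x voxels
    Q <- vapply(images, function(img) {
      if (mode == "synthetic") {
        stim <- as.matrix(img)
        if (!all(stim %in% c(0, 1))) stop("stimulus must be binary")
        as.vector(stim)[inside]
      } else {
        L <- if (inherits(img, "natural_image")) img$luminance else
          as.matrix(img)
        Lv <- as.vector(L)[inside]
        Lbar <- mean(Lv)
        if (Lbar == 0) stop("zero mean luminance in the spatial window")
        (Lv - Lbar)^2 / Lbar^2
      }
    }, numeric(sum(inside)))                      # pixels x images
    m <- t(crossprod(W, Q) / colSums(W))          # images x voxels
    dimnames(m) <- list(image_ids, voxel_ids)
    return(profile_matrix(m, mode = mode))
  }
  fun <- switch(mode, synthetic = predict_synthetic_response,
                natural = predict_natural_response)
  m <- matrix(0, length(images), length(prfs),
              dimnames = list(image_ids, voxel_ids))
  for (i in seq_along(images))
    for (v in seq_along(prfs))
      m[i, v] <- do.call(fun, c(list(prfs[[v]], images[[i]], grid), extra))
  profile_matrix(m, mode = mode)
}

#' @rdname build_predicted_profiles
#' @param values Images x voxels numeric matrix.
#' @param mode Label recording how the profiles were obtained.
#' @export
profile_matrix <- function(values, mode = "measured") {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("profiles must be finite")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("img", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("v", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values)))
    stop("voxel identifiers must be unique")
  structure(values, mode = mode, class = c("profile_matrix", "matrix"))
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("Response profiles (%s): %d image(s) x %d voxel(s)\n",
              attr(x, "mode"), nrow(x), ncol(x)))
  invisible(x)
}

# one prf object per row of a prf_fit
as_prf_list <- function(fit) {
  f <- fit$fits
  lapply(seq_len(nrow(f)),
         function(v) prf(f$x0[v], f$y0[v], f$sigma[v], f$beta[v]))
}
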
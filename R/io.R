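#' Read BOLD data as a voxels x frames matrix
#'
#' Accepts either an in-memory array or the path of a 4-D NIfTI volume
#' (read with the RNifti package, if installed). A logical/numeric ROI
#' volume restricts the voxels; for arrays the first three dimensions are
#' space and the fourth is time.
#'
#' @param x Matrix (voxels x frames), 4-D array, or NIfTI file path.
#' @param roi Optional 3-D mask (array or NIfTI path); nonzero voxels are
#'   kept.
#' @param discard_frames Number of initial frames to drop (start-up
#'   transients).
#' @return Voxels x frames numeric matrix.
#' @export
read_bold_matrix <- function(x, roi = NULL, discard_frames = 0) {
  load_vol <- function(v) {
    if (is.character(v)) {
      if (!requireNamespace("RNifti", quietly = TRUE))
        stop("reading NIfTI files requires the RNifti package")
      v <- RNifti::readNifti(v)
    }
    unclass(v)
  }
  x <- load_vol(x)
  if (length(dim(x)) == 4L) {
    d <- dim(x)
    x <- matrix(x, prod(d[1:3]), d[4])
    if (!is.null(roi)) {
      m <- load_vol(roi)
      x <- x[as.vector(m) != 0, , drop = FALSE]
    }
  } else {
    x <- as.matrix(x)
  }
  if (discard_frames > 0) x <- x[, -seq_len(discard_frames), drop = FALSE]
  x
}

#' Write / read response-profile matrices as CSV
#'
#' Profiles are stored images x voxels with image identifiers in the first
#' column and voxel identifiers as the header.
#'
#' @param profiles A `profile_matrix`.
#' @param path CSV file path.
#' @export
write_profiles_csv <- function(profiles, path) {
  df <- data.frame(image_id = rownames(profiles),
                   as.data.frame(unclass(profiles)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @param mode Mode label to attach on reading.
#' @export
read_profiles_csv <- function(path, mode = "measured") {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  profile_matrix(m, mode = mode)
}

#' Write per-voxel pRF fits as CSV
#'
#' One row per voxel: position, size, amplitude, variance explained, polar
#' angle and eccentricity.
#'
#' @param fit A `prf_fit`.
#' @param path CSV file path.
#' @export
write_prf_fits_csv <- function(fit, path) {
  utils::write.csv(fit$fits, path, row.names = FALSE)
  invisible(path)
}
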
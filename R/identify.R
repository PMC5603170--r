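#' Correlation matrix between measured and predicted profiles
#'
#' Entry (i, j) is the Pearson correlation between the measured response
#' profile of presented image i and the predicted response profile of
#' candidate image j, computed across the shared, identically ordered voxel
#' set.
#'
#' @param measured,predicted `profile_matrix` objects (images x voxels) with
#'   matching voxel columns.
#' @return A `cor_matrix`: measured images x candidate images matrix of
#'   Pearson r.
#' @export
correlation_matrix <- function(measured, predicted) {
  measured <- as.matrix(measured); predicted <- as.matrix(predicted)
  if (ncol(measured) != ncol(predicted) ||
      !identical(colnames(measured), colnames(predicted)))
    stop("measured and predicted profiles must share one ordered voxel set")
  sdm <- apply(measured, 1L, stats::sd)
  sdp <- apply(predicted, 1L, stats::sd)
  if (any(sdm == 0))
    stop("constant measured profile for image(s): ",
         paste(rownames(measured)[sdm == 0], collapse = ", "))
  if (any(sdp == 0))
    stop("constant predicted profile for image(s): ",
         paste(rownames(predicted)[sdp == 0], collapse = ", "))
  r <- stats::cor(t(measured), t(predicted))
  structure(r, class = c("cor_matrix", "matrix"))
}

#' Identify presented images from a correlation matrix
#'
#' For each presented image (row), the identified candidate is the one with
#' the highest Pearson correlation. Ties are broken toward the lowest
#' candidate index, with a warning. Accuracy is the percentage of rows whose
#' chosen candidate is the true image.
#'
#' @param corr A `cor_matrix`.
#' @param true_ids Candidate id of the true image for each row; defaults to
#'   the row names (presented images identified by their own label).
#' @return An `ident_result`: data frame per presented image (chosen id,
#'   rank of the true image, correct flag) plus `accuracy` (%) as an
#'   attribute-like list element.
#' @export
identify_images <- function(corr, true_ids = rownames(corr)) {
  corr <- as.matrix(corr)
  if (is.null(true_ids)) stop("true image ids are required")
  if (!all(true_ids %in% colnames(corr)))
    stop("true image(s) absent from the candidate set: ",
         paste(setdiff(true_ids, colnames(corr)), collapse = ", "))
  n <- nrow(corr)
  chosen <- character(n); rank_true <- integer(n)
  tie_seen <- FALSE
  for (i in seq_len(n)) {
    row <- corr[i, ]
    top <- which(row == max(row))
    if (length(top) > 1L) tie_seen <- TRUE
    chosen[i] <- colnames(corr)[top[1L]]
    r_true <- row[true_ids[i]]
    rank_true[i] <- 1L + sum(row > r_true)
  }
  if (tie_seen)
    warning("ties in the correlation argmax; lowest candidate index chosen")
  per_image <- data.frame(
    presented = if (!is.null(rownames(corr))) rownames(corr) else
      as.character(seq_len(n)),
    chosen = chosen, true = true_ids, rank = rank_true,
    correct = chosen == true_ids, row.names = NULL)
  structure(list(per_image = per_image,
                 accuracy = 100 * mean(per_image$correct),
                 n_candidates = ncol(corr)),
            class = "ident_result")
}

#' @export
print.ident_result <- function(x, ...) {
  cat(sprintf(
    "Image identification: %d/%d correct (accuracy %.1f%%) among %d candidates\n",
    sum(x$per_image$correct), nrow(x$per_image), x$accuracy,
    x$n_candidates))
  invisible(x)
}

#' Identification accuracy versus candidate-set size
#'
#' Bootstraps identification accuracy as the candidate set grows: for each
#' set size k, `n_boot` candidate sets are formed by keeping each presented
#' image's own prediction and sampling k - 1 distractors (without
#' replacement) from the candidate pool; accuracy is averaged over draws and
#' summarized with a percentile 95% confidence interval. When k equals the
#' pool size there is exactly one possible set, so the interval has zero
#' width. With `shuffle = TRUE` the "true" candidate of every presented
#' image is re-drawn uniformly from its sampled set on each draw, which
#' measures the empirical chance level (expected accuracy 100/k).
#'
#' @param measured Measured `profile_matrix` (presented images x voxels).
#' @param pool Predicted `profile_matrix` for the candidate pool; must
#'   contain a prediction for every presented image (matched by row name).
#' @param sizes Candidate-set sizes to evaluate.
#' @param n_boot Bootstrap draws per size.
#' @param seed RNG seed.
#' @param shuffle Replace the true labels by random ones (chance
#'   calibration).
#' @return A `set_size_curve`: data frame with columns `size`, `accuracy`
#'   (mean %), `ci_lo`, `ci_hi`, `chance` (= 100/size), `n_boot`; the seed
#'   is kept as an attribute.
#' @export
set_size_curve <- function(measured, pool, sizes, n_boot = 1000,
                           seed = NULL, shuffle = FALSE) {
  measured <- as.matrix(measured); pool <- as.matrix(pool)
  if (n_boot < 1) stop("'n_boot' must be at least 1")
  if (any(sizes < 2) || any(sizes > nrow(pool)))
    stop("sizes must lie between 2 and the pool size")
  if (!all(rownames(measured) %in% rownames(pool)))
    stop("the pool must contain a prediction for every presented image")
  corr <- stats::cor(t(measured), t(pool)) # presented x pool
  self_j <- match(rownames(measured), rownames(pool))
  n_pres <- nrow(measured); n_pool <- ncol(corr)
  res <- with_seed(seed, {
    out <- vector("list", length(sizes))
    for (si in seq_along(sizes)) {
      k <- sizes[si]
      exhaustive <- (k == n_pool) && !shuffle
      nb <- if (exhaustive) 1L else n_boot
      acc <- numeric(nb)
      for (b in seq_len(nb)) {
        correct <- logical(n_pres)
        for (i in seq_len(n_pres)) {
          if (exhaustive) {
            set_j <- seq_len(n_pool)
            true_j <- self_j[i]
          } else if (shuffle) {
            set_j <- sample(n_pool, k)
            true_j <- set_j[sample.int(k, 1L)]
          } else {
            set_j <- c(self_j[i],
                       sample(setdiff(seq_len(n_pool), self_j[i]), k - 1L))
            true_j <- self_j[i]
          }
          correct[i] <- set_j[which.max(corr[i, set_j])] == true_j
        }
        acc[b] <- 100 * mean(correct)
      }
      ci <- stats::quantile(acc, c(0.025, 0.975), names = FALSE)
      out[[si]] <- data.frame(size = k, accuracy = mean(acc),
                              ci_lo = ci[1], ci_hi = ci[2],
                              chance = 100 / k, n_boot = nb)
    }
    do.call(rbind, out)
  })
  structure(res, seed = seed, shuffle = shuffle,
            class = c("set_size_curve", "data.frame"))
}

#' Plot an identification set-size curve
#'
#' @param x A `set_size_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.set_size_curve <- function(x, ...) {
  graphics::plot(x$size, x$accuracy, type = "b", log = "x", ylim = c(0, 100),
                 xlab = "candidate set size",
                 ylab = "identification accuracy (%)", pch = 19, ...)
  graphics::arrows(x$size, x$ci_lo, x$size, x$ci_hi, angle = 90, code = 3,
                   length = 0.03)
  graphics::lines(x$size, x$chance, lty = 2)
  invisible(x)
}

#' Per-image identification confidence scores
#'
#' Quantifies how distinguishable each presented image is: the correlation
#' of its measured profile with its own prediction, minus the mean
#' correlation with all candidate predictions,
#' \deqn{c_i = -\frac{1}{N}\sum_{j=1}^{N}
#'   \left[r(i_m, j_p) - r(i_m, i_p)\right]
#'   = r(i_m, i_p) - \frac{1}{N}\sum_j r(i_m, j_p).}
#' The sum includes j = i (that term is zero), so N is the full candidate
#' count. Higher scores mean the image is easier to tell apart.
#'
#' @param corr A square `cor_matrix` whose candidate columns cover all
#'   presented rows (matched by identifier).
#' @return Named numeric vector of confidence scores.
#' @export
confidence_scores <- function(corr) {
  corr <- as.matrix(corr)
  if (!all(rownames(corr) %in% colnames(corr)))
    stop("every presented image needs a matching candidate prediction")
  self <- corr[cbind(seq_len(nrow(corr)), match(rownames(corr),
                                                colnames(corr)))]
  stats::setNames(self - rowMeans(corr), rownames(corr))
}
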
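test_that("boxcar regressors follow the block timing", {
  hrf <- test_hrf()
  ev <- data.frame(image_id = c("a", "b"),
                   onset_s = c(0, 21), duration_s = c(9, 9))
  des <- build_block_design(ev, n_frames = 30, tr_s = 1.5, hrf = hrf)
  box <- attr(des, "boxcars")
  # a 9 s block at TR 1.5 spans 6 frames
  expect_equal(sum(box[, "a"]), 6)
  expect_equal(which(box[, "a"] == 1), 1:6)
  # a 12 s rest between blocks leaves 8 zero frames
  expect_equal(which(box[, "b"] == 1), 15:20)
  expect_equal(sum(box[7:14, ]), 0)
  # intercept column is constant, convolved support starts at the block
  expect_true(all(des[, "intercept"] == 1))
  expect_true(all(des[1:14, "b"] == 0))
})

test_that("design construction validates events", {
  ev <- data.frame(image_id = "a", onset_s = 100, duration_s = 9)
  expect_error(build_block_design(ev, n_frames = 20, tr_s = 1.5), "beyond")
  ev2 <- data.frame(image_id = c("a", "a"), onset_s = c(0, 5),
                    duration_s = c(9, 9))
  expect_error(build_block_design(ev2, n_frames = 30, tr_s = 1.5),
               "overlapping")
  des <- build_block_design(data.frame(image_id = character(0),
                                       onset_s = numeric(0),
                                       duration_s = numeric(0)),
                            n_frames = 10, tr_s = 1.5)
  expect_equal(colnames(des), "intercept")
})

test_that("noiseless GLM recovers the generating betas exactly", {
  hrf <- test_hrf()
  ev <- data.frame(image_id = paste0("im", 1:3),
                   onset_s = c(6, 27, 48), duration_s = 9)
  des <- build_block_design(ev, n_frames = 45, tr_s = 1.5, hrf = hrf)
  true_b <- rbind(c(2, 0.5, 1.2), c(-1, 3, 0))
  X <- unclass(des)
  y <- true_b %*% t(X[, 1:3]) + 4 # constant baseline
  glm <- fit_glm(y, des)
  expect_equal(unname(coef(glm)), unname(true_b), tolerance = 1e-10)
  expect_equal(glm$dof, 45 - 4)
})

test_that("toy GLM matches the normal-equations oracle", {
  hrf <- test_hrf()
  ev <- data.frame(image_id = "a", onset_s = 0, duration_s = 3)
  des <- build_block_design(ev, n_frames = 8, tr_s = 1.5, hrf = hrf)
  set.seed(99)
  y <- rnorm(8)
  glm <- fit_glm(y, des)
  X <- cbind(unclass(des)[, "a"], 1)
  bh <- solve(t(X) %*% X) %*% t(X) %*% y
  res <- y - X %*% bh
  s2 <- sum(res^2) / (8 - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[1, 1])
  expect_equal(unname(glm$beta[1, 1]), bh[1, 1], tolerance = 1e-12)
  expect_equal(unname(glm$se[1, 1]), se, tolerance = 1e-12)
  expect_equal(unname(glm$t[1, 1]), bh[1, 1] / se, tolerance = 1e-12)
})

test_that("null data yield t-values centered on zero", {
  hrf <- test_hrf()
  ev <- data.frame(image_id = paste0("im", 1:2),
                   onset_s = c(6, 45), duration_s = 9)
  des <- build_block_design(ev, n_frames = 60, tr_s = 1.5, hrf = hrf)
  set.seed(123)
  y <- matrix(rnorm(500 * 60), 500, 60)
  glm <- fit_glm(y, des)
  expect_lt(abs(mean(glm$t)), 0.1)
})

test_that("t-values are invariant to positive rescaling of the data", {
  hrf <- test_hrf()
  ev <- data.frame(image_id = "a", onset_s = 3, duration_s = 9)
  des <- build_block_design(ev, n_frames = 20, tr_s = 1.5, hrf = hrf)
  set.seed(7)
  y <- rnorm(20) + 2 * unclass(des)[, "a"]
  expect_equal(fit_glm(y, des)$t, fit_glm(10 * y, des)$t,
               tolerance = 1e-10)
})

test_that("GLM rejects mismatched or deficient inputs", {
  des <- build_block_design(
    data.frame(image_id = "a", onset_s = 0, duration_s = 9),
    n_frames = 20, tr_s = 1.5)
  expect_error(fit_glm(rnorm(10), des), "frame counts")
  dup <- build_block_design(
    data.frame(image_id = "a", onset_s = 0, duration_s = 9),
    n_frames = 20, tr_s = 1.5)
  dupX <- cbind(unclass(dup)[, 1], unclass(dup))
  attr(dupX, "image_ids") <- c("a0", attr(dup, "image_ids"))
  attr(dupX, "tr_s") <- 1.5; attr(dupX, "boxcars") <- NULL
  class(dupX) <- c("design_matrix", "matrix")
  expect_error(fit_glm(rnorm(20), dupX), "rank deficient")
})

fake_fit <- function(ve, ecc) {
  ang <- seq_along(ve) * 0.3
  structure(list(fits = data.frame(
    voxel = seq_along(ve), x0 = ecc * cos(ang), y0 = ecc * sin(ang),
    sigma = 1, beta = 1, baseline = 0, rss = 0,
    variance_explained = ve, polar_angle = ang, eccentricity = ecc)),
    class = "prf_fit")
}

fake_glm <- function(tvals) {
  structure(list(beta = tvals, se = tvals * 0 + 1, t = tvals,
                 dof = 10, image_ids = colnames(tvals)),
            class = "prf_glm")
}

test_that("voxel filters apply the standard thresholds", {
  fit <- fake_fit(ve = c(0.54, 0.56, 0.80, 0.90),
                  ecc = c(2.0, 2.0, 5.0, 0.2))
  tv <- matrix(1, 4, 2, dimnames = list(NULL, c("im1", "im2")))
  glm <- fake_glm(tv)
  sel <- select_voxels(fit, glm)
  # VE 0.54 excluded, VE 0.56 at ecc 2 kept, ecc 5.0 and 0.2 excluded
  expect_equal(sel$voxels, 2L)
  glm$t[2, ] <- -1
  expect_error(select_voxels(fit, glm, t_rule = "any_image"), "no voxels")
})

test_that("an all-passing set survives selection intact", {
  fit <- fake_fit(ve = rep(0.9, 10), ecc = rep(2, 10))
  glm <- fake_glm(matrix(1, 10, 1, dimnames = list(NULL, "im1")))
  expect_length(select_voxels(fit, glm)$voxels, 10L)
})

test_that("tightening any threshold never adds voxels", {
  set.seed(11)
  fit <- fake_fit(ve = runif(50), ecc = runif(50, 0, 6))
  tv <- matrix(rnorm(50 * 3), 50, 3,
               dimnames = list(NULL, paste0("im", 1:3)))
  glm <- fake_glm(tv)
  base <- select_voxels(fit, glm, ve_min = 0.3, ecc_range = c(0.5, 5))
  tighter_ve <- select_voxels(fit, glm, ve_min = 0.6,
                              ecc_range = c(0.5, 5))
  tighter_ecc <- select_voxels(fit, glm, ve_min = 0.3,
                               ecc_range = c(1, 4))
  tighter_t <- select_voxels(fit, glm, ve_min = 0.3,
                             ecc_range = c(0.5, 5), t_rule = "all_images")
  expect_true(all(tighter_ve$voxels %in% base$voxels))
  expect_true(all(tighter_ecc$voxels %in% base$voxels))
  expect_true(all(tighter_t$voxels %in% base$voxels))
})

test_that("measured profiles carry t-values per image and voxel", {
  tv <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("a", "b")))
  glm <- fake_glm(tv)
  mp <- measured_profiles(glm)
  expect_equal(dim(mp), c(2L, 3L))
  expect_equal(unname(unclass(mp)), unname(t(tv)), ignore_attr = TRUE)
})
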
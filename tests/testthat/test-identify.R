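toy_profiles <- function(m, ids = NULL, vox = NULL) {
  if (is.null(ids)) ids <- paste0("img", seq_len(nrow(m)))
  if (is.null(vox)) vox <- paste0("v", seq_len(ncol(m)))
  dimnames(m) <- list(ids, vox)
  profile_matrix(m)
}

test_that("correlation matrix reproduces the textbook formula", {
  set.seed(2)
  meas <- toy_profiles(matrix(rnorm(12), 3, 4))
  pred <- toy_profiles(matrix(rnorm(12), 3, 4))
  r <- correlation_matrix(meas, pred)
  for (i in 1:3) for (j in 1:3) {
    x <- meas[i, ]; y <- pred[j, ]
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unname(r[i, j]), oracle, tolerance = 1e-12)
  }
})

test_that("perfect and inverted profiles hit the correlation bounds", {
  m <- toy_profiles(rbind(c(1, 2, 3, 4), c(4, 1, 3, 2)))
  p <- toy_profiles(rbind(c(1, 2, 3, 4), -c(1, 2, 3, 4)))
  r <- correlation_matrix(m, p)
  expect_equal(unname(r[1, 1]), 1)
  expect_equal(unname(r[1, 2]), -1)
  expect_true(all(r >= -1 & r <= 1))
})

test_that("degenerate profiles are flagged with the offending image", {
  m <- toy_profiles(rbind(c(1, 1, 1, 1), c(1, 2, 3, 4)),
                    ids = c("flat", "ok"))
  p <- toy_profiles(matrix(rnorm(8), 2, 4))
  expect_error(correlation_matrix(m, p), "flat")
  expect_error(correlation_matrix(toy_profiles(matrix(rnorm(8), 2, 4)),
                                  toy_profiles(matrix(rnorm(6), 2, 3))),
               "voxel set")
})

test_that("argmax identification scores accuracy as a percentage", {
  # diagonal-dominant matrix: every image identified, all ranks 1
  r <- structure(diag(3) * 0.5 + 0.1,
                 dimnames = list(paste0("i", 1:3), paste0("i", 1:3)),
                 class = c("cor_matrix", "matrix"))
  res <- identify_images(r)
  expect_equal(res$accuracy, 100)
  expect_true(all(res$per_image$rank == 1))
  # 14 of 15 correct -> 93.3%
  r15 <- diag(15) * 0.5
  r15[1, 2] <- 0.9 # first image misidentified as the second
  dimnames(r15) <- list(paste0("i", 1:15), paste0("i", 1:15))
  res15 <- identify_images(structure(r15,
                                     class = c("cor_matrix", "matrix")))
  expect_equal(sum(res15$per_image$correct), 14)
  expect_equal(round(res15$accuracy, 1), 93.3)
  expect_equal(res15$per_image$rank[1], 2)
})

test_that("ties break deterministically toward the lowest index", {
  r <- matrix(0.5, 2, 3,
              dimnames = list(c("a", "b"), c("a", "b", "c")))
  expect_warning(res <- identify_images(structure(
    r, class = c("cor_matrix", "matrix"))), "ties")
  expect_equal(res$per_image$chosen, c("a", "a"))
})

test_that("identification requires the true image among candidates", {
  r <- matrix(rnorm(4), 2, 2,
              dimnames = list(c("a", "b"), c("a", "c")))
  expect_error(identify_images(structure(
    r, class = c("cor_matrix", "matrix"))), "absent")
})

test_that("identification is invariant to affine profile transforms", {
  set.seed(31)
  meas <- toy_profiles(matrix(rnorm(60), 5, 12))
  pred <- toy_profiles(matrix(rnorm(60), 5, 12))
  r1 <- identify_images(correlation_matrix(meas, pred))
  scaled <- toy_profiles(2.5 * unclass(meas) + 7)
  r2 <- identify_images(correlation_matrix(scaled, pred))
  expect_identical(r1$per_image$chosen, r2$per_image$chosen)
})

test_that("set-size curve collapses to one combination at the pool size", {
  set.seed(41)
  pool <- toy_profiles(matrix(rnorm(200), 10, 20))
  meas <- toy_profiles(unclass(pool)[1:4, ] +
                         0.1 * matrix(rnorm(80), 4, 20),
                       ids = rownames(pool)[1:4])
  cv <- set_size_curve(meas, pool, sizes = 10, n_boot = 50, seed = 1)
  expect_equal(cv$n_boot, 1L)
  expect_equal(cv$ci_lo, cv$ci_hi)
  expect_equal(cv$chance, 10)
})

test_that("set-size curves are reproducible under a seed", {
  set.seed(43)
  pool <- toy_profiles(matrix(rnorm(600), 30, 20))
  meas <- toy_profiles(unclass(pool)[1:5, ] +
                         0.5 * matrix(rnorm(100), 5, 20),
                       ids = rownames(pool)[1:5])
  c1 <- set_size_curve(meas, pool, sizes = c(5, 15), n_boot = 200, seed = 7)
  c2 <- set_size_curve(meas, pool, sizes = c(5, 15), n_boot = 200, seed = 7)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_true(all(c1$ci_lo <= c1$accuracy & c1$accuracy <= c1$ci_hi))
  expect_error(set_size_curve(meas, pool, sizes = 100, n_boot = 10),
               "pool size")
  expect_error(set_size_curve(meas, pool, sizes = 5, n_boot = 0), "n_boot")
})

test_that("structureless profiles identify at chance level", {
  set.seed(47)
  pool <- toy_profiles(matrix(rnorm(100 * 30), 100, 30))
  meas <- toy_profiles(matrix(rnorm(10 * 30), 10, 30),
                       ids = rownames(pool)[1:10])
  k <- 20
  cv <- set_size_curve(meas, pool, sizes = k, n_boot = 1000, seed = 3,
                       shuffle = TRUE)
  p <- 1 / k
  se <- 100 * sqrt(p * (1 - p) / (1000 * 10))
  expect_lt(abs(cv$accuracy - 100 / k), 3 * se)
})

test_that("confidence scores equal self minus mean correlation", {
  r <- rbind(c(0.8, 0.2, 0.2), c(0.1, 0.4, 0.1), c(0.3, 0.3, 0.3))
  dimnames(r) <- list(paste0("i", 1:3), paste0("i", 1:3))
  cs <- confidence_scores(structure(r, class = c("cor_matrix", "matrix")))
  # hand evaluation: -(sum_j (r_ij - r_ii))/N
  expect_equal(unname(cs[1]), -((0.2 - 0.8) + (0.2 - 0.8)) / 3)
  expect_equal(unname(cs[2]), 0.4 - mean(c(0.1, 0.4, 0.1)))
  # a row with equal entries scores 0
  expect_equal(unname(cs[3]), 0)
  # self-correlation above all others gives a positive score
  expect_gt(cs[1], 0)
  # algebraic identity against the direct formula
  for (i in 1:3) expect_equal(unname(cs[i]), r[i, i] - mean(r[i, ]))
})
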
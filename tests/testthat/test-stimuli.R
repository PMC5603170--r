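test_that("bar mapping sequence has the standard frame structure", {
  ap <- test_apertures()
  expect_equal(ncol(ap$frames), 240L) # 8 passes x 20 steps + 4 x 20 blanks
  expect_true(all(ap$frames %in% c(0, 1)))
  expect_equal(ap$frame_duration_s, 1.5)
  # blanks are identically zero and there are 4 x 20 of them
  blank <- is.na(ap$frame_info$pass)
  expect_equal(sum(blank), 80L)
  expect_true(all(ap$frames[, blank] == 0))
  # all stimulus energy confined to the circular aperture
  outside <- !as.vector(stimulus_area(ap$grid))
  expect_true(all(ap$frames[outside, ] == 0))
})

test_that("bar width along the motion axis matches radius/4", {
  ap <- bar_aperture_sequence(vf_grid(11, 8))
  px <- 1 / 8
  # a mid-pass frame of the vertical-bar pass (orientation 90, moving in x)
  fi <- ap$frame_info
  idx <- which(!is.na(fi$orientation) & fi$orientation == 90 &
                 fi$direction == 1 & fi$step == 10)[1]
  frame <- aperture_frame(ap, idx)
  on_cols <- which(colSums(frame) > 0)
  xs <- ap$grid$x[1, on_cols]
  expect_equal(max(xs) - min(xs) + px, 1.375, tolerance = px)
})

test_that("bar passes jointly cover the whole circular aperture", {
  ap <- test_apertures()
  covered <- rowSums(ap$frames) > 0
  inside <- as.vector(stimulus_area(ap$grid))
  expect_true(all(covered[inside]))
})

test_that("oversized bars are rejected", {
  g <- test_grid()
  expect_error(bar_aperture_sequence(g, bar_width_deg = 20), "exceeds")
})

test_that("bandpass noise is median-binarized and reproducible", {
  g <- vf_grid(8, 8)
  tx <- bandpass_noise(g, 1.5, seed = 11)
  expect_true(all(tx %in% c(0, 1)))
  expect_equal(mean(tx), 0.5, tolerance = 1 / length(tx) + 1e-12)
  expect_identical(tx, bandpass_noise(g, 1.5, seed = 11))
  expect_false(identical(tx, bandpass_noise(g, 1.5, seed = 12)))
  expect_error(bandpass_noise(g, 10), "Nyquist")
})

test_that("pre-binarized noise spectrum peaks at the band center", {
  g <- vf_grid(8, 8)
  field <- bandpass_noise(g, 1.5, seed = 5, binarize = FALSE)
  # FFT oracle: radially averaged power spectrum
  pw <- Mod(stats::fft(field))^2
  f1 <- c(seq(0, g$n / 2), seq(-(g$n / 2 - 1), -1)) / g$n *
    g$pixels_per_degree
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  bins <- cut(as.vector(fr), breaks = seq(0, 4, by = 0.25))
  radial <- tapply(as.vector(pw), bins, mean)
  peak_bin <- names(which.max(radial))
  expect_equal(peak_bin, "(1.25,1.5]")
})

test_that("hex patterns are binary, 60 cells, seed-reproducible", {
  expect_equal(sum(random_hex_pattern(0, seed = 1)), 0L)
  expect_equal(sum(random_hex_pattern(1, seed = 1)), 60L)
  p1 <- random_hex_pattern(0.5, seed = 42)
  expect_identical(p1, random_hex_pattern(0.5, seed = 42))
  expect_length(p1, 60L)
  expect_error(hex_pattern(rep(0, 59)), "60")
  expect_error(random_hex_pattern(1.5), "fill_probability")
})

test_that("hex layout has 60 cells inside the aperture", {
  lay <- hex_layout()
  expect_equal(nrow(lay$centers), 60L)
  ecc <- sqrt(rowSums(lay$centers^2))
  expect_true(all(ecc <= 5.5 - lay$cell_size_deg))
  expect_gt(min(ecc), 0) # central fixation cell excluded
})

test_that("hex rendering honors cell states and is idempotent", {
  g <- vf_grid(11, 4)
  empty <- render_hex_stimulus(random_hex_pattern(0, seed = 1), g)
  expect_true(all(empty == 0))
  all_on <- render_hex_stimulus(random_hex_pattern(1, seed = 1), g)
  # the full pattern equals the union of the 60 single-cell renders
  union_img <- matrix(0, g$n, g$n)
  for (k in seq_len(60)) {
    states <- rep(0L, 60); states[k] <- 1L
    union_img <- pmax(union_img, render_hex_stimulus(hex_pattern(states), g))
  }
  expect_equal(union_img, all_on)
  pat <- random_hex_pattern(0.5, seed = 9)
  expect_identical(render_hex_stimulus(pat, g),
                   render_hex_stimulus(pat, g))
  expect_error(render_hex_stimulus(pat, vf_grid(11, 1)), "coarse")
})

test_that("isolated filled cells render as that many components", {
  g <- vf_grid(11, 6)
  lay <- hex_layout()
  # greedily pick cells with pairwise center distance > 3 cell widths
  chosen <- integer(0)
  for (k in seq_len(60)) {
    if (length(chosen) == 4) break
    d <- if (length(chosen)) sqrt(rowSums(
      (lay$centers[chosen, , drop = FALSE] -
         matrix(lay$centers[k, ], length(chosen), 2, byrow = TRUE))^2))
      else Inf
    if (all(d > 3 * sqrt(3) * lay$cell_size_deg)) chosen <- c(chosen, k)
  }
  states <- rep(0L, 60); states[chosen] <- 1L
  img <- render_hex_stimulus(hex_pattern(states), g)
  expect_equal(count_components(img), length(chosen))
})

test_that("natural-image preprocessing hits the contrast target", {
  g <- vf_grid(11, 4)
  set.seed(7)
  raw <- matrix(runif(64 * 64), 64, 64)
  img <- preprocess_natural_image(raw, g)
  expect_lt(abs(img$achieved_rms - 0.5) / 0.5, 0.02)
  # pixels with zero mask weight sit exactly at mean luminance
  expect_true(all(img$luminance[img$mask == 0] == img$mean_luminance))
  expect_true(all(img$luminance >= 0 & img$luminance <= 1))
})

test_that("preprocessing rejects constant images and ignores affine scale", {
  g <- vf_grid(11, 4)
  expect_error(preprocess_natural_image(matrix(0.5, 32, 32), g), "constant")
  set.seed(8)
  raw <- matrix(runif(48 * 48), 48, 48)
  a <- preprocess_natural_image(raw, g)
  b <- preprocess_natural_image(0.2 + 3 * raw, g)
  expect_equal(a$luminance, b$luminance, tolerance = 1e-12)
})

test_that("raised-cosine mask ramps from 1 to 0 over the edge width", {
  g <- vf_grid(11, 8)
  m <- raised_cosine_mask(g, edge_width_deg = 0.9)
  r <- sqrt(g$x^2 + g$y^2)
  expect_true(all(m[r <= 5.5 - 0.9] == 1))
  expect_true(all(m[r > 5.5] == 0))
  mid <- abs(r - (5.5 - 0.45)) < 0.02
  expect_true(all(abs(m[mid] - 0.5) < 0.1))
})

test_that("synthetic natural textures run the full preprocessing", {
  g <- vf_grid(11, 4)
  img <- simulate_natural_texture(g, seed = 3)
  expect_s3_class(img, "natural_image")
  expect_lt(abs(img$achieved_rms - 0.5) / 0.5, 0.02)
  expect_identical(img$luminance,
                   simulate_natural_texture(g, seed = 3)$luminance)
})
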
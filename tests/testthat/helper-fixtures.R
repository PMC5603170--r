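# Shared fixtures for the test suite. Grids are kept small so the whole
# suite runs in minutes on one CPU; the science does not depend on pixel
# density beyond resolving the stimuli.

test_grid <- function(ppd = 3) vf_grid(11, ppd)

test_hrf <- function(tr = 1.5) hrf_parameters(tr = tr)

test_apertures <- function(ppd = 3) bar_aperture_sequence(test_grid(ppd))

# full-field binary stimulus (all on inside the circular aperture)
full_field <- function(grid) {
  matrix(as.numeric(stimulus_area(grid)), grid$n, grid$n)
}

# independent connected-component counter (4-connectivity flood fill);
# used as an oracle for the hexagonal renderer
count_components <- function(img) {
  n <- nrow(img); m <- ncol(img)
  lab <- matrix(0L, n, m); cur <- 0L
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (img[i, j] == 1 && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= n && q[2] >= 1 && q[2] <= m &&
              img[q[1], q[2]] == 1 && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- cur
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  cur
}

# simulate mapping data and refit, returning truth and estimates
recovery_experiment <- function(n_voxels, noise_sd = 0, seed = 1,
                                ppd = 3, search = prf_search(
                                  position_spacing = 0.5, n_sigma = 8)) {
  ap <- test_apertures(ppd)
  hrf <- test_hrf()
  prfs <- sample_prf_population(
    population_spec(n_voxels = n_voxels, ecc_range = c(0.5, 4.0)),
    seed = seed)
  bold <- simulate_mapping_run(prfs, ap, hrf, noise_sd = noise_sd,
                               seed = seed + 1L)
  fit <- fit_prf(bold, ap, hrf, search = search)
  truth <- data.frame(x0 = vapply(prfs, `[[`, 0, "x0"),
                      y0 = vapply(prfs, `[[`, 0, "y0"),
                      sigma = vapply(prfs, `[[`, 0, "sigma"))
  list(truth = truth, fit = fit, prfs = prfs, apertures = ap, hrf = hrf,
       bold = bold)
}
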
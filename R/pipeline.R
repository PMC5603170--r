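#' Validate and complete a run configuration
#'
#' Fills the standard analysis defaults (variance-explained threshold 0.55,
#' eccentricity band 0.5-4.5 deg, 1000 bootstrap draws, TR 1.5 s, 8 discarded
#' start-up frames) into a configuration list and rejects unknown keys or
#' out-of-range values. The configuration can be given as a list or as the
#' path of a YAML file.
#'
#' @param config Named list (possibly empty) or YAML file path.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defaults <- list(
    extent_deg = 11, pixels_per_degree = 4,
    tr_s = 1.5, discard_frames = 8,
    ve_min = 0.55, ecc_range = c(0.5, 4.5), t_rule = "any_image",
    n_images = 15, mode = "synthetic",
    n_voxels = 120, noise_sd = 0,
    sizes = c(15, 45, 100, 200), pool_size = 200, n_boot = 1000,
    seed = 1, out_dir = NULL,
    search = list(position_spacing = 0.5, n_sigma = 8))
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (cfg$tr_s <= 0) stop("'tr_s' must be positive")
  if (cfg$n_boot < 1) stop("'n_boot' must be at least 1")
  if (cfg$ve_min < 0) stop("'ve_min' must be nonnegative")
  if (cfg$extent_deg <= 0 || cfg$pixels_per_degree <= 0)
    stop("grid extent and density must be positive")
  if (cfg$noise_sd < 0) stop("'noise_sd' must be nonnegative")
  if (cfg$pool_size < cfg$n_images)
    stop("'pool_size' must be at least 'n_images'")
  if (any(cfg$sizes > cfg$pool_size))
    stop("set sizes cannot exceed the candidate pool size")
  class(cfg) <- "run_config"
  cfg
}

#' Run the full simulated identification pipeline
#'
#' Executes the complete analysis on a simulated session: sample a
#' ground-truth pRF population, simulate the mapping run and image session,
#' fit pRFs, fit the block-design GLM, apply the voxel-selection filters,
#' build predicted profiles for a candidate pool, identify the presented
#' images, and compute the set-size accuracy curve and per-image confidence
#' scores. All randomness derives from `config$seed`. If `config$out_dir`
#' is set, intermediate tables and a JSON report are written there.
#'
#' @param config A [validate_config()] result (or a list/path, which is
#'   validated first).
#' @return A `run_report`: list with the configuration, per-stage voxel
#'   counts, the identification result, the set-size curve, and confidence
#'   scores.
#' @export
run_end_to_end <- function(config = list()) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  grid <- stage("grid", vf_grid(config$extent_deg, config$pixels_per_degree))
  apertures <- stage("stimuli", bar_aperture_sequence(grid))
  hrf <- hrf_parameters(tr = config$tr_s)
  prfs <- stage("population", sample_prf_population(
    population_spec(n_voxels = config$n_voxels), seed = config$seed))
  mapping <- stage("mapping", simulate_mapping_run(
    prfs, apertures, hrf, noise_sd = config$noise_sd,
    seed = config$seed + 1L))
  fit <- stage("prf_fit", fit_prf(
    mapping, apertures, hrf,
    search = do.call(prf_search, config$search)))

  images <- stage("images", {
    if (config$mode == "synthetic")
      lapply(seq_len(config$n_images), function(i)
        render_hex_stimulus(
          random_hex_pattern(seed = config$seed + 100L + i), grid))
    else
      lapply(seq_len(config$n_images), function(i)
        simulate_natural_texture(grid, seed = config$seed + 100L + i))
  })
  names(images) <- sprintf("img%02d", seq_along(images))
  session <- stage("session", simulate_image_session(
    prfs, images, grid, mode = config$mode, tr_s = config$tr_s, hrf = hrf,
    noise_sd = config$noise_sd, seed = config$seed + 2L))
  design <- stage("design", build_block_design(
    session$events, session$n_frames, config$tr_s, hrf))
  glm <- stage("glm", fit_glm(session$bold, design))
  sel <- stage("selection", select_voxels(
    fit, glm, ve_min = config$ve_min, ecc_range = config$ecc_range,
    t_rule = config$t_rule))

  measured <- measured_profiles(glm)[, sel$voxels, drop = FALSE]
  measured <- profile_matrix(measured, mode = "measured_t")
  fitted_prfs <- as_prf_list(fit)[sel$voxels]
  predicted <- stage("predict", {
    pm <- build_predicted_profiles(fitted_prfs, images, grid,
                                   mode = config$mode,
                                   image_ids = names(images))
    colnames(pm) <- colnames(measured)
    profile_matrix(pm, mode = "predicted")
  })
  corr <- stage("identify", correlation_matrix(measured, predicted))
  ident <- identify_images(corr)
  conf <- confidence_scores(corr)

  pool_images <- stage("pool", {
    extra <- config$pool_size - config$n_images
    pool <- images
    if (extra > 0) {
      more <- if (config$mode == "synthetic")
        lapply(seq_len(extra), function(i)
          render_hex_stimulus(
            random_hex_pattern(seed = config$seed + 1000L + i), grid))
      else
        lapply(seq_len(extra), function(i)
          simulate_natural_texture(grid, seed = config$seed + 1000L + i))
      names(more) <- sprintf("pool%03d", seq_len(extra))
      pool <- c(pool, more)
    }
    pool
  })
  pool_pred <- build_predicted_profiles(fitted_prfs, pool_images, grid,
                                        mode = config$mode,
                                        image_ids = names(pool_images))
  colnames(pool_pred) <- colnames(measured)
  pool_pred <- profile_matrix(pool_pred, mode = "predicted")
  curve <- stage("set_size", set_size_curve(
    measured, pool_pred, sizes = config$sizes, n_boot = config$n_boot,
    seed = config$seed + 3L))

  report <- list(
    config = unclass(config),
    n_voxels_simulated = length(prfs),
    n_voxels_selected = length(sel$voxels),
    selection_criteria = sel$criteria,
    identification = ident$per_image,
    accuracy = ident$accuracy,
    set_size_curve = as.data.frame(curve),
    confidence_scores = conf)
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir,
                                                 fit = fit, glm = glm)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("End-to-end identification run\n")
  cat(sprintf("  voxels: %d simulated, %d selected\n",
              x$n_voxels_simulated, x$n_voxels_selected))
  cat(sprintf("  within-set accuracy: %.1f%% (%d images)\n",
              x$accuracy, nrow(x$identification)))
  cat("  set-size curve:\n")
  print(round(x$set_size_curve[, c("size", "accuracy", "ci_lo", "ci_hi",
                                   "chance")], 2))
  invisible(x)
}

# CSV + JSON outputs for a pipeline run
write_run_report <- function(report, out_dir, fit = NULL, glm = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(fit))
    utils::write.csv(fit$fits, file.path(out_dir, "prf_fits.csv"),
                     row.names = FALSE)
  if (!is.null(glm))
    utils::write.csv(as.data.frame(glm$t), file.path(out_dir, "glm_t.csv"))
  utils::write.csv(report$identification,
                   file.path(out_dir, "identification.csv"),
                   row.names = FALSE)
  utils::write.csv(report$set_size_curve,
                   file.path(out_dir, "set_size_curve.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = report$config,
         n_voxels_selected = report$n_voxels_selected,
         accuracy = report$accuracy,
         set_size_curve = report$set_size_curve,
         confidence_scores = as.list(report$confidence_scores)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}
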
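#' Default pipeline configuration
#'
#' One nested list with a section per stage, mirroring the module
#' configuration objects. Any subset can be overridden from a YAML file
#' ([read_config()]); values are validated before a stage runs.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    phantom = list(
      n = 10L,
      grid_shape = c(64L, 64L, 64L),
      spacing = c(0.4, 0.4, 0.4),
      noise_sd = 18,
      bias_amplitude = 0.2,
      n_landmarks = 64L,
      jitter_sd = 0.05,
      pose_trans_voxels = 5,
      pose_rot_deg = 10,
      pose_scale_range = c(0.9, 1.1)
    ),
    ssm = list(tol = 1e-7, max_iter = 100L, init = "first"),
    registration = list(bins = 32L, max_iter = 50L, step_trans_mm = 2.0,
                        step_rot_rad = 0.05, tol = 1e-6, pyramid_levels = 2L),
    roi = list(margin_voxels = 3L),
    drlse = list(mu = 0.1, lambda = 3, alpha = 0, epsilon = 1.5,
                 dt = 1, n_iter = 10L, sigma = 1.0),
    region_growing = list(tolerance_frac = 0.35, connectivity = 26L,
                          curvature_percentile = 95, smooth_sigma = 2.0)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values found in the file override the defaults section-by-section;
#' anything omitted keeps its default.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Constructs every downstream configuration object (phantom spec,
#' registration config, DRLSE parameters) so that each module's invariants
#' are checked before any stage runs.
#'
#' @param cfg configuration list as from [default_config()].
#' @return `cfg`, invisibly; errors name the offending section.
#' @export
validate_config <- function(cfg) {
  try_section <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("invalid config section '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  try_section("phantom", config_phantom_spec(cfg))
  try_section("registration", config_registration(cfg))
  try_section("drlse", config_drlse(cfg))
  try_section("region_growing", {
    rg <- cfg$region_growing
    if (rg$tolerance_frac <= 0) stop("tolerance_frac must be > 0")
    region_grow_config(c(0L, 0L, 0L), tolerance = 1,
                       connectivity = rg$connectivity,
                       curvature_percentile = rg$curvature_percentile)
  })
  try_section("ssm", {
    if (cfg$ssm$tol <= 0 || cfg$ssm$max_iter < 1) stop("bad tol/max_iter")
  })
  if (cfg$phantom$n < 2)
    stop("invalid config section 'phantom': a cohort needs n >= 2")
  invisible(cfg)
}

config_phantom_spec <- function(cfg) {
  p <- cfg$phantom
  phantom_spec(grid_shape = p$grid_shape, spacing = p$spacing,
               noise_sd = p$noise_sd, bias_amplitude = p$bias_amplitude,
               n_landmarks = p$n_landmarks, jitter_sd = p$jitter_sd,
               pose_trans_voxels = p$pose_trans_voxels,
               pose_rot_deg = p$pose_rot_deg,
               pose_scale_range = p$pose_scale_range)
}

config_registration <- function(cfg) {
  r <- cfg$registration
  registration_config(bins = r$bins, max_iter = r$max_iter,
                      step_trans_mm = r$step_trans_mm,
                      step_rot_rad = r$step_rot_rad, tol = r$tol,
                      pyramid_levels = r$pyramid_levels)
}

config_drlse <- function(cfg) {
  d <- cfg$drlse
  drlse_params(mu = d$mu, lambda = d$lambda, alpha = d$alpha,
               epsilon = d$epsilon, dt = d$dt, n_iter = d$n_iter,
               sigma = d$sigma)
}

#' Automatic seed and tolerance for the region-growing baseline
#'
#' Seeds at the brightest voxel of the Gaussian-smoothed volume (for a
#' T2-like phantom this lies inside the fluid-filled labyrinth) and sets
#' the tolerance to `tolerance_frac` of the robust intensity range (0.5th
#' to 99.5th percentile).
#'
#' @param vol a [volume3d()].
#' @param rg region-growing section of the configuration.
#' @return a [region_grow_config()].
#' @export
auto_region_grow_config <- function(vol, rg = default_config()$region_growing) {
  sm <- gaussian_smooth(vol$data, rg$smooth_sigma)
  seed <- which(sm == max(sm), arr.ind = TRUE)[1, ] - 1L
  q <- stats::quantile(vol$data, c(0.005, 0.995), names = FALSE)
  region_grow_config(seed, tolerance = rg$tolerance_frac * (q[2] - q[1]),
                     connectivity = rg$connectivity,
                     curvature_percentile = rg$curvature_percentile)
}

#' ROI box of a truth mask plus a margin
#'
#' @param mask a nonempty [binary_mask()].
#' @param margin_voxels margin added on every side (clipped to the grid).
#' @return a [roi_box()].
#' @export
mask_roi <- function(mask, margin_voxels = 3L) {
  w <- which(mask$data, arr.ind = TRUE)
  if (!nrow(w)) stop("mask is empty")
  lo <- pmax(apply(w, 2, min) - 1L - margin_voxels, 0L)
  hi <- pmin(apply(w, 2, max) + margin_voxels, dim(mask$data))
  roi_box(lo, hi)
}

log_stage <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
}

#' Run the segmentation pipeline
#'
#' Executes the requested stage(s) in order on a working directory:
#'
#' * `simulate` — generate a phantom cohort (volumes, truth masks,
#'   landmarks, cohort manifest);
#' * `build-ssm` — generalized Procrustes alignment of the cohort
#'   landmarks, atlas designation (first sample) and atlas ROI;
#' * `segment` — shape-model level-set segmentation and the
#'   region-growing baseline for every non-atlas subject;
#' * `evaluate` — metric panel of both methods against the truth masks,
#'   written as `evaluation.csv`;
#' * `all` — all of the above.
#'
#' Stages read their inputs from `out_dir`, so later stages fail with a
#' dependency error naming the missing stage when run out of order.
#'
#' @param command one of `"simulate"`, `"build-ssm"`, `"segment"`,
#'   `"evaluate"`, `"all"`.
#' @param out_dir working directory (created if missing).
#' @param config configuration list ([default_config()] / [read_config()]).
#' @param seed integer master seed.
#' @param verbose log stage boundaries and parameters.
#' @return run manifest (list), invisibly written as `run_manifest.json`.
#' @export
run_pipeline <- function(command = c("all", "simulate", "build-ssm",
                                     "segment", "evaluate"),
                         out_dir, config = default_config(), seed = 1L,
                         verbose = FALSE) {
  command <- match.arg(command)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (command == "all")
    c("simulate", "build-ssm", "segment", "evaluate") else command

  manifest <- list(tool = "labyrinthSeg",
                   version = as.character(utils::packageVersion("labyrinthSeg")),
                   seed = as.integer(seed), command = command,
                   config = config, outputs = list())
  t_all <- Sys.time()
  for (st in stages) {
    log_stage(verbose, "stage ", st, " started")
    t0 <- Sys.time()
    outs <- switch(st,
      "simulate" = stage_simulate(out_dir, config, seed, verbose),
      "build-ssm" = stage_build_ssm(out_dir, config, verbose),
      "segment" = stage_segment(out_dir, config, verbose),
      "evaluate" = stage_evaluate(out_dir, verbose))
    manifest$outputs[[st]] <-
      list(files = outs, seconds = as.numeric(difftime(Sys.time(), t0,
                                                       units = "secs")))
    log_stage(verbose, "stage ", st, " finished")
  }
  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t_all,
                                                units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

require_stage_file <- function(path, stage) {
  if (!file.exists(path))
    stop("missing '", basename(path), "': run the '", stage,
         "' stage first", call. = FALSE)
  path
}

stage_simulate <- function(out_dir, config, seed, verbose) {
  spec <- config_phantom_spec(config)
  cohort <- generate_cohort(config$phantom$n, spec, seed)
  files <- character(0)
  entries <- list()
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    vf <- file.path(out_dir, sprintf("subject_%02d.nii.gz", i))
    mf <- file.path(out_dir, sprintf("subject_%02d_truth.nii.gz", i))
    lf <- file.path(out_dir, sprintf("subject_%02d_landmarks.csv", i))
    write_volume(s$volume, vf)
    write_volume(s$truth_mask, mf)
    write_landmarks(s$landmarks, lf)
    files <- c(files, vf, mf, lf)
    entries[[i]] <- list(volume = basename(vf), truth = basename(mf),
                         landmarks = basename(lf), seed = s$seed,
                         pose = list(scale = s$pose$scale,
                                     rotation = as.numeric(t(s$pose$rotation)),
                                     translation_mm = s$pose$translation))
  }
  cf <- file.path(out_dir, "cohort.json")
  jsonlite::write_json(list(n = length(cohort), samples = entries), cf,
                       auto_unbox = TRUE, digits = NA)
  log_stage(verbose, "simulated ", length(cohort), " phantoms")
  c(files, cf)
}

read_cohort_manifest <- function(out_dir) {
  cf <- require_stage_file(file.path(out_dir, "cohort.json"), "simulate")
  jsonlite::read_json(cf, simplifyVector = FALSE)
}

stage_build_ssm <- function(out_dir, config, verbose) {
  man <- read_cohort_manifest(out_dir)
  lms <- lapply(man$samples, function(s)
    read_landmarks(file.path(out_dir, s$landmarks)))
  model <- build_shape_model(lms, tol = config$ssm$tol,
                             max_iter = config$ssm$max_iter,
                             init = config$ssm$init)
  mf <- file.path(out_dir, "model.json")
  write_shape_model(model, mf)
  # atlas: first cohort sample; ROI from its truth mask
  truth1 <- read_mask(file.path(out_dir, man$samples[[1]]$truth))
  box <- mask_roi(truth1, config$roi$margin_voxels)
  rf <- file.path(out_dir, "atlas_roi.json")
  write_roi(box, rf)
  log_stage(verbose, "SSM built from ", length(lms), " shapes in ",
            model$iterations, " iterations (converged: ", model$converged, ")")
  c(mf, rf)
}

load_segmentation_model <- function(out_dir) {
  man <- read_cohort_manifest(out_dir)
  mf <- require_stage_file(file.path(out_dir, "model.json"), "build-ssm")
  rf <- require_stage_file(file.path(out_dir, "atlas_roi.json"), "build-ssm")
  model <- read_shape_model(mf)
  atlas <- read_volume(file.path(out_dir, man$samples[[1]]$volume))
  atlas_lm <- read_landmarks(file.path(out_dir, man$samples[[1]]$landmarks))
  attach_atlas(structure(model, class = "shape_model"), atlas_lm, atlas,
               read_roi(rf))
}

stage_segment <- function(out_dir, config, verbose) {
  man <- read_cohort_manifest(out_dir)
  model <- load_segmentation_model(out_dir)
  reg_cfg <- config_registration(config)
  dp <- config_drlse(config)
  files <- character(0)
  for (i in seq_along(man$samples)[-1]) {
    vol <- read_volume(file.path(out_dir, man$samples[[i]]$volume))
    res <- segment_is3dls(vol, model, reg_cfg, dp,
                          roi_margin_voxels = config$roi$margin_voxels)
    f1 <- file.path(out_dir, sprintf("subject_%02d_is3dls.nii.gz", i))
    write_volume(res$mask, f1)
    base <- segment_region_growing_baseline(
      vol, auto_region_grow_config(vol, config$region_growing), dp)
    f2 <- file.path(out_dir, sprintf("subject_%02d_rg.nii.gz", i))
    write_volume(base, f2)
    files <- c(files, f1, f2)
    log_stage(verbose, "segmented subject ", i)
  }
  files
}

stage_evaluate <- function(out_dir, verbose) {
  man <- read_cohort_manifest(out_dir)
  rows <- list()
  for (i in seq_along(man$samples)[-1]) {
    truth <- read_mask(file.path(out_dir, man$samples[[i]]$truth))
    for (method in c("is3dls", "rg")) {
      pf <- file.path(out_dir, sprintf("subject_%02d_%s.nii.gz", i, method))
      require_stage_file(pf, "segment")
      rep <- evaluate_segmentation(read_mask(pf), truth)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(subject = i, method = method),
              as.data.frame(rep))
    }
  }
  df <- do.call(rbind, rows)
  ef <- file.path(out_dir, "evaluation.csv")
  utils::write.csv(df, ef, row.names = FALSE)
  log_stage(verbose, "evaluated ", nrow(df), " segmentations")
  ef
}
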
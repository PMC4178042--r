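#' Pipeline configuration
#'
#' Bundles every tunable parameter of the eye-analysis pipeline with its
#' default. All defaults are documented on the stage functions.
#'
#' @param threshold_frac Layer-peak threshold fraction ([detect_boundaries()]).
#' @param denoise_size Median filter half-width.
#' @param axial_sigma,lateral_sigma Ridge filter scales.
#' @param refine_window Gradient refinement search span, rows.
#' @param snake A [snake_params()] (or `NULL` to skip refinement).
#' @param h_um Curvature stencil arm, µm.
#' @param step_um Dense resampling step, µm.
#' @param max_gap_um Widest bridgeable invalid gap, µm.
#' @param resolution_um_per_px En-face raster scale.
#' @param scale A [color_scale()].
#' @param thresholds A [staphyloma_thresholds()].
#' @param metric_sampling `"dense"` or `"ascan"` (see [eye_metrics()]).
#' @param seed Seed recorded in the run log.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_frac = 0.3, denoise_size = 1L,
                            axial_sigma = 2, lateral_sigma = 1,
                            refine_window = 8L, snake = snake_params(),
                            h_um = 500, step_um = 1, max_gap_um = 1000,
                            resolution_um_per_px = 10, scale = color_scale(),
                            thresholds = staphyloma_thresholds(),
                            metric_sampling = "dense", seed = NULL) {
  structure(list(threshold_frac = threshold_frac, denoise_size = denoise_size,
                 axial_sigma = axial_sigma, lateral_sigma = lateral_sigma,
                 refine_window = refine_window, snake = snake, h_um = h_um,
                 step_um = step_um, max_gap_um = max_gap_um,
                 resolution_um_per_px = resolution_um_per_px, scale = scale,
                 thresholds = thresholds, metric_sampling = metric_sampling,
                 seed = seed),
            class = "pipeline_config")
}

segment_scan <- function(scan, config, corrections = NULL) {
  den <- oct_denoise(scan$pixels, config$denoise_size)
  bounds <- detect_boundaries(scan, threshold_frac = config$threshold_frac,
                              denoise_size = config$denoise_size,
                              axial_sigma = config$axial_sigma,
                              lateral_sigma = config$lateral_sigma,
                              refine_window = config$refine_window)
  bm <- bounds$bm
  if (!is.null(corrections) && NROW(corrections))
    bm <- apply_corrections(bm, corrections)
  if (!is.null(config$snake)) {
    # attract the contour to the feature that defines the BM line: the
    # falling-gradient posterior edge of the RPE/BM complex
    edge <- pmax(-gradient_response(den), 0)
    bm <- refine_snakes(bm, scan$pixels, config$snake, response = edge)
  }
  bm
}

#' Run the full analysis pipeline on one eye
#'
#' Loads a radial scan set, segments the BM line in every B-scan (filter
#' cascade, optional manual corrections, active-contour refinement), computes
#' the 12 curvature profiles, renders the en-face color map, derives the eye
#' metrics with the staphyloma classification, and writes all artifacts plus
#' a machine-readable run log (JSON, including an md5 hash of the effective
#' configuration). Deterministic for a given manifest and configuration.
#'
#' @param manifest Path to the eye's scan-set manifest
#'   ([load_radial_set()]), or a [radial_scan_set()] directly.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param config A [pipeline_config()].
#' @param corrections Optional data frame (or CSV path) of manual re-plots
#'   with columns `angle_deg`, `column`, `depth_px`.
#' @param verbose Log per-stage counts with `message()`.
#' @return Invisibly, a list with `metrics`, `map`, `profiles`, `traces`
#'   and the written-files manifest.
#' @export
run_eye <- function(manifest, out_dir = NULL, config = pipeline_config(),
                    corrections = NULL, verbose = FALSE) {
  set <- if (inherits(manifest, "radial_scan_set")) manifest
         else load_radial_set(manifest)
  if (is.character(corrections)) corrections <- read_corrections_csv(corrections)

  log_counts <- list()
  traces <- list()
  profiles <- list()
  for (i in seq_along(set$scans)) {
    scan <- set$scans[[i]]
    corr <- NULL
    if (!is.null(corrections)) {
      corr <- corrections[corrections$angle_deg == scan$angle_deg, , drop = FALSE]
      if (!nrow(corr)) corr <- NULL
    }
    bm <- segment_scan(scan, config, corr)
    prof <- trace_curvature(bm, scan$calib, scan$center_col,
                            h_um = config$h_um, step_um = config$step_um,
                            max_gap_um = config$max_gap_um)
    traces[[i]] <- bm
    profiles[[i]] <- prof
    log_counts[[i]] <- list(angle_deg = scan$angle_deg,
                            cols_segmented = sum(bm$valid),
                            manual_points = sum(bm$manual),
                            valid_kappa = sum(prof$valid))
    if (verbose)
      message(sprintf("scan %g deg: %d cols segmented, %d manual, %d kappa samples",
                      scan$angle_deg, sum(bm$valid), sum(bm$manual),
                      sum(prof$valid)))
  }
  angles <- scan_angles(set)
  map <- render_enface(profiles, angles, config$resolution_um_per_px,
                       config$scale)
  cov <- coverage_of_map(map)
  metrics <- eye_metrics(profiles, coverage = cov,
                         sampling = config$metric_sampling,
                         eye_id = set$eye_id)
  metrics$staphyloma <- classify_staphyloma(metrics, config$thresholds)
  if (verbose)
    message(sprintf("eye '%s': coverage %.1f%%, staphyloma = %s",
                    set$eye_id, 100 * cov, metrics$staphyloma))

  files <- NULL
  if (!is.null(out_dir)) {
    files <- write_outputs(metrics, map, out_dir, eye_id = set$eye_id)
    cfg_json <- jsonlite::toJSON(config_as_list(config), auto_unbox = TRUE,
                                 digits = NA)
    run_log <- list(eye_id = set$eye_id, n_lines = set$n_lines,
                    config_md5 = md5_string(as.character(cfg_json)),
                    config = config_as_list(config),
                    stages = log_counts,
                    coverage = cov,
                    staphyloma = metrics$staphyloma)
    log_path <- file.path(out_dir, paste0(set$eye_id, "_runlog.json"))
    jsonlite::write_json(run_log, log_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- rbind(files, data.frame(kind = "runlog_json", path = log_path))
  }
  invisible(list(metrics = metrics, map = map, profiles = profiles,
                 traces = traces, files = files))
}

config_as_list <- function(config) {
  lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
}

#' Simulate a cohort of phantom eyes to disk
#'
#' Generates the cohort ([generate_cohort()]), renders each eye's radial
#' scan set, writes one directory per eye (images + manifest, analyzable
#' with [run_eye()] unchanged) and a ground-truth CSV of the generative
#' metrics. Re-running with the same spec and seed reproduces the truth CSV
#' byte for byte.
#'
#' @param spec Cohort spec: a list with `seed` and `groups`
#'   (see [generate_cohort()]), or a path to such a spec as JSON.
#' @param out_dir Output directory.
#' @param n_angles Scan lines per eye.
#' @return Invisibly, the path of the truth CSV.
#' @export
run_simulate <- function(spec, out_dir, n_angles = 12) {
  if (is.character(spec)) {
    spec <- jsonlite::read_json(spec, simplifyVector = FALSE)
    spec$groups <- lapply(spec$groups, function(g)
      lapply(g, function(x) if (is.list(x)) unlist(x) else x))
  }
  if (is.null(spec$groups) || !length(spec$groups))
    stopf("cohort spec has zero groups")
  eyes <- generate_cohort(spec$groups, seed = spec$seed %||% 1L,
                          render = TRUE, n_angles = n_angles)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(eyes, function(e) {
    id <- e$eye$set$eye_id
    write_radial_set(e$eye$set, file.path(out_dir, id))
    data.frame(eye_id = id, label = e$label,
               mean_abs_kappa = e$truth$mean_abs_kappa,
               var_kappa = e$truth$var_kappa,
               base_radius_um = e$model$base_radius_um,
               kind = e$model$kind,
               speckle_sigma = e$speckle_sigma)
  })
  truth_path <- file.path(out_dir, "truth.csv")
  write_exact_csv(do.call(rbind, rows), truth_path)
  invisible(truth_path)
}
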
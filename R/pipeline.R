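# End-to-end pipeline plumbing: configuration, dataset simulation on disk,
# and the calibrate -> fuse -> gait -> agree run, with a machine-readable
# manifest so identical configs yield identical outputs.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default. The values round-trip
#' losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @return nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    rig = list(n_rows = 3L, row_spacing = 2.5, corridor_width = 2,
               inward_angle = 35, sensor_height = 0.8),
    markers = list(n_markers = 3L, spacing = 2.5, start_x = 1.5,
                   template_side = 0.30, noise_sigma = 0.005),
    clouds = list(density = 400L, noise_sigma = 0.002),
    gait = list(step_length = 0.73, step_width = 0.12, cadence = 100,
                duty_factor = 0.6, n_strides = 8, start_foot = "L",
                lead_in = 0.5, lead_out = 0.5),
    corruption = list(joint_noise_sigma = 0.01, lateral_bias = 0.015,
                      occlusion = TRUE, occlusion_threshold = 0.08,
                      timestamp_jitter = 0.002, rate_wobble = 0.5),
    fusion = list(rate = 30L, max_gap = 0.2, filter_order = 4L,
                  filter_cutoff = 6),
    analysis = list(hysteresis = 0.02, start_foot = "L"),
    dataset = list(n_subjects = 10L, n_recordings = 1L,
                   reference_rate = 120L),
    stats = list(pair_max_dt = 0.2)
  )
}

#' Validate a pipeline configuration
#'
#' @param config configuration list.
#' @return the config, invisibly; errors name the offending field.
#' @export
validate_pipeline_config <- function(config) {
  d <- config$gait$duty_factor
  if (!is.null(d) && (d <= 0.5 || d >= 1)) {
    stop("config field gait.duty_factor must be in (0.5, 1), got ", d,
         call. = FALSE)
  }
  if (config$fusion$filter_cutoff >= config$fusion$rate / 2) {
    stop("config field fusion.filter_cutoff must be below the Nyquist ",
         "frequency of fusion.rate", call. = FALSE)
  }
  if (!config$analysis$start_foot %in% c("L", "R")) {
    stop("config field analysis.start_foot must be 'L' or 'R'", call. = FALSE)
  }
  invisible(config)
}

#' @rdname default_pipeline_config
#' @param config configuration list.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname default_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- utils::modifyList(default_pipeline_config(), yaml::read_yaml(path))
  validate_pipeline_config(cfg)
  cfg
}

subject_gait_command <- function(cfg, subject_idx) {
  # per-subject gait variation around the commanded defaults, seeded from the
  # dataset seed so subjects are reproducible individuals
  g <- cfg$gait
  g$step_length <- g$step_length * stats::runif(1, 0.9, 1.1)
  g$step_width <- g$step_width * stats::runif(1, 0.8, 1.2)
  g$cadence <- g$cadence * stats::runif(1, 0.92, 1.08)
  g
}

#' Simulate a complete dataset on disk
#'
#' Writes everything the pipeline consumes: the rig and marker ground truth,
#' marker observations, per-sensor point clouds, and per recording the
#' per-sensor skeleton streams, a reference-system ankle-trajectory file and
#' a ground-truth sidecar, plus a manifest with the seed and config hash.
#'
#' @param dir output directory.
#' @param config configuration list (default [default_pipeline_config()]).
#' @param seed overrides `config$seed` when given.
#' @return the directory, invisibly.
#' @export
simulate_dataset <- function(dir, config = default_pipeline_config(),
                             seed = NULL) {
  cfg <- validate_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)

  rig <- simulate_rig(cfg$rig$n_rows, cfg$rig$row_spacing,
                      cfg$rig$corridor_width, cfg$rig$inward_angle,
                      cfg$rig$sensor_height)
  markers <- default_marker_poses(cfg$markers$n_markers, cfg$markers$spacing,
                                  cfg$markers$start_x)
  template <- marker_template(cfg$markers$template_side)
  obs <- simulate_marker_observations(rig, markers, template,
                                      cfg$markers$noise_sigma,
                                      seed = cfg$seed)
  write_marker_observations(obs, file.path(dir, "markers.tsv"))
  clouds <- simulate_point_clouds(rig, density = cfg$clouds$density,
                                  noise_sigma = cfg$clouds$noise_sigma,
                                  seed = cfg$seed + 1L)
  cloud_dir <- file.path(dir, "clouds")
  dir.create(cloud_dir, showWarnings = FALSE)
  for (id in names(clouds)) {
    write_point_cloud(clouds[[id]], file.path(cloud_dir, paste0("sensor_", id, ".xyz")))
  }
  truth_cal <- rig_poses_in_marker_frame(rig, markers)
  true_cal <- tibble::tibble(sensor_id = truth_cal$sensor_id,
                             transform = truth_cal$pose,
                             path = purrr::map(truth_cal$sensor_id,
                                               ~ character(0)),
                             path_length = 0L, rms = 0, refined = FALSE)
  attr(true_cal, "origin_marker") <- "1"
  class(true_cal) <- c("rig_calibration", class(true_cal))
  write_calibration(true_cal, file.path(dir, "ground_truth_poses.yaml"))

  inv_m1 <- rt_invert(markers$pose[[1]])
  set.seed(cfg$seed + 2L)
  rec_id <- 0L
  for (s in seq_len(cfg$dataset$n_subjects)) {
    gcmd <- subject_gait_command(cfg, s)
    for (r in seq_len(cfg$dataset$n_recordings)) {
      rec_id <- rec_id + 1L
      truth <- simulate_gait(gcmd$step_length, gcmd$step_width, gcmd$cadence,
                             gcmd$duty_factor, gcmd$n_strides,
                             gcmd$start_foot, lead_in = gcmd$lead_in,
                             lead_out = gcmd$lead_out)
      streams <- corrupt_streams(
        truth, rig,
        joint_noise_sigma = cfg$corruption$joint_noise_sigma,
        lateral_bias = cfg$corruption$lateral_bias,
        occlusion = cfg$corruption$occlusion,
        occlusion_threshold = cfg$corruption$occlusion_threshold,
        timestamp_jitter = cfg$corruption$timestamp_jitter,
        rate_wobble = cfg$corruption$rate_wobble,
        seed = cfg$seed + 100L + rec_id)
      # streams are recorded in each sensor's local frame
      poses <- stats::setNames(truth_cal$pose, truth_cal$sensor_id)
      streams <- streams |>
        dplyr::group_by(.data$sensor_id) |>
        dplyr::group_modify(function(d, key) {
          # world -> origin-marker frame -> sensor local
          to_local <- rt_invert(poses[[as.character(key$sensor_id)]])
          transform_stream(transform_stream(d, inv_m1), to_local)
        }) |>
        dplyr::ungroup()
      rdir <- file.path(dir, sprintf("recording_%03d", rec_id))
      write_skeleton_streams(streams, file.path(rdir, "streams"))
      ref <- dplyr::filter(truth$trajectory,
                           .data$joint %in% c("AnkleLeft", "AnkleRight")) |>
        transform_stream(inv_m1)    # reference shares the global frame
      write_reference_trajectories(ref, file.path(rdir, "reference.tsv"),
                                   rate = cfg$dataset$reference_rate)
      gt_place <- truth$placements
      yaml::write_yaml(list(
        subject_id = as.character(s), recording_id = sprintf("%03d", rec_id),
        command = gcmd, walking_speed = truth$walking_speed,
        step_length_cm = gcmd$step_length * 100,
        step_width_cm = gcmd$step_width * 100,
        step_time_s = 60 / gcmd$cadence,
        n_placements = nrow(gt_place)),
        file.path(rdir, "ground_truth.yaml"), precision = 15)
    }
  }
  yaml::write_yaml(list(seed = cfg$seed, config_hash = rlang::hash(cfg),
                        n_recordings = rec_id,
                        package_version = as.character(utils::packageVersion("gaitrig"))),
                   file.path(dir, "manifest.yaml"))
  write_pipeline_config(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Analyse a reference-system trajectory with the identical procedure
#'
#' Resamples the (typically higher-rate) reference ankle trajectories onto
#' the pipeline grid, applies the same temporal filter, and runs the same
#' event detection and parameter extraction as for the fused skeleton.
#'
#' @param reference long trajectory tibble from
#'   [read_reference_trajectories()].
#' @param rate,filter_order,filter_cutoff,hysteresis,start_foot pipeline
#'   parameters (defaults as in [default_pipeline_config()]).
#' @return a `gait_parameters` object.
#' @export
analyze_reference <- function(reference, rate = 30, filter_order = 4,
                              filter_cutoff = 6, hysteresis = 0.02,
                              start_foot = "L") {
  gridded <- reference |>
    dplyr::mutate(sensor_id = "reference") |>
    fuse_streams(rate = rate)
  smoothed <- smooth_series(gridded, order = filter_order,
                            cutoff = filter_cutoff, rate = rate)
  analyze_gait(smoothed, hysteresis = hysteresis, start_foot = start_foot)
}

#' Run the full pipeline on a simulated dataset
#'
#' Calibrates the rig from the marker observations (optionally refining with
#' the point clouds), then for every recording fuses the skeleton streams for
#' each requested sensor subset, extracts gait parameters from the fused and
#' the reference trajectories, and computes agreement tables of system
#' versus reference per subset.
#'
#' @param dir dataset directory from [simulate_dataset()].
#' @param out_dir output directory (default `file.path(dir, "results")`).
#' @param config configuration; default read from the dataset.
#' @param subsets sensor subsets to reconstruct (default
#'   `c("left_only", "both")` — the one-sided versus two-sided comparison).
#' @param refine run ICP refinement on the point clouds (default TRUE).
#' @return list with `calibration`, `parameters` (long table, all systems),
#'   `agreement` (named list of `agreement_table`s), `log` (counts of
#'   exclusions and warnings).
#' @export
run_pipeline <- function(dir, out_dir = file.path(dir, "results"),
                         config = NULL, subsets = c("left_only", "both"),
                         refine = TRUE) {
  cfg <- config %||% read_pipeline_config(file.path(dir, "config.yaml"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(warnings = character())

  obs <- read_marker_observations(file.path(dir, "markers.tsv"))
  cal <- calibrate_rig(obs, marker_template(cfg$markers$template_side))
  if (refine) {
    cloud_files <- list.files(file.path(dir, "clouds"), pattern = "\\.xyz$",
                              full.names = TRUE)
    if (length(cloud_files)) {
      clouds <- stats::setNames(
        lapply(cloud_files, read_point_cloud),
        sub("^sensor_(.*)\\.xyz$", "\\1", basename(cloud_files)))
      cal <- withCallingHandlers(
        icp_refine(clouds, cal),
        warning = function(w) {
          log$warnings <<- c(log$warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
  }
  write_calibration(cal, file.path(out_dir, "calibration.yaml"))

  rec_dirs <- list.dirs(dir, recursive = FALSE)
  rec_dirs <- rec_dirs[grepl("recording_", basename(rec_dirs))]
  params <- list()
  for (rdir in rec_dirs) {
    gt <- yaml::read_yaml(file.path(rdir, "ground_truth.yaml"))
    streams <- read_skeleton_streams(file.path(rdir, "streams"))
    for (subset in subsets) {
      fused <- fuse_streams(streams, cal, subset = subset,
                            rate = cfg$fusion$rate, max_gap = cfg$fusion$max_gap)
      fused <- smooth_series(fused, order = cfg$fusion$filter_order,
                             cutoff = cfg$fusion$filter_cutoff,
                             rate = cfg$fusion$rate)
      gp <- analyze_gait(fused, hysteresis = cfg$analysis$hysteresis,
                         start_foot = cfg$analysis$start_foot)
      params[[length(params) + 1L]] <- gait_parameter_table(
        gp, gt$recording_id, system = "rig", sides_used = subset,
        subject_id = gt$subject_id)
    }
    ref <- read_reference_trajectories(file.path(rdir, "reference.tsv"))
    gpr <- analyze_reference(ref, rate = cfg$fusion$rate,
                             filter_order = cfg$fusion$filter_order,
                             filter_cutoff = cfg$fusion$filter_cutoff,
                             hysteresis = cfg$analysis$hysteresis,
                             start_foot = cfg$analysis$start_foot)
    params[[length(params) + 1L]] <- gait_parameter_table(
      gpr, gt$recording_id, system = "reference", sides_used = "reference",
      subject_id = gt$subject_id)
  }
  params <- dplyr::bind_rows(params)
  write_gait_parameters(params, file.path(out_dir, "gait_parameters.csv"))

  ref_tbl <- dplyr::filter(params, .data$system == "reference")
  agreement <- list()
  for (subset in subsets) {
    sys_tbl <- dplyr::filter(params, .data$system == "rig",
                             .data$sides_used == subset)
    at <- agreement_table(sys_tbl, ref_tbl, max_dt = cfg$stats$pair_max_dt)
    agreement[[subset]] <- at
    write_agreement_table(at, file.path(out_dir,
                                        paste0("agreement_", subset, ".csv")))
    writeLines(format_agreement_table(at),
               file.path(out_dir, paste0("agreement_", subset, ".txt")))
  }
  log$dropped_pairs <- vapply(agreement, function(a) attr(a, "dropped") %||% 0L,
                              integer(1))
  yaml::write_yaml(list(seed = cfg$seed, config_hash = rlang::hash(cfg),
                        n_recordings = length(rec_dirs),
                        warnings = log$warnings,
                        dropped_pairs = as.list(log$dropped_pairs)),
                   file.path(out_dir, "run_manifest.yaml"))
  invisible(list(calibration = cal, parameters = params,
                 agreement = agreement, log = log))
}
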
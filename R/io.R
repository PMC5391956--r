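# Plain-text file formats: marker observations (TSV), calibration (YAML with
# unit quaternions), point clouds (XYZ), skeleton streams (wide TSV + YAML
# sidecar), fused series (TSV), gait parameters and agreement tables (CSV).

#' Read and write marker-observation files
#'
#' Tab-separated, one row per observed corner: `sensor_id`, `marker_id`,
#' `corner`, `x`, `y`, `z` (meters, sensor frame).
#'
#' @param observations observation tibble.
#' @param path file path.
#' @return `read_marker_observations()` returns the tibble.
#' @export
write_marker_observations <- function(observations, path) {
  readr::write_tsv(observations, path)
  invisible(path)
}

#' @rdname write_marker_observations
#' @export
read_marker_observations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(sensor_id = readr::col_character()))
}

#' Read and write calibration files
#'
#' YAML carrying, per sensor, a unit quaternion (`w, x, y, z`), translation
#' (meters), chaining path, RMS corner residual and refinement flag, plus the
#' global-frame convention string.
#'
#' @param calibration a `rig_calibration`.
#' @param path file path.
#' @return `read_calibration()` returns a `rig_calibration` (without the
#'   graph attribute).
#' @export
write_calibration <- function(calibration, path) {
  doc <- list(
    frame_convention = paste("origin marker defines the frame: plane spans the",
                             "horizontal axes, first in-plane edge = X,",
                             "plane normal = Z up"),
    origin_marker = attr(calibration, "origin_marker"),
    sensors = purrr::pmap(
      calibration[, c("sensor_id", "transform", "path", "path_length", "rms",
                      "refined")],
      function(sensor_id, transform, path, path_length, rms, refined) {
        list(sensor_id = sensor_id,
             quaternion = as.list(rot_to_quat(transform$rotation)),
             translation = as.list(transform$translation),
             path = as.list(path), path_length = path_length,
             rms = rms, refined = refined)
      }))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- purrr::map_dfr(doc$sensors, function(s) {
    q <- as.numeric(unlist(s$quaternion))
    tibble::tibble(
      sensor_id = as.character(s$sensor_id),
      transform = list(rigid_transform(quat_to_rot(q),
                                       as.numeric(unlist(s$translation)))),
      path = list(as.character(unlist(s$path))),
      path_length = as.integer(s$path_length),
      rms = as.numeric(s$rms),
      refined = isTRUE(s$refined))
  })
  attr(out, "origin_marker") <- as.character(doc$origin_marker)
  class(out) <- c("rig_calibration", class(out))
  out
}

#' Read and write XYZ point-cloud files
#'
#' Whitespace-separated text, one `x y z` point per line, meters.
#'
#' @param cloud n x 3 matrix.
#' @param path file path.
#' @return `read_point_cloud()` returns an n x 3 matrix.
#' @export
write_point_cloud <- function(cloud, path) {
  utils::write.table(cloud, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(path) {
  as.matrix(utils::read.table(path, col.names = c("x", "y", "z")))
}

#' Read and write skeleton-stream files
#'
#' One tab-separated file per sensor: `timestamp_s`, `body_id`, then for each
#' of the 25 joints in canonical order four columns `<Joint>_x/_y/_z/_state`.
#' A YAML sidecar (`<file>.meta.yaml`) carries `sensor_id` and `side`.
#'
#' @param stream single-sensor long stream tibble.
#' @param path TSV path (sidecar written next to it).
#' @param sensor_id,side stream metadata; taken from the tibble when present.
#' @return `read_skeleton_stream()` returns the long stream tibble with
#'   `sensor_id` and `side` columns.
#' @export
write_skeleton_stream <- function(stream, path, sensor_id = NULL, side = NULL) {
  stream <- tibble::as_tibble(stream)
  sensor_id <- sensor_id %||% unique(stream$sensor_id)[1]
  side <- side %||% if ("side" %in% names(stream)) unique(stream$side)[1] else NA
  body_id <- if ("body_id" %in% names(stream)) stream$body_id[1] else 1L
  wide <- stream |>
    dplyr::select("time", "joint", "x", "y", "z", "state") |>
    tidyr::pivot_wider(names_from = "joint",
                       values_from = c("x", "y", "z", "state"),
                       names_glue = "{joint}_{.value}")
  cols <- c("timestamp_s", "body_id",
            as.vector(t(outer(kinect_joints(), c("_x", "_y", "_z", "_state"),
                              paste0))))
  wide <- dplyr::mutate(wide, timestamp_s = .data$time, body_id = body_id)
  readr::write_tsv(wide[, cols], path)
  yaml::write_yaml(list(sensor_id = as.character(sensor_id),
                        side = as.character(side)),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_skeleton_stream
#' @export
read_skeleton_stream <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  long <- wide |>
    tidyr::pivot_longer(-c("timestamp_s", "body_id"),
                        names_to = c("joint", ".value"),
                        names_pattern = "^(.*)_([xyz]|state)$") |>
    dplyr::transmute(sensor_id = meta$sensor_id, side = meta$side,
                     time = .data$timestamp_s, body_id = .data$body_id,
                     joint = .data$joint, x = .data$x, y = .data$y,
                     z = .data$z, state = .data$state)
  long
}

#' Write / read all streams of a recording
#'
#' @param streams multi-sensor stream tibble.
#' @param dir directory; one `sensor_<id>.tsv` (+ sidecar) per sensor.
#' @return `read_skeleton_streams()` binds all sensors into one tibble.
#' @export
write_skeleton_streams <- function(streams, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in unique(streams$sensor_id)) {
    write_skeleton_stream(dplyr::filter(streams, .data$sensor_id == id),
                          file.path(dir, paste0("sensor_", id, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_skeleton_streams
#' @export
read_skeleton_streams <- function(dir) {
  files <- list.files(dir, pattern = "^sensor_.*\\.tsv$", full.names = TRUE)
  purrr::map_dfr(files, read_skeleton_stream)
}

#' Read and write fused-series files
#'
#' Tab-separated gridded series: `time`, `joint`, `x`, `y`, `z`, `valid`,
#' `n_sensors`.
#'
#' @param series a `fused_series`.
#' @param path file path.
#' @return `read_fused_series()` returns a `fused_series` tibble.
#' @export
write_fused_series <- function(series, path) {
  readr::write_tsv(tibble::as_tibble(series), path)
  invisible(path)
}

#' @rdname write_fused_series
#' @export
read_fused_series <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  class(out) <- c("fused_series", class(out))
  out
}

#' Write a reference-system trajectory file
#'
#' Generic labeled-trajectory TSV for reference (marker-based) data:
#' `time` plus `<Name>_x/_y/_z` columns, meters.
#'
#' @param trajectory long tibble `time`, `joint`, `x`, `y`, `z` (e.g. the
#'   ground-truth trajectory restricted to ankle markers).
#' @param path file path.
#' @param rate optional resampling rate, Hz (e.g. 120 for an optical system);
#'   `NULL` keeps the native sampling.
#' @return `read_reference_trajectories()` returns the long tibble with a
#'   `state` column (always `"tracked"`).
#' @export
write_reference_trajectories <- function(trajectory, path, rate = NULL) {
  traj <- tibble::as_tibble(trajectory)
  if (!is.null(rate)) {
    grid <- seq(min(traj$time), max(traj$time), by = 1 / rate)
    traj <- traj |>
      dplyr::group_by(.data$joint) |>
      dplyr::group_modify(~ tibble::tibble(
        time = grid,
        x = stats::approx(.x$time, .x$x, grid)$y,
        y = stats::approx(.x$time, .x$y, grid)$y,
        z = stats::approx(.x$time, .x$z, grid)$y)) |>
      dplyr::ungroup()
  }
  wide <- tidyr::pivot_wider(traj, id_cols = "time", names_from = "joint",
                             values_from = c("x", "y", "z"),
                             names_glue = "{joint}_{.value}")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_reference_trajectories
#' @export
read_reference_trajectories <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  wide |>
    tidyr::pivot_longer(-"time", names_to = c("joint", ".value"),
                        names_pattern = "^(.*)_([xyz])$") |>
    dplyr::mutate(state = "tracked")
}

#' Read and write gait-parameter tables
#'
#' CSV in the long exchange schema (`subject_id`, `recording_id`, `system`,
#' `sides_used`, `foot`, `parameter`, `value`, `time`). `read_gait_parameters()`
#' can ingest foreign files via `mapping`, a named character vector from
#' schema names to the file's column names (unmapped key columns are filled
#' with `NA`).
#'
#' @param params long gait-parameter tibble.
#' @param path file path.
#' @param mapping optional named character vector, e.g.
#'   `c(value = "measurement", parameter = "variable")`.
#' @return `read_gait_parameters()` returns the tibble in the package schema.
#' @export
write_gait_parameters <- function(params, path) {
  readr::write_csv(params, path)
  invisible(path)
}

#' @rdname write_gait_parameters
#' @export
read_gait_parameters <- function(path, mapping = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  schema <- c("subject_id", "recording_id", "system", "sides_used", "foot",
              "parameter", "value", "time")
  if (!is.null(mapping)) {
    for (k in names(mapping)) {
      if (!mapping[[k]] %in% names(raw)) {
        stop("mapped column '", mapping[[k]], "' not found in ", path,
             call. = FALSE)
      }
      raw[[k]] <- raw[[mapping[[k]]]]
    }
  }
  for (k in schema) if (!k %in% names(raw)) raw[[k]] <- NA
  out <- raw[, schema]
  out$subject_id <- as.character(out$subject_id)
  out$recording_id <- as.character(out$recording_id)
  out$value <- as.numeric(out$value)
  out$time <- as.numeric(out$time)
  out
}

#' Write an agreement table (CSV) and Bland-Altman plot data
#'
#' @param table an `agreement_table`.
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
write_agreement_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

#' Bland-Altman plot data for one paired set
#'
#' Mean-versus-difference pairs plus the bias and limits-of-agreement lines,
#' ready for CSV export or [plot_bland_altman()].
#'
#' @param a,b paired numeric vectors.
#' @return list with `points` (tibble `mean`, `diff`) and `lines` (tibble
#'   `name`, `value`: bias, bias +/- RPC).
#' @export
bland_altman_plot_data <- function(a, b) {
  ba <- bland_altman(a, b)
  list(points = tibble::tibble(mean = (a + b) / 2, diff = a - b),
       lines = tibble::tibble(name = c("bias", "upper", "lower"),
                              value = c(ba$bias, ba$bias + ba$rpc,
                                        ba$bias - ba$rpc)))
}
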
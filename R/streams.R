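#' The 25 skeleton joints, in canonical sensor-SDK order
#'
#' Every skeleton frame carries exactly these joints in this order; stream
#' files name their columns after them.
#'
#' @return character vector of 25 joint names.
#' @export
kinect_joints <- function() {
  c("SpineBase", "SpineMid", "Neck", "Head",
    "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
    "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
    "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
    "HipRight", "KneeRight", "AnkleRight", "FootRight",
    "SpineShoulder", "HandTipLeft", "ThumbLeft",
    "HandTipRight", "ThumbRight")
}

#' Validate a skeleton stream tibble
#'
#' A stream is a long tibble with columns `time` (s), `joint` (one of
#' [kinect_joints()]), `x`, `y`, `z` (m) and `state` (`"tracked"`,
#' `"inferred"` or `"untracked"`), optionally `sensor_id`, `side` and
#' `body_id`. Timestamps must be strictly increasing within each sensor.
#'
#' @param stream tibble to validate.
#' @return the stream, invisibly; errors describe the violation.
#' @export
validate_stream <- function(stream) {
  stream <- tibble::as_tibble(stream)
  need <- c("time", "joint", "x", "y", "z", "state")
  missing <- setdiff(need, names(stream))
  if (length(missing)) {
    stop("stream is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(stream$joint), kinect_joints())
  if (length(bad)) stop("unknown joints: ", paste(bad, collapse = ", "), call. = FALSE)
  bad_state <- setdiff(unique(stream$state), c("tracked", "inferred", "untracked"))
  if (length(bad_state)) {
    stop("unknown tracking states: ", paste(bad_state, collapse = ", "),
         call. = FALSE)
  }
  grp <- if ("sensor_id" %in% names(stream)) "sensor_id" else character(0)
  ts <- stream |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c(grp, "time")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(ok = !is.unsorted(.data$time, strictly = TRUE), .groups = "drop")
  if (!all(ts$ok)) stop("timestamps must be strictly increasing within a stream",
                        call. = FALSE)
  invisible(stream)
}

#' Map a skeleton stream into another coordinate frame
#'
#' Applies a rigid transform to every joint position; timestamps and tracking
#' states are untouched. With a calibration, each sensor's rows are mapped by
#' that sensor's pose, taking all streams into the shared global frame.
#'
#' @param stream skeleton stream tibble (see [validate_stream()]).
#' @param pose a [rigid_transform] (sensor-local to global).
#' @return the stream with transformed `x`, `y`, `z`.
#' @export
transform_stream <- function(stream, pose) {
  stopifnot(inherits(pose, "rigid_transform"))
  stream <- tibble::as_tibble(stream)
  p <- rt_apply(pose, as.matrix(stream[, c("x", "y", "z")]))
  stream$x <- p[, 1]; stream$y <- p[, 2]; stream$z <- p[, 3]
  stream
}

#' @rdname transform_stream
#' @param streams multi-sensor stream tibble with a `sensor_id` column.
#' @param calibration a `rig_calibration` supplying one pose per sensor.
#' @export
transform_streams <- function(streams, calibration) {
  stopifnot(inherits(calibration, "rig_calibration"))
  streams <- tibble::as_tibble(streams)
  poses <- stats::setNames(calibration$transform, calibration$sensor_id)
  streams |>
    dplyr::group_by(.data$sensor_id) |>
    dplyr::group_modify(function(d, key) {
      pose <- poses[[as.character(key$sensor_id)]]
      if (is.null(pose)) stop("no calibrated pose for sensor ", key$sensor_id,
                              call. = FALSE)
      transform_stream(d, pose)
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("sensor_id")
}
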
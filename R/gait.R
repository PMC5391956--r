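# Spatiotemporal gait parameters from ankle trajectories.
#
# Foot placements are not measured directly: the moments when one foot passes
# the other in walking direction (crossings of the two ankle trajectories)
# are sharp, easily detected events, and at each crossing the stance ankle's
# forward position is a plateau equal to where that foot was placed. Steps,
# strides, widths, times and walking speed all derive from the resulting
# placement sequence, identically for fused-skeleton and reference data.

#' Extract the two ankle trajectories from a fused series
#'
#' @param series a `fused_series` (or any tibble with `time`, `joint`, `x`,
#'   `y`, `z`, `valid`).
#' @param left_joint,right_joint joint names (defaults `"AnkleLeft"`,
#'   `"AnkleRight"`).
#' @return wide tibble: `time`, `lx, ly, lz`, `rx, ry, rz`, `valid` (both
#'   ankles valid).
#' @export
ankle_trajectories <- function(series, left_joint = "AnkleLeft",
                               right_joint = "AnkleRight") {
  series <- tibble::as_tibble(series)
  if (!"valid" %in% names(series)) series$valid <- TRUE
  l <- dplyr::filter(series, .data$joint == left_joint)
  r <- dplyr::filter(series, .data$joint == right_joint)
  dplyr::inner_join(
    dplyr::select(l, "time", lx = "x", ly = "y", lz = "z", lvalid = "valid"),
    dplyr::select(r, "time", rx = "x", ry = "y", rz = "z", rvalid = "valid"),
    by = "time") |>
    dplyr::mutate(valid = .data$lvalid & .data$rvalid) |>
    dplyr::select(-"lvalid", -"rvalid") |>
    dplyr::arrange(.data$time)
}

#' Estimate the walking frame from ankle trajectories
#'
#' The forward axis is the unit horizontal direction of the net displacement
#' of the mid-ankle trajectory; the lateral axis is `vertical x forward`.
#' Requires more than `min_displacement` of net horizontal travel.
#'
#' @param ankles wide ankle tibble from [ankle_trajectories()].
#' @param vertical unit up vector (default `c(0, 0, 1)`).
#' @param min_displacement minimum net horizontal displacement, m (default 1).
#' @return list with unit 3-vectors `forward`, `lateral`, `vertical` and the
#'   3-point `origin` (first valid mid-ankle position).
#' @export
estimate_axes <- function(ankles, vertical = c(0, 0, 1), min_displacement = 1) {
  a <- dplyr::filter(tibble::as_tibble(ankles), .data$valid)
  if (nrow(a) < 2) stop("not enough valid samples to estimate axes", call. = FALSE)
  vertical <- vertical / sqrt(sum(vertical^2))
  mid <- cbind((a$lx + a$rx) / 2, (a$ly + a$ry) / 2, (a$lz + a$rz) / 2)
  disp <- mid[nrow(mid), ] - mid[1, ]
  disp <- disp - sum(disp * vertical) * vertical
  norm <- sqrt(sum(disp^2))
  if (norm <= min_displacement) {
    stop("net horizontal displacement (", round(norm, 3),
         " m) is below ", min_displacement, " m; walking direction undefined",
         call. = FALSE)
  }
  forward <- disp / norm
  lateral <- c(vertical[2] * forward[3] - vertical[3] * forward[2],
               vertical[3] * forward[1] - vertical[1] * forward[3],
               vertical[1] * forward[2] - vertical[2] * forward[1])
  list(forward = forward, lateral = lateral, vertical = vertical,
       origin = mid[1, ])
}

# project ankle positions onto the walking frame; adds lf/rf (forward, m)
# and ll/rl (lateral, m)
project_ankles <- function(ankles, axes) {
  a <- tibble::as_tibble(ankles)
  o <- axes$origin
  a$lf <- (a$lx - o[1]) * axes$forward[1] + (a$ly - o[2]) * axes$forward[2] +
    (a$lz - o[3]) * axes$forward[3]
  a$rf <- (a$rx - o[1]) * axes$forward[1] + (a$ry - o[2]) * axes$forward[2] +
    (a$rz - o[3]) * axes$forward[3]
  a$ll <- (a$lx - o[1]) * axes$lateral[1] + (a$ly - o[2]) * axes$lateral[2] +
    (a$lz - o[3]) * axes$lateral[3]
  a$rl <- (a$rx - o[1]) * axes$lateral[1] + (a$ry - o[2]) * axes$lateral[2] +
    (a$rz - o[3]) * axes$lateral[3]
  a
}

#' Detect ankle-crossing foot events
#'
#' Events are the zero crossings of `d(t) = left_forward - right_forward`,
#' with sub-sample times by linear interpolation. A crossing is accepted only
#' if `|d|` has exceeded `hysteresis` since the previous accepted event, which
#' suppresses chatter from noise around zero. The passing foot is the one with
#' the larger forward speed (central differences) at the event; the other foot
#' is in stance.
#'
#' @param time grid times, seconds.
#' @param left_fwd,right_fwd forward ankle positions on that grid, meters.
#' @param hysteresis arming threshold, meters (default 0.02).
#' @return tibble: `time`, `passing_foot`, `stance_foot`, `slope` (|d'| at the
#'   event, m/s), `index` (grid sample left of the crossing).
#' @export
detect_crossings <- function(time, left_fwd, right_fwd, hysteresis = 0.02) {
  ok <- is.finite(left_fwd) & is.finite(right_fwd)
  time <- time[ok]; lf <- left_fwd[ok]; rf <- right_fwd[ok]
  if (length(time) < 3) stop("no valid overlap between the ankle trajectories",
                             call. = FALSE)
  d <- lf - rf
  s <- sign(d)
  # carry the previous sign through exact zeros so a touch does not double-count
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  flips <- which(s[-1] != s[-length(s)] & s[-1] != 0 & s[-length(s)] != 0)

  lv <- central_diff(lf, time)
  rv <- central_diff(rf, time)

  events <- list()
  last <- 0L   # sample index of the last accepted event
  for (i in flips) {
    armed <- max(abs(d[(last + 1L):i])) > hysteresis
    if (!armed && hysteresis > 0) next
    w <- d[i] / (d[i] - d[i + 1L])
    t_ev <- time[i] + w * (time[i + 1L] - time[i])
    lv_ev <- (1 - w) * lv[i] + w * lv[i + 1L]
    rv_ev <- (1 - w) * rv[i] + w * rv[i + 1L]
    passing <- if (abs(lv_ev) >= abs(rv_ev)) "L" else "R"
    events[[length(events) + 1L]] <- tibble::tibble(
      time = t_ev,
      passing_foot = passing,
      stance_foot = if (passing == "L") "R" else "L",
      slope = abs(lv_ev - rv_ev),
      index = i
    )
    last <- i
  }
  if (!length(events)) {
    return(tibble::tibble(time = numeric(), passing_foot = character(),
                          stance_foot = character(), slope = numeric(),
                          index = integer()))
  }
  dplyr::bind_rows(events)
}

central_diff <- function(x, t) {
  n <- length(x)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  v[1] <- (x[2] - x[1]) / (t[2] - t[1])
  v[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  v
}

#' Read foot placements off the crossing events
#'
#' At every crossing the stance ankle sits on its stance plateau, so its
#' projected position *is* the foot's placement. Consecutive placements must
#' alternate feet; when two consecutive events share a stance foot (a
#' data-quality symptom), the weaker event — the one whose trajectories cross
#' with the smaller |slope| — is dropped and the result is flagged.
#'
#' @param events tibble from [detect_crossings()].
#' @param ankles wide ankle tibble.
#' @param axes walking frame from [estimate_axes()].
#' @return tibble: `foot`, `time`, `forward_pos`, `lateral_pos` (meters),
#'   `flagged`.
#' @export
extract_placements <- function(events, ankles, axes) {
  if (nrow(events) < 2) stop("need at least 2 foot events", call. = FALSE)
  if (length(unique(events$stance_foot)) < 2) {
    stop("all events have the same stance foot; cannot form placements",
         call. = FALSE)
  }
  a <- project_ankles(dplyr::filter(tibble::as_tibble(ankles), .data$valid), axes)
  ev <- events[order(events$time), ]
  flagged <- FALSE
  repeat {
    rep_idx <- which(ev$stance_foot[-1] == ev$stance_foot[-nrow(ev)])
    if (!length(rep_idx)) break
    i <- rep_idx[1]
    drop <- if (ev$slope[i] <= ev$slope[i + 1]) i else i + 1L
    ev <- ev[-drop, ]
    flagged <- TRUE
  }
  interp <- function(v, t) stats::approx(a$time, v, xout = t, rule = 2)$y
  tibble::tibble(
    foot = ev$stance_foot,
    time = ev$time,
    forward_pos = ifelse(ev$stance_foot == "L",
                         interp(a$lf, ev$time), interp(a$rf, ev$time)),
    lateral_pos = ifelse(ev$stance_foot == "L",
                         interp(a$ll, ev$time), interp(a$rl, ev$time)),
    flagged = flagged
  )
}

#' Compute step, stride and summary gait parameters from placements
#'
#' For consecutive placements `p[k-1], p[k]` the step belongs to the foot of
#' `p[k]` (the foot last placed): step length = forward advance (cm), step
#' width = absolute lateral separation (cm), step time = elapsed time (s).
#' Stride length for a foot is the forward distance between its consecutive
#' placements (cm). Because the first step after gait initiation is atypical,
#' the first step of `start_foot` and the first stride of the opposite foot
#' are excluded from all outputs. Walking speed is the sum of included step
#' lengths over the sum of included step times (cm/s).
#'
#' @param placements tibble from [extract_placements()].
#' @param start_foot which foot started the walk, `"L"` (default) or `"R"`.
#' @return A `gait_parameters` object: list with tibbles `steps` (`foot`,
#'   `step_length`, `step_width`, `step_time`, `time`), `strides` (`foot`,
#'   `stride_length`, `time`) and one-row `summary`.
#' @export
compute_parameters <- function(placements, start_foot = c("L", "R")) {
  start_foot <- match.arg(start_foot)
  p <- tibble::as_tibble(placements)
  p <- p[order(p$time), ]
  if (nrow(p) < 3) stop("need at least 3 placements", call. = FALSE)
  if (any(p$foot[-1] == p$foot[-nrow(p)])) {
    stop("placements do not alternate feet", call. = FALSE)
  }
  other <- if (start_foot == "L") "R" else "L"

  k <- 2:nrow(p)
  steps <- tibble::tibble(
    foot = p$foot[k],
    step_length = (p$forward_pos[k] - p$forward_pos[k - 1]) * 100,
    step_width = abs(p$lateral_pos[k] - p$lateral_pos[k - 1]) * 100,
    step_time = p$time[k] - p$time[k - 1],
    time = p$time[k]
  )
  strides <- p |>
    dplyr::group_by(.data$foot) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) return(tibble::tibble(stride_length = numeric(),
                                             time = numeric()))
      j <- 2:nrow(d)
      tibble::tibble(stride_length = (d$forward_pos[j] - d$forward_pos[j - 1]) * 100,
                     time = d$time[j])
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("foot")

  # gait-initiation exclusions: first step of the starting foot, first stride
  # of the opposite foot
  first_step <- which(steps$foot == start_foot)[1]
  if (!is.na(first_step)) steps <- steps[-first_step, ]
  first_stride <- which(strides$foot == other)[1]
  if (!is.na(first_stride)) strides <- strides[-first_stride, ]
  if (!nrow(steps)) stop("no steps remain after exclusions", call. = FALSE)

  summary <- tibble::tibble(
    walking_speed = sum(steps$step_length) / sum(steps$step_time),
    n_steps = nrow(steps),
    n_strides = nrow(strides),
    step_length_mean = mean(steps$step_length),
    step_width_mean = mean(steps$step_width),
    step_time_mean = mean(steps$step_time),
    stride_length_mean = if (nrow(strides)) mean(strides$stride_length) else NA_real_,
    flagged = any(placements$flagged)
  )
  structure(list(steps = steps, strides = strides, summary = summary,
                 start_foot = start_foot),
            class = "gait_parameters")
}

#' @export
print.gait_parameters <- function(x, ...) {
  cat("<gait_parameters> ", nrow(x$steps), " steps, ", nrow(x$strides),
      " strides, walking speed ", round(x$summary$walking_speed, 2),
      " cm/s\n", sep = "")
  invisible(x)
}

#' Tidy gait parameters into the long one-row-per-measure form
#'
#' @param x a `gait_parameters` object.
#' @param ... unused.
#' @return tibble with columns `foot`, `parameter`, `value`, `time`; units are
#'   cm for lengths/widths and s for times.
#' @export
tidy.gait_parameters <- function(x, ...) {
  dplyr::bind_rows(
    x$steps |>
      tidyr::pivot_longer(c("step_length", "step_width", "step_time"),
                          names_to = "parameter", values_to = "value") |>
      dplyr::select("foot", "parameter", "value", "time"),
    x$strides |>
      dplyr::mutate(parameter = "stride_length") |>
      dplyr::select("foot", "parameter", value = "stride_length", "time")
  )
}

#' @rdname tidy.gait_parameters
#' @export
glance.gait_parameters <- function(x, ...) x$summary

#' End-to-end gait analysis of one recording
#'
#' Extracts ankle trajectories, estimates the walking frame, detects
#' crossings, reads placements and computes all parameters.
#'
#' @param series a `fused_series` (or an ankle tibble from
#'   [ankle_trajectories()]).
#' @param hysteresis crossing hysteresis, meters (default 0.02).
#' @param start_foot starting foot (default `"L"`).
#' @param vertical up direction (default `c(0, 0, 1)`).
#' @return A `gait_parameters` object with `events`, `placements` and `axes`
#'   attached.
#' @examples
#' truth <- simulate_gait(n_strides = 6, seed = 1)
#' gp <- analyze_gait(truth$trajectory)
#' glance(gp)
#' @export
analyze_gait <- function(series, hysteresis = 0.02, start_foot = "L",
                         vertical = c(0, 0, 1)) {
  ankles <- if (all(c("lx", "rx") %in% names(series))) {
    tibble::as_tibble(series)
  } else {
    ankle_trajectories(series)
  }
  axes <- estimate_axes(ankles, vertical = vertical)
  a <- project_ankles(dplyr::filter(ankles, .data$valid), axes)
  events <- detect_crossings(a$time, a$lf, a$rf, hysteresis = hysteresis)
  placements <- extract_placements(events, ankles, axes)
  gp <- compute_parameters(placements, start_foot = start_foot)
  gp$events <- events
  gp$placements <- placements
  gp$axes <- axes
  gp
}

#' Long gait-parameter table for one analysed recording
#'
#' The exchange format between the gait and agreement modules: one row per
#' step/stride measure plus one `walking_speed` row, keyed by recording,
#' system and sensor subset.
#'
#' @param gp a `gait_parameters` object.
#' @param recording_id,system,sides_used key columns
#'   (`sides_used` is `"both"`, `"left_only"` or `"reference"`).
#' @param subject_id optional subject key.
#' @return tibble: `subject_id`, `recording_id`, `system`, `sides_used`,
#'   `foot`, `parameter`, `value`, `time`.
#' @export
gait_parameter_table <- function(gp, recording_id, system,
                                 sides_used = "both", subject_id = NA_character_) {
  stopifnot(inherits(gp, "gait_parameters"))
  dplyr::bind_rows(
    tidy(gp),
    tibble::tibble(foot = NA_character_, parameter = "walking_speed",
                   value = gp$summary$walking_speed, time = NA_real_)
  ) |>
    dplyr::mutate(subject_id = as.character(subject_id),
                  recording_id = as.character(recording_id),
                  system = system, sides_used = sides_used,
                  .before = 1)
}
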
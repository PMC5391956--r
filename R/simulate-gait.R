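# Parameterised straight-walk generator with exact ground truth.
#
# Each ankle's forward position is piecewise: exactly constant during stance
# and a raised-cosine advance of one stride length during swing (C1 at the
# stance boundaries). Feet alternate with the commanded cadence; the duty
# factor (> 0.5) sets the double-support fraction. Every commanded quantity —
# step length, width, time, the crossing times, the placement positions — is
# therefore known in closed form and emitted alongside the trajectories.

raised_cosine <- function(u) {
  u <- pmin(1, pmax(0, u))
  (1 - cos(pi * u)) / 2
}

#' Simulate a straight walk with known gait parameters
#'
#' Generates 25-joint stick-figure trajectories for a walker: the ankles
#' follow the stance-plateau / raised-cosine-swing profile, the remaining
#' joints are kinematically slaved to them (pelvis midway between the feet,
#' trunk and arms at fixed offsets). With `start_foot = "L"` the left foot
#' swings first from a mid-gait posture (left one step length behind), so the
#' first ankle crossing has the right foot in stance.
#'
#' @param step_length commanded step length, m (default 0.73).
#' @param step_width commanded lateral foot separation, m (default 0.12).
#' @param cadence steps per minute (default 100; step time = 60/cadence s).
#' @param duty_factor stance fraction of the gait cycle, in (0.5, 1)
#'   (default 0.6; at or below 0.5 there is no double support).
#' @param n_strides number of full strides (default 8; 2 crossings each).
#' @param start_foot foot that swings first (default `"L"`).
#' @param origin world position of the right foot's initial placement
#'   (default `c(0, 0, 0)`).
#' @param heading walking direction, radians about +z from +x (default 0).
#' @param lead_in,lead_out standing time before/after the walk, s
#'   (default 0.5 each).
#' @param rate sampling rate of the emitted ground-truth trajectory, Hz
#'   (default 240; dense enough that linear resampling error is microns).
#' @param seed accepted for interface symmetry; the generator is
#'   deterministic given the command.
#' @return A `gait_truth` list: `trajectory` (tibble `time`, `joint`, `x`,
#'   `y`, `z`, `state`), `placements` (ground-truth crossing-detected
#'   placements), `events` (crossing times and stance feet), `steps`
#'   (ground-truth per-step parameters, cm/s units), `command`,
#'   `walking_speed` (cm/s), `duration` (s).
#' @export
simulate_gait <- function(step_length = 0.73, step_width = 0.12, cadence = 100,
                          duty_factor = 0.6, n_strides = 8,
                          start_foot = c("L", "R"), origin = c(0, 0, 0),
                          heading = 0, lead_in = 0.5, lead_out = 0.5,
                          rate = 240, seed = NULL) {
  start_foot <- match.arg(start_foot)
  stopifnot(step_length > 0, step_width > 0, cadence > 0, n_strides >= 1)
  if (duty_factor <= 0.5 || duty_factor >= 1) {
    stop("duty_factor must be in (0.5, 1): at or below 0.5 the gait has no ",
         "double support", call. = FALSE)
  }
  step_time <- 60 / cadence
  cycle <- 2 * step_time
  swing <- (1 - duty_factor) * cycle
  n_swings <- 2L * n_strides
  duration <- lead_in + (n_swings - 1) * step_time + swing + lead_out
  t <- seq(0, duration, by = 1 / rate)

  feet <- if (start_foot == "L") c("L", "R") else c("R", "L")
  swing_foot <- rep(feet, length.out = n_swings)
  swing_start <- lead_in + (seq_len(n_swings) - 1) * step_time

  fwd0 <- c(L = if (start_foot == "L") -step_length else 0,
            R = if (start_foot == "L") 0 else -step_length)
  ankle_height <- 0.08; clearance <- 0.05
  foot_fwd <- function(foot) {
    f <- rep(fwd0[[foot]], length(t))
    for (i in which(swing_foot == foot)) {
      f <- f + 2 * step_length * raised_cosine((t - swing_start[i]) / swing)
    }
    f
  }
  foot_lift <- function(foot) {
    z <- rep(ankle_height, length(t))
    for (i in which(swing_foot == foot)) {
      u <- (t - swing_start[i]) / swing
      inswing <- u > 0 & u < 1
      z[inswing] <- z[inswing] + clearance * sin(pi * u[inswing])
    }
    z
  }
  lat <- c(L = step_width / 2, R = -step_width / 2)
  lf <- foot_fwd("L"); rf <- foot_fwd("R")
  lz <- foot_lift("L"); rz <- foot_lift("R")
  pelvis_f <- (lf + rf) / 2

  # slaved stick figure: forward/lateral/height per joint
  joint_def <- function(joint) {
    switch(joint,
      AnkleLeft   = cbind(lf, lat[["L"]], lz),
      AnkleRight  = cbind(rf, lat[["R"]], rz),
      FootLeft    = cbind(lf + 0.15, lat[["L"]], lz - 0.04),
      FootRight   = cbind(rf + 0.15, lat[["R"]], rz - 0.04),
      KneeLeft    = cbind((lf + pelvis_f) / 2, lat[["L"]], (lz + 0.92) / 2),
      KneeRight   = cbind((rf + pelvis_f) / 2, lat[["R"]], (rz + 0.92) / 2),
      HipLeft     = cbind(pelvis_f, 0.10, 0.92),
      HipRight    = cbind(pelvis_f, -0.10, 0.92),
      SpineBase   = cbind(pelvis_f, 0, 0.95),
      SpineMid    = cbind(pelvis_f, 0, 1.15),
      SpineShoulder = cbind(pelvis_f, 0, 1.38),
      Neck        = cbind(pelvis_f, 0, 1.45),
      Head        = cbind(pelvis_f, 0, 1.62),
      ShoulderLeft  = cbind(pelvis_f, 0.19, 1.38),
      ShoulderRight = cbind(pelvis_f, -0.19, 1.38),
      ElbowLeft   = cbind(pelvis_f, 0.22, 1.10),
      ElbowRight  = cbind(pelvis_f, -0.22, 1.10),
      WristLeft   = cbind(pelvis_f, 0.23, 0.86),
      WristRight  = cbind(pelvis_f, -0.23, 0.86),
      HandLeft    = cbind(pelvis_f, 0.23, 0.78),
      HandRight   = cbind(pelvis_f, -0.23, 0.78),
      HandTipLeft = cbind(pelvis_f, 0.23, 0.72),
      HandTipRight = cbind(pelvis_f, -0.23, 0.72),
      ThumbLeft   = cbind(pelvis_f, 0.20, 0.76),
      ThumbRight  = cbind(pelvis_f, -0.20, 0.76)
    )
  }
  frame <- rigid_transform(axis_rotation("z", heading), origin)
  traj <- purrr::map_dfr(kinect_joints(), function(j) {
    p <- joint_def(j)          # cbind recycles scalar lateral/height columns
    pw <- rt_apply(frame, p)
    tibble::tibble(time = t, joint = j, x = pw[, 1], y = pw[, 2], z = pw[, 3],
                   state = "tracked")
  })

  # ground truth: crossing i happens at the midpoint of swing i (the swinging
  # foot passes the stance plateau exactly halfway through its raised cosine)
  stance_foot <- ifelse(swing_foot == "L", "R", "L")
  ev_time <- swing_start + swing / 2
  place_fwd <- (seq_len(n_swings) - 1) * step_length
  place_world <- rt_apply(frame, cbind(place_fwd,
                                       unname(lat[stance_foot]),
                                       0))
  events <- tibble::tibble(time = ev_time, passing_foot = swing_foot,
                           stance_foot = stance_foot)
  placements <- tibble::tibble(foot = stance_foot, time = ev_time,
                               forward_pos = place_fwd,
                               lateral_pos = unname(lat[stance_foot]),
                               x = place_world[, 1], y = place_world[, 2])
  k <- 2:n_swings
  steps <- tibble::tibble(
    foot = stance_foot[k],
    step_length = rep(step_length * 100, length(k)),
    step_width = rep(step_width * 100, length(k)),
    step_time = rep(step_time, length(k)),
    time = ev_time[k])

  structure(list(
    trajectory = traj, placements = placements, events = events, steps = steps,
    command = list(step_length = step_length, step_width = step_width,
                   cadence = cadence, duty_factor = duty_factor,
                   n_strides = n_strides, start_foot = start_foot,
                   heading = heading, origin = origin),
    walking_speed = 100 * step_length / step_time,
    duration = duration), class = "gait_truth")
}

#' @export
print.gait_truth <- function(x, ...) {
  cat("<gait_truth> ", x$command$n_strides, " strides, step ",
      x$command$step_length * 100, " cm x ", x$command$step_width * 100,
      " cm, cadence ", x$command$cadence, " steps/min, speed ",
      round(x$walking_speed, 2), " cm/s\n", sep = "")
  invisible(x)
}

# minimum distance between 3D segments p1-q1 and p2-q2 (Eberly's clamped
# quadratic)
seg_seg_dist <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-12 && e <= 1e-12) return(sqrt(sum(r * r)))
  if (a <= 1e-12) {
    s <- 0; tt <- min(1, max(0, f / e))
  } else {
    c1 <- sum(d1 * r)
    if (e <= 1e-12) {
      tt <- 0; s <- min(1, max(0, -c1 / a))
    } else {
      b <- sum(d1 * d2); denom <- a * e - b * b
      s <- if (denom > 1e-12) min(1, max(0, (b * f - c1 * e) / denom)) else 0
      tt <- (b * s + f) / e
      if (tt < 0) { tt <- 0; s <- min(1, max(0, -c1 / a)) }
      else if (tt > 1) { tt <- 1; s <- min(1, max(0, (b - c1) / a)) }
    }
  }
  v <- (p1 + s * d1) - (p2 + tt * d2)
  sqrt(sum(v * v))
}

#' Corrupt ground-truth trajectories into per-sensor skeleton streams
#'
#' Emulates what each depth sensor in the rig would report: frames sampled at
#' its own jittered clock, isotropic joint noise, a lateral "surface pull"
#' bias of magnitude `lateral_bias` along the cross-walk axis toward the
#' sensor's side (each sensor sees only the near surface of a limb, so its
#' joint estimates sit closer to it; for flanking sensors that displacement
#' is lateral, so left- and right-placed sensors inject exactly opposite
#' biases), frustum culling, and self-occlusion
#' dropout: a far-leg joint whose line of sight passes within
#' `occlusion_threshold` of the near-leg hip-ankle segment is reported
#' untracked. Left-placed sensors therefore only ever drop right-leg joints
#' and vice versa.
#'
#' @param truth a `gait_truth`.
#' @param rig a `sensor_rig` (poses in the same world frame as the truth).
#' @param joint_noise_sigma isotropic joint noise sd, m (default 0).
#' @param lateral_bias surface-pull magnitude, m (default 0).
#' @param occlusion enable self-occlusion dropout (default TRUE).
#' @param occlusion_threshold line-of-sight clearance, m (default 0.08).
#' @param timestamp_jitter clock jitter half-range, s (default 0.002).
#' @param rate_wobble half-range of per-frame rate variation, Hz (default 0.5).
#' @param rate nominal frame rate, Hz (default 30).
#' @param seed RNG seed; the streams are bit-reproducible under it.
#' @return multi-sensor stream tibble: `sensor_id`, `side`, `time`, `joint`,
#'   `x`, `y`, `z`, `state`.
#' @export
corrupt_streams <- function(truth, rig, joint_noise_sigma = 0,
                            lateral_bias = 0, occlusion = TRUE,
                            occlusion_threshold = 0.08,
                            timestamp_jitter = 0.002, rate_wobble = 0.5,
                            rate = 30, seed = NULL) {
  stopifnot(inherits(truth, "gait_truth"))
  if (!is.null(seed)) set.seed(seed)
  traj <- truth$trajectory
  joints <- kinect_joints()
  tt <- unique(traj$time)
  # truth positions as time x joint matrices for fast interpolation
  pos <- lapply(c(x = "x", y = "y", z = "z"), function(col) {
    m <- matrix(traj[[col]], nrow = length(tt), ncol = length(joints))
    colnames(m) <- joints   # traj is generated joint-blockwise in this order
    m
  })
  leg <- list(L = c("HipLeft", "KneeLeft", "AnkleLeft", "FootLeft"),
              R = c("HipRight", "KneeRight", "AnkleRight", "FootRight"))

  purrr::pmap_dfr(rig[, c("sensor_id", "side", "pose", "fov_h", "fov_v",
                          "range_min", "range_max")],
    function(sensor_id, side, pose, fov_h, fov_v, range_min, range_max) {
      n_nom <- floor(truth$duration * rate)
      dt <- 1 / (rate + stats::runif(n_nom, -rate_wobble, rate_wobble))
      times <- cumsum(dt)
      times <- times[times <= truth$duration - 1 / rate] +
        stats::runif(sum(times <= truth$duration - 1 / rate),
                     -timestamp_jitter, timestamp_jitter)
      times <- sort(pmax(times, 0))
      times <- times[c(TRUE, diff(times) > 1e-6)]

      interp <- function(m) {
        apply(m, 2, function(col) stats::approx(tt, col, xout = times)$y)
      }
      px <- interp(pos$x); py <- interp(pos$y); pz <- interp(pos$z)
      sensor_pos <- pose$translation
      inv_pose <- rt_invert(pose)

      near <- leg[[if (side == "left") "L" else "R"]]
      far <- leg[[if (side == "left") "R" else "L"]]

      # cross-walk unit axis; the sensor's side decides the pull sign
      lat_axis <- as.numeric(axis_rotation("z", truth$command$heading) %*%
                               c(0, 1, 0))
      out <- purrr::map_dfr(joints, function(j) {
        p <- cbind(px[, j], py[, j], pz[, j])
        if (lateral_bias > 0) {
          lat_sensor <- sum(sensor_pos * lat_axis)
          lat_joint <- p %*% lat_axis
          pull <- lateral_bias * sign(lat_sensor - lat_joint)
          p <- p + outer(as.numeric(pull), lat_axis)
        }
        state <- ifelse(in_frustum(rt_apply(inv_pose, p), fov_h, fov_v,
                                   range_min, range_max),
                        "tracked", "untracked")
        if (occlusion && j %in% far) {
          hip <- cbind(px[, near[1]], py[, near[1]], pz[, near[1]])
          ank <- cbind(px[, near[3]], py[, near[3]], pz[, near[3]])
          for (i in seq_along(times)) {
            if (state[i] == "untracked") next
            d <- seg_seg_dist(sensor_pos, p[i, ], hip[i, ], ank[i, ])
            if (d < occlusion_threshold) state[i] <- "untracked"
          }
        }
        if (joint_noise_sigma > 0) {
          p <- p + matrix(stats::rnorm(length(p), sd = joint_noise_sigma),
                          ncol = 3)
        }
        tibble::tibble(time = times, joint = j, x = p[, 1], y = p[, 2],
                       z = p[, 3], state = state)
      })
      out$sensor_id <- sensor_id
      out$side <- side
      dplyr::relocate(out, "sensor_id", "side")
    })
}
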
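# Synthetic sensor rig, marker observations and point clouds with known
# ground truth. The default geometry is a walking corridor covered by paired
# depth sensors: rows 2.5 m apart along the walk, sensors 2 m apart across
# it, each rotated 35 degrees inward from the walking direction, 70x60 degree
# field of view, 0.5-4.5 m depth range. The global "world" frame has X along
# the corridor, Z up.

#' Is a local-frame point inside a sensor's frustum?
#'
#' Depth is measured along the boresight (local +z); the horizontal and
#' vertical view angles must stay within half the field of view.
#'
#' @param points_local n x 3 matrix in the sensor's local frame (meters).
#' @param fov_h,fov_v field of view, degrees (defaults 70, 60).
#' @param range_min,range_max depth range, meters (defaults 0.5, 4.5).
#' @return logical vector.
#' @export
in_frustum <- function(points_local, fov_h = 70, fov_v = 60,
                       range_min = 0.5, range_max = 4.5) {
  if (is.null(dim(points_local))) points_local <- matrix(points_local, ncol = 3)
  x <- points_local[, 1]; y <- points_local[, 2]; z <- points_local[, 3]
  z >= range_min & z <= range_max &
    abs(atan2(x, z)) <= fov_h / 2 * pi / 180 &
    abs(atan2(y, z)) <= fov_v / 2 * pi / 180
}

#' Simulate a paired-sensor corridor rig
#'
#' Places `n_rows` left/right sensor pairs along the corridor, mirror
#' symmetric about the midline: row `i` sits at `x = (i-1) * row_spacing`,
#' sensors at `y = +/- corridor_width / 2`, height `sensor_height`, boresight
#' horizontal and rotated `inward_angle` degrees from the walking direction
#' (+x) toward the midline. Sensor local frames: +z boresight, +y up,
#' +x image-right.
#'
#' @param n_rows number of sensor rows (>= 1, default 3: six sensors).
#' @param row_spacing spacing between rows along the walk, m (default 2.5).
#' @param corridor_width lateral sensor separation, m (default 2).
#' @param inward_angle inward rotation, degrees (default 35).
#' @param sensor_height mounting height, m (default 0.8).
#' @param seed accepted for interface symmetry; the rig is deterministic.
#' @return A `sensor_rig` tibble: `sensor_id`, `row`, `side`, `pose`
#'   (list of sensor-local -> world [rigid_transform]), `fov_h`, `fov_v`,
#'   `range_min`, `range_max`, `rate`.
#' @export
simulate_rig <- function(n_rows = 3, row_spacing = 2.5, corridor_width = 2,
                         inward_angle = 35, sensor_height = 0.8, seed = NULL) {
  stopifnot(n_rows >= 1)
  a <- inward_angle * pi / 180
  rows <- purrr::map_dfr(seq_len(n_rows), function(i) {
    purrr::map_dfr(c("left", "right"), function(side) {
      sgn <- if (side == "left") 1 else -1          # left sensors at +y
      pos <- c((i - 1) * row_spacing, sgn * corridor_width / 2, sensor_height)
      dir <- c(cos(a), -sgn * sin(a), 0)            # boresight, toward midline
      up <- c(0, 0, 1)
      xs <- c(up[2] * dir[3] - up[3] * dir[2],
              up[3] * dir[1] - up[1] * dir[3],
              up[1] * dir[2] - up[2] * dir[1])
      rot <- cbind(xs, up, dir)
      tibble::tibble(
        sensor_id = as.character((i - 1) * 2 + if (side == "left") 1 else 2),
        row = i, side = side,
        pose = list(rigid_transform(rot, pos)),
        fov_h = 70, fov_v = 60, range_min = 0.5, range_max = 4.5, rate = 30)
    })
  })
  class(rows) <- c("sensor_rig", class(rows))
  rows
}

#' Default calibration-marker poses for a corridor rig
#'
#' Flat floor markers along the corridor midline, one per sensor row, placed
#' `start_x` plus multiples of `spacing` downstream so each marker is inside
#' the frusta of the nearest row(s). Marker `i` is yawed by `(i-1) * yaw_step`
#' radians so rotation recovery is exercised. Marker 1 defines the global
#' frame: its plane spans the horizontal axes, its normal is up.
#'
#' @param n_markers number of markers (default 3).
#' @param spacing marker spacing along the corridor, m (default 2.5).
#' @param start_x position of marker 1, m (default 1.5).
#' @param yaw_step yaw increment between markers, radians (default 0.25).
#' @return tibble: `marker_id`, `pose` (list of marker -> world
#'   [rigid_transform]).
#' @export
default_marker_poses <- function(n_markers = 3, spacing = 2.5, start_x = 1.5,
                                 yaw_step = 0.25) {
  purrr::map_dfr(seq_len(n_markers), function(i) {
    tibble::tibble(
      marker_id = i,
      pose = list(rigid_transform(axis_rotation("z", (i - 1) * yaw_step),
                                  c(start_x + (i - 1) * spacing, 0, 0))))
  })
}

#' Ground-truth sensor poses in the origin-marker frame
#'
#' The calibration's global frame is the frame of the origin marker, while the
#' simulator's ground truth lives in the world frame; this re-expresses the
#' true sensor poses in the origin marker's frame so they compare directly
#' with a `rig_calibration`.
#'
#' @param rig a `sensor_rig`.
#' @param markers marker-pose tibble (see [default_marker_poses()]).
#' @param origin_marker id of the origin marker (default 1).
#' @return tibble: `sensor_id`, `pose` (sensor-local -> origin-marker frame).
#' @export
rig_poses_in_marker_frame <- function(rig, markers, origin_marker = 1) {
  m1 <- markers$pose[[which(markers$marker_id == origin_marker)]]
  inv_m1 <- rt_invert(m1)
  tibble::tibble(
    sensor_id = rig$sensor_id,
    pose = purrr::map(rig$pose, ~ rt_compose(inv_m1, .x)))
}

#' Simulate marker observations for every sensor
#'
#' Transforms each marker's template corners into every sensor's local frame
#' and emits an observation when all corners fall inside that sensor's
#' frustum, with isotropic Gaussian corner noise. A sensor that sees no
#' marker simply produces no rows (the calibration then fails its
#' connectivity check, as it should).
#'
#' @param rig a `sensor_rig`.
#' @param markers marker-pose tibble.
#' @param template corner template (default [marker_template()]).
#' @param noise_sigma corner noise standard deviation, m (default 0.005).
#' @param seed RNG seed for reproducibility.
#' @return observation tibble: `sensor_id`, `marker_id`, `corner`, `x`, `y`,
#'   `z` (sensor frame, meters).
#' @export
simulate_marker_observations <- function(rig, markers,
                                         template = marker_template(),
                                         noise_sigma = 0.005, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  purrr::pmap_dfr(rig[, c("sensor_id", "pose", "fov_h", "fov_v",
                          "range_min", "range_max")],
    function(sensor_id, pose, fov_h, fov_v, range_min, range_max) {
      inv_pose <- rt_invert(pose)
      purrr::map_dfr(seq_len(nrow(markers)), function(mi) {
        corners_world <- rt_apply(markers$pose[[mi]], template)
        local <- rt_apply(inv_pose, corners_world)
        if (!all(in_frustum(local, fov_h, fov_v, range_min, range_max))) {
          return(NULL)
        }
        noisy <- local + matrix(stats::rnorm(length(local), sd = noise_sigma),
                                ncol = 3)
        tibble::tibble(sensor_id = sensor_id,
                       marker_id = markers$marker_id[mi],
                       corner = seq_len(nrow(template)),
                       x = noisy[, 1], y = noisy[, 2], z = noisy[, 3])
      })
    })
}

# uniform samples on an axis-aligned rectangle patch given two corner points
# varying in exactly two coordinates
sample_rect <- function(n, lo, hi) {
  dims <- which(hi > lo)
  pts <- matrix(rep(lo, each = n), ncol = 3)
  for (d in dims) pts[, d] <- stats::runif(n, lo[d], hi[d])
  pts
}

#' Default scene surfaces for point-cloud simulation
#'
#' The corridor floor plus two boxes standing in the corridor; the boxes'
#' vertical faces break the planar symmetry so that cloud alignment
#' constrains all six degrees of freedom, and the second box gives the far
#' sensor rows overlap structure too.
#'
#' @param length corridor length, m (default 10).
#' @param width corridor width, m (default 2).
#' @return list of rectangles, each `list(lo = c(x, y, z), hi = c(x, y, z))`.
#' @export
default_surfaces <- function(length = 10, width = 2) {
  hw <- width / 2
  box_faces <- function(lo, hi) {
    list(
      list(lo = c(lo[1], lo[2], 0), hi = c(lo[1], hi[2], hi[3])),
      list(lo = c(hi[1], lo[2], 0), hi = c(hi[1], hi[2], hi[3])),
      list(lo = c(lo[1], lo[2], 0), hi = c(hi[1], lo[2], hi[3])),
      list(lo = c(lo[1], hi[2], 0), hi = c(hi[1], hi[2], hi[3])),
      list(lo = c(lo[1], lo[2], hi[3]), hi = c(hi[1], hi[2], hi[3]))
    )
  }
  c(list(
      list(lo = c(0, -hw, 0), hi = c(length, hw, 0)),                   # floor
      list(lo = c(0, -hw, 0), hi = c(length, -hw, 2)),                  # walls
      list(lo = c(0, hw, 0), hi = c(length, hw, 2))),
    box_faces(c(3.2, -0.3, 0), c(3.8, 0.3, 1.2)),
    box_faces(c(6.0, 0.1, 0), c(6.5, 0.6, 1.0)))
}

#' Simulate per-sensor point clouds of shared scene surfaces
#'
#' Samples points uniformly on the scene surfaces in the world frame, then
#' expresses, for every sensor, the points inside its frustum in that sensor's
#' local frame with isotropic noise. Noiseless clouds of two sensors are
#' therefore related exactly by the sensors' relative pose on their overlap.
#'
#' @param rig a `sensor_rig`.
#' @param surfaces list of rectangles (default [default_surfaces()]).
#' @param density points sampled per surface (default 1500). Zero yields
#'   empty clouds.
#' @param noise_sigma point noise sd, m (default 0.002).
#' @param seed RNG seed.
#' @return named list (by sensor id) of n x 3 local-frame point matrices.
#' @export
simulate_point_clouds <- function(rig, surfaces = default_surfaces(),
                                  density = 1500, noise_sigma = 0.002,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  world <- if (density > 0) {
    do.call(rbind, lapply(surfaces, function(s) sample_rect(density, s$lo, s$hi)))
  } else {
    matrix(numeric(0), ncol = 3)
  }
  clouds <- purrr::pmap(rig[, c("sensor_id", "pose", "fov_h", "fov_v",
                                "range_min", "range_max")],
    function(sensor_id, pose, fov_h, fov_v, range_min, range_max) {
      if (!nrow(world)) return(world)
      local <- rt_apply(rt_invert(pose), world)
      local <- local[in_frustum(local, fov_h, fov_v, range_min, range_max), ,
                     drop = FALSE]
      local + matrix(stats::rnorm(length(local), sd = noise_sigma), ncol = 3)
    })
  stats::setNames(clouds, rig$sensor_id)
}
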
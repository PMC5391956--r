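test_that("the default rig is mirror-symmetric and matches the stated geometry", {
  rig <- simulate_rig()
  expect_equal(nrow(rig), 6)
  expect_equal(rig$side, rep(c("left", "right"), 3))
  for (row in 1:3) {
    l <- rig$pose[[2 * row - 1]]; r <- rig$pose[[2 * row]]
    expect_equal(l$translation[1], r$translation[1])        # same x
    expect_equal(l$translation[2], -r$translation[2])       # mirrored y
    expect_equal(l$translation[2], 1)                       # 2 m apart
    # boresights mirror about the corridor plane
    d_l <- l$rotation[, 3]; d_r <- r$rotation[, 3]
    expect_equal(d_l[1], d_r[1], tolerance = 1e-12)
    expect_equal(d_l[2], -d_r[2], tolerance = 1e-12)
    # 35 degrees inward from the walking direction
    expect_equal(acos(d_l[1]) * 180 / pi, 35, tolerance = 1e-9)
  }
  expect_equal(rig$pose[[3]]$translation[1] - rig$pose[[1]]$translation[1], 2.5)
})

test_that("the combined tracking volume spans about nine meters with row overlap", {
  rig <- simulate_rig()
  # probe a walker-torso slab along the corridor
  probe <- expand.grid(x = seq(-2, 12, by = 0.02), y = c(-0.3, 0, 0.3), z = 1)
  seen_by_row <- sapply(1:3, function(row) {
    sub <- rig[rig$row == row, ]
    Reduce(`|`, lapply(sub$pose, function(p) {
      in_frustum(rt_apply(rt_invert(p), as.matrix(probe)))
    }))
  })
  covered <- rowSums(seen_by_row) > 0
  xs <- sort(unique(probe$x[covered]))
  volume_length <- max(xs) - min(xs)
  expect_gt(volume_length, 8.5)
  expect_lt(volume_length, 10.5)
  # no holes between rows: coverage is contiguous
  expect_lt(max(diff(xs)), 0.05)
  # consecutive rows' volumes overlap by about two meters
  for (row in 1:2) {
    hi <- max(probe$x[seen_by_row[, row]])
    lo <- min(probe$x[seen_by_row[, row + 1]])
    expect_gt(hi - lo, 2)
  }
})

test_that("marker observations are frustum-culled and noiseless fits round-trip", {
  rig <- simulate_rig(n_rows = 1)
  # a marker straight ahead is observed; one far beyond depth range is not
  near <- tibble::tibble(marker_id = 1L,
                         pose = list(rigid_transform(diag(3), c(2, 0, 0))))
  far <- tibble::tibble(marker_id = 2L,
                        pose = list(rigid_transform(diag(3), c(8, 0, 0))))
  obs_near <- simulate_marker_observations(rig, near, noise_sigma = 0, seed = 1)
  obs_far <- simulate_marker_observations(rig, far, noise_sigma = 0, seed = 1)
  expect_gt(nrow(obs_near), 0)
  expect_equal(nrow(obs_far), 0)

  # noiseless round trip: the fitted marker->sensor transform matches the
  # constructed relative pose to numerical precision
  one <- dplyr::filter(obs_near, sensor_id == "1")
  fit <- procrustes_fit(marker_template(),
                        as.matrix(one[order(one$corner), c("x", "y", "z")]))
  constructed <- rt_compose(rt_invert(rig$pose[[1]]), near$pose[[1]])
  expect_equal(fit$transform$rotation, constructed$rotation, tolerance = 1e-9)
  expect_equal(fit$transform$translation, constructed$translation,
               tolerance = 1e-9)
})

test_that("gait commands translate exactly into ground-truth parameters", {
  truth <- simulate_gait(step_length = 0.73, step_width = 0.12, cadence = 100,
                         n_strides = 8)
  expect_equal(unique(truth$steps$step_time), 0.6)
  expect_equal(unique(truth$steps$step_length), 73)
  expect_equal(unique(truth$steps$step_width), 12)
  expect_equal(truth$walking_speed, 73 / 0.6, tolerance = 1e-12)
  # walking-speed identity holds exactly on the emitted step table
  expect_equal(sum(truth$steps$step_length) / sum(truth$steps$step_time),
               truth$walking_speed, tolerance = 1e-12)
  # left swings first, so the first crossing-detected placement is Right
  expect_equal(truth$placements$foot[1], "R")
  expect_equal(nrow(truth$events), 16)

  expect_error(simulate_gait(duty_factor = 0.5), "double support")
  expect_error(simulate_gait(duty_factor = 0.45), "double support")
})

test_that("zero corruption reproduces the truth at a steady 30 Hz", {
  truth <- simulate_gait(n_strides = 4)
  rig <- simulate_rig(n_rows = 1)
  streams <- corrupt_streams(truth, rig, joint_noise_sigma = 0,
                             lateral_bias = 0, occlusion = FALSE,
                             timestamp_jitter = 0, rate_wobble = 0, seed = 1)
  s1 <- dplyr::filter(streams, sensor_id == "1", joint == "AnkleLeft")
  expect_equal(diff(sort(unique(s1$time))),
               rep(1 / 30, length(unique(s1$time)) - 1), tolerance = 1e-9)
  truth_ank <- dplyr::filter(truth$trajectory, joint == "AnkleLeft")
  expect_equal(s1$x, stats::approx(truth_ank$time, truth_ank$x, s1$time)$y,
               tolerance = 1e-12)
})

test_that("corrupted streams are bit-reproducible under a seed", {
  truth <- simulate_gait(n_strides = 3)
  rig <- simulate_rig(n_rows = 1)
  s1 <- corrupt_streams(truth, rig, joint_noise_sigma = 0.01, seed = 42)
  s2 <- corrupt_streams(truth, rig, joint_noise_sigma = 0.01, seed = 42)
  expect_identical(s1, s2)
  s3 <- corrupt_streams(truth, rig, joint_noise_sigma = 0.01, seed = 43)
  expect_false(identical(s1$x, s3$x))
})

test_that("occlusion dropout is side-consistent", {
  truth <- simulate_gait(n_strides = 6)
  rig <- simulate_rig()
  streams <- corrupt_streams(truth, rig, occlusion = TRUE,
                             timestamp_jitter = 0, rate_wobble = 0, seed = 5)
  leg_l <- c("HipLeft", "KneeLeft", "AnkleLeft", "FootLeft")
  leg_r <- c("HipRight", "KneeRight", "AnkleRight", "FootRight")
  occluded <- streams |>
    dplyr::filter(state == "untracked", joint %in% c(leg_l, leg_r))
  # restrict to samples inside each sensor's frustum: those dropouts are
  # occlusion, not culling
  clean <- corrupt_streams(truth, rig, occlusion = FALSE,
                           timestamp_jitter = 0, rate_wobble = 0, seed = 5)
  vis <- dplyr::semi_join(
    dplyr::filter(clean, state == "tracked"),
    occluded, by = c("sensor_id", "time", "joint"))
  expect_gt(nrow(vis), 0)   # occlusion does fire inside the frustum
  expect_true(all(!(vis$joint %in% leg_l) | vis$side == "right"))
  expect_true(all(!(vis$joint %in% leg_r) | vis$side == "left"))
})

test_that("the injected lateral bias points toward each sensor's side", {
  truth <- simulate_gait(n_strides = 4)
  rig <- simulate_rig(n_rows = 1)
  b <- 0.015
  streams <- corrupt_streams(truth, rig, lateral_bias = b, occlusion = FALSE,
                             timestamp_jitter = 0, rate_wobble = 0, seed = 2)
  truth_ank <- dplyr::filter(truth$trajectory, joint == "AnkleLeft")
  for (sid in c("1", "2")) {
    s <- dplyr::filter(streams, sensor_id == sid, joint == "AnkleLeft")
    offset <- s$y - stats::approx(truth_ank$time, truth_ank$y, s$time)$y
    expected <- if (unique(s$side) == "left") b else -b
    expect_equal(unique(round(offset, 12)), expected)
  }
})

test_that("point clouds of two sensors are related exactly by their relative pose", {
  rig <- simulate_rig(n_rows = 1)
  clouds <- simulate_point_clouds(rig, density = 300, noise_sigma = 0, seed = 6)
  rel <- rt_compose(rt_invert(rig$pose[[2]]), rig$pose[[1]])  # 1-local -> 2-local
  c1_in_2 <- rt_apply(rel, clouds[["1"]])
  # shared world points appear in both clouds: every transformed point of
  # cloud 1 safely inside sensor 2's frustum must coincide with one of cloud 2
  # (a small margin avoids boundary points culled in one path only)
  inside <- in_frustum(c1_in_2, fov_h = 68, fov_v = 58,
                       range_min = 0.6, range_max = 4.4)
  shared <- c1_in_2[inside, , drop = FALSE]
  expect_gt(nrow(shared), 50)
  idx <- gaitrig:::nn_index(shared, clouds[["2"]])
  d <- sqrt(rowSums((shared - clouds[["2"]][idx, , drop = FALSE])^2))
  expect_lt(max(d), 1e-9)
})
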
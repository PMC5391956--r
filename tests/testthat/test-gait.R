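make_ankles <- function(time, lf, rf, l_lat = 0.06, r_lat = -0.06) {
  tibble::tibble(time = time,
                 lx = lf, ly = rep_len(l_lat, length(time)), lz = 0.08,
                 rx = rf, ry = rep_len(r_lat, length(time)), rz = 0.08,
                 valid = TRUE)
}

test_that("walking-frame axes follow the net displacement and rotate equivariantly", {
  tt <- seq(0, 5, by = 1 / 30)
  ank <- make_ankles(tt, lf = 0.5 * tt, rf = 0.5 * tt - 0.1)
  ax <- estimate_axes(ank)
  expect_equal(ax$forward, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(ax$lateral, c(0, 1, 0), tolerance = 1e-9)

  th <- 30 * pi / 180
  rot <- axis_rotation("z", th)
  l <- t(rot %*% t(cbind(ank$lx, ank$ly, ank$lz)))
  r <- t(rot %*% t(cbind(ank$rx, ank$ry, ank$rz)))
  rot_ank <- tibble::tibble(time = tt, lx = l[, 1], ly = l[, 2], lz = l[, 3],
                            rx = r[, 1], ry = r[, 2], rz = r[, 3], valid = TRUE)
  ax2 <- estimate_axes(rot_ank)
  expect_equal(ax2$forward, as.numeric(rot %*% ax$forward), tolerance = 1e-9)
  expect_equal(ax2$lateral, as.numeric(rot %*% ax$lateral), tolerance = 1e-9)

  still <- make_ankles(tt, lf = rep(0, length(tt)), rf = rep(-0.1, length(tt)))
  expect_error(estimate_axes(still), "displacement")
})

test_that("crossing detection finds the analytic zeros of a sinusoid difference", {
  tt <- seq(0, 2.05, by = 1 / 30)
  # left forward leads by sin(2 pi t); crossings at every half period
  ev <- detect_crossings(tt, left_fwd = sin(2 * pi * tt) + tt,
                         right_fwd = tt, hysteresis = 0)
  expect_equal(nrow(ev), 4)
  expect_equal(ev$time, c(0.5, 1.0, 1.5, 2.0), tolerance = 1e-3)
})

test_that("hysteresis suppresses noise chatter, matching a brute-force oracle", {
  set.seed(21)
  tt <- seq(0, 2, by = 1 / 60)
  for (trial in 1:20) {
    # one true crossing at t = 1 plus sub-hysteresis noise
    d <- 0.1 * (tt - 1) + runif(length(tt), -0.015, 0.015)
    ev <- detect_crossings(tt, left_fwd = d, right_fwd = rep(0, length(tt)),
                           hysteresis = 0.02)
    expect_equal(nrow(ev), crossing_count_oracle(d, 0.02))
  }
  # a single clean crossing yields exactly one event
  d <- 0.1 * (tt - 1)
  ev <- detect_crossings(tt, d, rep(0, length(tt)), hysteresis = 0.02)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time, 1, tolerance = 1e-9)
})

test_that("a simulated walk yields two crossings per stride with alternating stance", {
  truth <- simulate_gait(n_strides = 8)
  ank <- ankle_trajectories(truth$trajectory)
  ax <- estimate_axes(ank)
  a <- gaitrig:::project_ankles(ank, ax)
  ev <- detect_crossings(a$time, a$lf, a$rf)
  expect_equal(nrow(ev), 16)
  expect_true(all(ev$stance_foot[-1] != ev$stance_foot[-16]))
  expect_equal(ev$stance_foot[1], "R")   # left foot swings first
  expect_equal(ev$time, truth$events$time, tolerance = 2e-3)
})

test_that("placements read the stance plateau and recover generator footfalls", {
  truth <- simulate_gait(n_strides = 6)
  gp <- analyze_gait(truth$trajectory)
  pl <- gp$placements
  expect_equal(nrow(pl), nrow(truth$placements))
  expect_equal(pl$foot, truth$placements$foot)
  # forward positions are reported relative to the estimated walking-frame
  # origin; compare displacements from the first placement
  expect_lt(max(abs((pl$forward_pos - pl$forward_pos[1]) -
                      (truth$placements$forward_pos -
                         truth$placements$forward_pos[1]))), 1e-3)
  expect_lt(max(abs(abs(pl$lateral_pos) - 0.06)), 1e-3)
  expect_false(any(pl$flagged))
})

test_that("a repeated stance foot drops the weaker event and flags the result", {
  tt <- seq(0, 3, by = 1 / 30)
  ank <- make_ankles(tt, lf = 0.5 * tt, rf = 0.5 * tt)
  ev <- tibble::tibble(time = c(0.5, 1.0, 1.4, 2.0),
                       passing_foot = c("L", "R", "R", "L"),
                       stance_foot = c("R", "L", "L", "R"),
                       slope = c(1, 0.2, 1.5, 1), index = c(15, 30, 42, 60))
  pl <- extract_placements(ev, ank, estimate_axes(ank))
  expect_equal(nrow(pl), 3)
  expect_equal(pl$foot, c("R", "L", "R"))
  expect_equal(pl$time[2], 1.4)  # the stronger of the two L-stance events
  expect_true(all(pl$flagged))

  same <- dplyr::mutate(ev, stance_foot = "L", passing_foot = "R")
  expect_error(extract_placements(same, ank, estimate_axes(ank)),
               "same stance foot")
})

test_that("step and stride parameters follow the placement arithmetic with exclusions", {
  pl <- tibble::tibble(
    foot = c("R", "L", "R", "L", "R"),
    time = c(0, 0.6, 1.2, 1.8, 2.4),
    forward_pos = c(0, 0.73, 1.46, 2.19, 2.92),
    lateral_pos = c(0.06, -0.06, 0.06, -0.06, 0.06),
    flagged = FALSE)
  gp <- compute_parameters(pl, start_foot = "L")
  # 4 raw steps; the first left step is excluded
  expect_equal(nrow(gp$steps), 3)
  expect_equal(sum(gp$steps$foot == "L"), 1)
  expect_equal(sum(gp$steps$foot == "R"), 2)
  expect_equal(gp$steps$step_length, rep(73, 3), tolerance = 1e-12)
  expect_equal(gp$steps$step_width, rep(12, 3), tolerance = 1e-12)
  expect_equal(gp$steps$step_time, rep(0.6, 3), tolerance = 1e-12)
  # strides: R has two (first excluded -> one kept), L has one
  expect_equal(sum(gp$strides$foot == "R"), 1)
  expect_equal(sum(gp$strides$foot == "L"), 1)
  expect_equal(gp$strides$stride_length, rep(146, 2), tolerance = 1e-12)
  expect_equal(gp$summary$walking_speed, (73 * 3) / (0.6 * 3),
               tolerance = 1e-12)

  # collinear walking: all widths zero
  pl0 <- dplyr::mutate(pl, lateral_pos = 0)
  gp0 <- compute_parameters(pl0)
  expect_true(all(gp0$steps$step_width == 0))

  expect_error(compute_parameters(pl[c(1, 3, 5), ]), "alternate")
  expect_error(compute_parameters(pl[1:2, ]), "at least 3")
})

test_that("stride lengths equal the sum of their constituent steps on a straight walk", {
  truth <- simulate_gait(n_strides = 7, step_length = 0.68, cadence = 108)
  gp <- analyze_gait(truth$trajectory, start_foot = "L")
  # reconstruct per-foot sums from unexcluded placements
  pl <- gp$placements
  for (i in 3:nrow(pl)) {
    stride <- (pl$forward_pos[i] - pl$forward_pos[i - 2]) * 100
    two_steps <- (pl$forward_pos[i] - pl$forward_pos[i - 1]) * 100 +
      (pl$forward_pos[i - 1] - pl$forward_pos[i - 2]) * 100
    expect_equal(stride, two_steps, tolerance = 1e-9)
  }
  expect_equal(gp$summary$walking_speed,
               sum(gp$steps$step_length) / sum(gp$steps$step_time),
               tolerance = 1e-12)
})

test_that("parameters are invariant under a global rigid motion of the scene", {
  truth <- simulate_gait(n_strides = 6)
  gp0 <- analyze_gait(truth$trajectory)
  moved <- transform_stream(truth$trajectory,
                            rigid_transform(axis_rotation("z", 0.7),
                                            c(4, -2, 0)))
  gp1 <- analyze_gait(moved)
  expect_equal(gp1$steps$step_length, gp0$steps$step_length, tolerance = 1e-6)
  expect_equal(gp1$steps$step_width, gp0$steps$step_width, tolerance = 1e-6)
  expect_equal(gp1$steps$step_time, gp0$steps$step_time, tolerance = 1e-9)
  expect_equal(gp1$summary$walking_speed, gp0$summary$walking_speed,
               tolerance = 1e-6)
})

test_that("tidy and the parameter table expose the long exchange schema", {
  truth <- simulate_gait(n_strides = 5)
  gp <- analyze_gait(truth$trajectory)
  td <- tidy(gp)
  expect_setequal(unique(td$parameter),
                  c("step_length", "step_width", "step_time", "stride_length"))
  tbl <- gait_parameter_table(gp, "rec1", "rig", "both", subject_id = "s1")
  expect_true("walking_speed" %in% tbl$parameter)
  expect_equal(unique(tbl$recording_id), "rec1")
  expect_equal(nrow(tbl), nrow(td) + 1)
})
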
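# Shared fixtures built in code.

# a rig_calibration holding the ground-truth poses (origin-marker frame)
truth_calibration <- function(rig, markers, origin_marker = 1) {
  tp <- rig_poses_in_marker_frame(rig, markers, origin_marker)
  pl <- rep(c(1L, 1L, 3L, 3L, 5L, 5L), length.out = nrow(rig))
  cal <- tibble::tibble(sensor_id = tp$sensor_id, transform = tp$pose,
                        path = lapply(tp$sensor_id, function(i) character(0)),
                        path_length = pl, rms = 0, refined = FALSE)
  attr(cal, "origin_marker") <- as.character(origin_marker)
  class(cal) <- c("rig_calibration", class(cal))
  cal
}

# observations of markers placed at given poses, seen by synthetic "sensors"
# at given poses, noiseless unless sigma > 0; no frustum culling
project_observations <- function(sensor_poses, marker_poses,
                                 template = marker_template(), sigma = 0) {
  rows <- list()
  for (s in names(sensor_poses)) {
    for (m in names(marker_poses)) {
      local <- rt_apply(rt_compose(rt_invert(sensor_poses[[s]]),
                                   marker_poses[[m]]), template)
      if (sigma > 0) local <- local + matrix(rnorm(length(local), sd = sigma),
                                             ncol = 3)
      rows[[length(rows) + 1]] <- tibble::tibble(
        sensor_id = s, marker_id = as.integer(m),
        corner = seq_len(nrow(template)),
        x = local[, 1], y = local[, 2], z = local[, 3])
    }
  }
  dplyr::bind_rows(rows)
}

# minimal single-sensor stream for one joint
one_joint_stream <- function(time, x, y = 0, z = 0, state = "tracked",
                             joint = "AnkleLeft") {
  tibble::tibble(time = time, joint = joint,
                 x = x, y = rep_len(y, length(time)),
                 z = rep_len(z, length(time)),
                 state = rep_len(state, length(time)))
}

# independent reachability oracle: can every sensor reach the origin marker?
# (transitive closure by repeated boolean matrix multiplication)
reachability_oracle <- function(edges, sensors, origin) {
  nodes <- unique(c(edges$from, edges$to, sensors, origin))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges$from[i], edges$to[i]] <- TRUE
    adj[edges$to[i], edges$from[i]] <- TRUE
  }
  reach <- adj | diag(n) > 0
  for (k in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  all(reach[sensors, origin])
}

# independent hysteresis-crossing oracle: enumerate sign flips of d and keep
# only those preceded by an excursion beyond h since the last kept flip
crossing_count_oracle <- function(d, h) {
  s <- sign(d)
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  kept <- 0L; last <- 0L
  for (i in seq_len(length(d) - 1)) {
    if (s[i] != 0 && s[i + 1] != 0 && s[i] != s[i + 1]) {
      if (max(abs(d[(last + 1):i])) > h) {
        kept <- kept + 1L
        last <- i
      }
    }
  }
  kept
}

# independent ICC(A,1) oracle through aov()'s two-way mean squares
icc_a1_aov_oracle <- function(a, b) {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
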
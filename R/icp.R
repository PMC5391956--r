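# Point-to-point iterative closest point refinement of a chained calibration.
# Chained poses accumulate Procrustes estimation error along the path; ICP
# against overlapping point clouds pulls every sensor back onto the scene
# geometry. Correspondence search is brute-force blocked nearest neighbour —
# clouds are subsampled first, so the quadratic search stays cheap.

# index of the nearest row of `target` for every row of `source`
nn_index <- function(source, target, block = 512L) {
  t2 <- rowSums(target^2)
  idx <- integer(nrow(source))
  for (start in seq(1L, nrow(source), by = block)) {
    rows <- start:min(start + block - 1L, nrow(source))
    d2 <- outer(rowSums(source[rows, , drop = FALSE]^2), t2, "+") -
      2 * source[rows, , drop = FALSE] %*% t(target)
    idx[rows] <- max.col(-d2, ties.method = "first")
  }
  idx
}

# deterministic uniform subsample: every k-th point, no RNG consumed
subsample_rows <- function(m, fraction) {
  if (fraction >= 1 || nrow(m) < 10) return(m)
  step <- max(1L, floor(1 / fraction))
  m[seq(1L, nrow(m), by = step), , drop = FALSE]
}

icp_pair <- function(source_local, pose, target_global, max_iterations,
                     tolerance, max_pair_distance, subsample_fraction,
                     min_pairs) {
  src <- subsample_rows(source_local, subsample_fraction)
  prev_mean <- Inf
  prev_pose <- pose
  for (iter in seq_len(max_iterations)) {
    src_g <- rt_apply(pose, src)
    idx <- nn_index(src_g, target_global)
    d <- sqrt(rowSums((src_g - target_global[idx, , drop = FALSE])^2))
    # adaptive trim: as the fit tightens, non-overlap pairs fall away
    keep <- d <= min(max_pair_distance, 3 * stats::median(d))
    if (sum(keep) < min_pairs) {
      if (iter == 1) return(list(pose = pose, converged = FALSE, refined = FALSE))
      break
    }
    mean_d <- mean(pmin(d, max_pair_distance))   # capped mean over all pairs
    if (mean_d > prev_mean + tolerance) {        # reject step, keep best pose
      pose <- prev_pose
      break
    }
    converged <- prev_mean - mean_d < tolerance && iter > 1
    prev_mean <- mean_d
    prev_pose <- pose
    if (converged) break
    delta <- procrustes_fit(src_g[keep, , drop = FALSE],
                            target_global[idx[keep], , drop = FALSE])$transform
    pose <- rt_compose(delta, pose)
  }
  list(pose = pose, converged = TRUE, refined = TRUE)
}

#' Refine a calibration with iterative closest point alignment
#'
#' Point-to-point ICP on per-sensor 3D point clouds. Sensors are refined one
#' at a time in ascending chaining-path-length order: the sensor closest to
#' the origin is the anchor and never moves; each subsequent sensor is aligned
#' against the merged, already-fixed clouds. Correspondences beyond
#' `max_pair_distance` are rejected; a sensor whose cloud shares fewer than
#' `min_pairs` close correspondences with the fixed scene is left at its
#' initial pose with a warning.
#'
#' @param clouds named list (by sensor id) of n x 3 point matrices in each
#'   sensor's local frame, meters.
#' @param calibration a `rig_calibration` from [calibrate_rig()] /
#'   [chain_to_origin()].
#' @param max_iterations maximum ICP iterations per sensor (default 200; convergence on plane-dominated scenes is slow along in-plane directions before the exact-correspondence basin is reached).
#' @param tolerance convergence threshold on the change of the mean matched
#'   nearest-neighbour distance, meters (default 1e-7).
#' @param max_pair_distance correspondence rejection radius, meters
#'   (default 0.10).
#' @param subsample_fraction uniform fraction of source points used
#'   (default 0.2; deterministic striding, no randomness).
#' @param min_pairs minimum accepted correspondences for refinement
#'   (default 50).
#' @return The calibration with updated poses and `refined` flags.
#' @export
icp_refine <- function(clouds, calibration, max_iterations = 200,
                       tolerance = 1e-7, max_pair_distance = 0.10,
                       subsample_fraction = 0.2, min_pairs = 50) {
  stopifnot(inherits(calibration, "rig_calibration"))
  ord <- order(calibration$path_length,
               suppressWarnings(as.numeric(calibration$sensor_id)),
               calibration$sensor_id)
  cal <- calibration
  fixed_cloud <- NULL
  for (i in ord) {
    id <- cal$sensor_id[i]
    cloud <- clouds[[id]]
    if (is.null(cloud) || !nrow(cloud)) {
      warning("no point cloud for sensor ", id, "; pose not refined")
      next
    }
    cloud <- as.matrix(cloud)
    if (is.null(fixed_cloud)) {
      # anchor: defines the refined frame, never moves. The fixed target is
      # kept at full density so true twin points are available for matching.
      fixed_cloud <- rt_apply(cal$transform[[i]], cloud)
      cal$refined[i] <- TRUE
      next
    }
    res <- icp_pair(cloud, cal$transform[[i]], fixed_cloud, max_iterations,
                    tolerance, max_pair_distance, subsample_fraction, min_pairs)
    if (!res$refined) {
      warning("insufficient cloud overlap for sensor ", id,
              " (fewer than ", min_pairs, " pairs within ", max_pair_distance,
              " m); pose not refined")
    } else {
      cal$transform[[i]] <- res$pose
      cal$refined[i] <- TRUE
    }
    fixed_cloud <- rbind(fixed_cloud, rt_apply(cal$transform[[i]], cloud))
  }
  cal
}
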
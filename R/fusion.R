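# Temporal alignment and averaging of per-sensor skeleton streams.
#
# Sensors run free at "about 30 Hz", so streams are first linearly resampled
# onto one fixed-rate grid; a grid sample is valid only when both flanking
# raw frames are *tracked* (inferred joints are deliberately not trusted) and
# no more than `max_gap` apart. Valid samples are then averaged across
# sensors with equal weights, and the averaged trajectories are low-pass
# filtered per contiguous valid run.

#' Resample one sensor's stream onto a uniform grid
#'
#' Linear interpolation at fixed-rate grid times. A grid sample for a joint is
#' valid only if both flanking raw frames have state `"tracked"` and their
#' separation is at most `max_gap` seconds; untracked and inferred frames are
#' treated as missing. A grid time that coincides with a raw frame time (to
#' 1e-9 s) is valid if that single frame is tracked.
#'
#' @param stream single-sensor skeleton stream tibble.
#' @param rate grid rate in Hz (default 30).
#' @param max_gap largest bridgeable gap between flanking frames, seconds
#'   (default 0.2).
#' @param grid optional explicit grid times (seconds); when `NULL`, the grid
#'   spans the stream's own time range starting at its first frame.
#' @return tibble with columns `time`, `joint`, `x`, `y`, `z`, `valid`.
#' @export
resample_stream <- function(stream, rate = 30, max_gap = 0.2, grid = NULL) {
  stream <- tibble::as_tibble(stream)
  times <- sort(unique(stream$time))
  if (length(times) < 2) stop("need at least 2 frames to resample", call. = FALSE)
  if (is.null(grid)) {
    grid <- times[1] + seq(0, floor((times[length(times)] - times[1]) * rate)) / rate
  }
  stream |>
    dplyr::group_by(.data$joint) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$time), ]
      n <- nrow(d)
      i <- findInterval(grid, d$time)
      left <- pmax(i, 1L); right <- pmin(i + 1L, n)
      exact <- i >= 1L & abs(grid - d$time[left]) < 1e-9
      interior <- i >= 1L & i < n
      tracked <- d$state == "tracked"
      ok_pair <- interior & tracked[left] & tracked[right] &
        (d$time[right] - d$time[left]) <= max_gap
      valid <- ok_pair | (exact & tracked[pmin(i, n)])
      dt <- d$time[right] - d$time[left]
      w <- ifelse(interior & dt > 0, (grid - d$time[left]) / dt, 0)
      out <- tibble::tibble(
        time = grid,
        x = d$x[left] + w * (d$x[right] - d$x[left]),
        y = d$y[left] + w * (d$y[right] - d$y[left]),
        z = d$z[left] + w * (d$z[right] - d$z[left]),
        valid = valid
      )
      out$x[exact & valid] <- d$x[i[exact & valid]]
      out$y[exact & valid] <- d$y[i[exact & valid]]
      out$z[exact & valid] <- d$z[i[exact & valid]]
      out[!out$valid, c("x", "y", "z")] <- NA_real_
      out
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("time")
}

#' Average gridded streams into one fused skeleton
#'
#' Unweighted mean, per joint and grid time, over the sensors whose sample is
#' valid; a fused sample is missing when no sensor contributes. All input
#' streams must share the grid.
#'
#' @param gridded tibble of resampled streams with columns `sensor_id`,
#'   `time`, `joint`, `x`, `y`, `z`, `valid`.
#' @return A `fused_series` tibble: `time`, `joint`, `x`, `y`, `z`, `valid`,
#'   `n_sensors`.
#' @export
fuse_gridded <- function(gridded) {
  gridded <- tibble::as_tibble(gridded)
  out <- gridded |>
    dplyr::group_by(.data$time, .data$joint) |>
    dplyr::summarise(
      n_sensors = sum(.data$valid),
      x = if (any(.data$valid)) mean(.data$x[.data$valid]) else NA_real_,
      y = if (any(.data$valid)) mean(.data$y[.data$valid]) else NA_real_,
      z = if (any(.data$valid)) mean(.data$z[.data$valid]) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(valid = .data$n_sensors > 0L) |>
    dplyr::relocate("time", "joint", "x", "y", "z", "valid", "n_sensors") |>
    dplyr::arrange(.data$joint, .data$time)
  class(out) <- c("fused_series", class(out))
  out
}

#' Fuse multi-sensor skeleton streams into one global-frame skeleton
#'
#' Full spatial + temporal integration: optionally transforms each sensor's
#' stream into the global frame with its calibrated pose, restricts to a
#' sensor subset, resamples everything onto one shared fixed-rate grid
#' (spanning the intersection of the streams' time ranges, anchored at the
#' latest stream start), and averages with equal weights.
#'
#' @param streams multi-sensor stream tibble (column `sensor_id`; column
#'   `side` required for `subset = "left_only"`).
#' @param calibration optional `rig_calibration`; when supplied, streams are
#'   first mapped into the global frame.
#' @param subset `"both"` (default), `"left_only"`, or a character vector of
#'   sensor ids. One-sided reconstruction uses the same recordings but only
#'   the sensors on one side — the comparison that exposes view-angle bias.
#' @param rate,max_gap see [resample_stream()].
#' @return A `fused_series` tibble.
#' @export
fuse_streams <- function(streams, calibration = NULL,
                         subset = c("both", "left_only"),
                         rate = 30, max_gap = 0.2) {
  streams <- tibble::as_tibble(streams)
  if (!"sensor_id" %in% names(streams)) streams$sensor_id <- "1"
  if (is.character(subset) && length(subset) > 1 &&
      all(subset %in% c("both", "left_only"))) {
    subset <- subset[1]
  }
  if (is.character(subset) && length(subset) == 1 &&
      subset %in% c("both", "left_only")) {
    if (subset == "left_only") {
      stopifnot("side" %in% names(streams))
      streams <- dplyr::filter(streams, .data$side == "left")
    }
  } else {
    streams <- dplyr::filter(streams, .data$sensor_id %in% as.character(subset))
  }
  if (!nrow(streams)) stop("sensor subset selects no streams", call. = FALSE)
  if (!is.null(calibration)) streams <- transform_streams(streams, calibration)

  ranges <- streams |>
    dplyr::group_by(.data$sensor_id) |>
    dplyr::summarise(t0 = min(.data$time), t1 = max(.data$time), .groups = "drop")
  t0 <- max(ranges$t0); t1 <- min(ranges$t1)
  if (t1 <= t0) stop("streams have no overlapping time range", call. = FALSE)
  grid <- t0 + seq(0, floor((t1 - t0) * rate)) / rate

  gridded <- streams |>
    dplyr::group_by(.data$sensor_id) |>
    dplyr::group_modify(~ resample_stream(.x, rate = rate, max_gap = max_gap,
                                          grid = grid)) |>
    dplyr::ungroup()
  out <- fuse_gridded(gridded)
  attr(out, "rate") <- rate
  out
}

#' Zero-phase low-pass filtering of a fused series
#'
#' Butterworth low-pass applied forward and backward (zero phase lag) to each
#' coordinate, independently on every contiguous run of valid samples. Runs
#' shorter than three times the filter's effective length are passed through
#' unfiltered; the validity mask is never changed. The defaults (order 4,
#' 6 Hz cutoff) retain all gait-band content while suppressing sensor jitter.
#'
#' @param series a `fused_series` (uniform grid).
#' @param order filter order (default 4).
#' @param cutoff cutoff frequency, Hz (default 6); must be below the Nyquist
#'   frequency of the grid.
#' @param rate grid rate, Hz; taken from the series attribute when present.
#' @return the series with smoothed `x`, `y`, `z`.
#' @export
smooth_series <- function(series, order = 4, cutoff = 6, rate = NULL) {
  series <- tibble::as_tibble(series)
  if (is.null(rate)) rate <- attr(series, "rate")
  if (is.null(rate)) {
    ts <- sort(unique(series$time))
    rate <- 1 / stats::median(diff(ts))
  }
  if (cutoff >= rate / 2) {
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency ",
         rate / 2, " Hz", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  eff_len <- 3 * (order + 1)       # effective settle length of one pass
  min_len <- 3 * eff_len
  # odd-reflection padding keeps the forward-backward pass transient-free at
  # the segment ends (filtfilt itself does not pad)
  filt0 <- function(x) {
    p <- min(length(x) - 1L, 3L * eff_len)
    head_pad <- 2 * x[1] - x[(p + 1):2]
    tail_pad <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - p)]
    y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    y[(p + 1):(p + length(x))]
  }
  out <- series |>
    dplyr::group_by(.data$joint) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$time), ]
      runs <- rle(d$valid)
      ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
      for (r in which(runs$values)) {
        idx <- starts[r]:ends[r]
        if (length(idx) < min_len) next
        for (col in c("x", "y", "z")) {
          d[[col]][idx] <- filt0(d[[col]][idx])
        }
      }
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("time")
  class(out) <- c("fused_series", class(out))
  attr(out, "rate") <- rate
  out
}
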
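#' Rigid (Euclidean) transforms in 3D
#'
#' A rigid transform is a proper rotation plus a translation, `x -> R x + t`.
#' It preserves distances: no scaling, no reflection. Rigid transforms are the
#' currency of extrinsic sensor calibration: every sensor pose and every
#' marker-to-sensor relation is one.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 vector, in meters.
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @examples
#' t1 <- rigid_transform(diag(3), c(1, 2, 3))
#' rt_apply(t1, matrix(0, 1, 3))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("`rotation` is not orthonormal", call. = FALSE)
  }
  if (det(rotation) < 0) {
    stop("`rotation` is a reflection (determinant < 0), not a proper rotation",
         call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() {
  rigid_transform(diag(3), c(0, 0, 0))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation (angle", format(rt_angle(x) * 180 / pi, digits = 4), "deg):\n")
  print(round(x$rotation, 6))
  cat("translation (m):", format(x$translation, digits = 6), "\n")
  invisible(x)
}

#' Compose and invert rigid transforms
#'
#' `rt_compose(a, b)` is the transform mapping `x` to `a(b(x))`;
#' `rt_invert(t)` undoes `t`, so `rt_compose(t, rt_invert(t))` is the identity.
#'
#' @param a,b,t `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rt_compose
#' @export
rt_invert <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rigid_transform(t(t$rotation), as.numeric(-t(t$rotation) %*% t$translation))
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid_transform`.
#' @param points n x 3 numeric matrix (or length-3 vector) of points, meters.
#' @return n x 3 matrix of transformed points.
#' @export
rt_apply <- function(t, points) {
  stopifnot(inherits(t, "rigid_transform"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  sweep(points %*% t(t$rotation), 2, t$translation, "+")
}

#' Rotation angle of a rigid transform
#'
#' The geodesic angle (radians) of the rotation part; 0 for the identity.
#' Useful as a pose-error metric together with the translation norm.
#'
#' @param t a `rigid_transform`.
#' @return angle in radians, in `[0, pi]`.
#' @export
rt_angle <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  c_theta <- (sum(diag(t$rotation)) - 1) / 2
  acos(min(1, max(-1, c_theta)))
}

#' Pose error between two transforms
#'
#' Rotation angle and translation norm of `rt_compose(a, rt_invert(b))`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A tibble with columns `rot_err_rad` and `trans_err_m`.
#' @export
rt_error <- function(a, b) {
  d <- rt_compose(a, rt_invert(b))
  tibble::tibble(rot_err_rad = rt_angle(d),
                 trans_err_m = sqrt(sum(d$translation^2)))
}

#' Least-squares rigid fit between corresponding point sets
#'
#' Rigid Procrustes superposition: finds the rotation `R` and translation `t`
#' minimising `sum ||R s_i + t - d_i||^2` over corresponding points, with the
#' rotation constrained to be proper (determinant +1; the sign of the smallest
#' singular value is corrected, so reflections are never returned and scaling
#' is never absorbed). This is the Kabsch/Umeyama solution via the SVD of the
#' cross-covariance of the centred point sets.
#'
#' @param source,target n x 3 matrices of corresponding points (row i of
#'   `source` corresponds to row i of `target`), n >= 3, not collinear.
#' @return A list with `transform` (a [rigid_transform] mapping source onto
#'   target) and `rms` (root-mean-square residual distance, meters).
#' @examples
#' pts <- matrix(rnorm(12), 4, 3)
#' fit <- procrustes_fit(pts, pts)
#' fit$rms # 0
#' @export
procrustes_fit <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) != nrow(target)) {
    stop("`source` and `target` must have the same number of points", call. = FALSE)
  }
  if (nrow(source) < 3) stop("need at least 3 corresponding points", call. = FALSE)
  if (!all(is.finite(source)) || !all(is.finite(target))) {
    stop("points must be finite", call. = FALSE)
  }
  cs <- colMeans(source); ct <- colMeans(target)
  s0 <- sweep(source, 2, cs); t0 <- sweep(target, 2, ct)
  # rank < 2 after centering means the points are (near-)collinear and the
  # rotation about the common axis is unidentifiable
  if (qr(s0, tol = 1e-10)$rank < 2 || qr(t0, tol = 1e-10)$rank < 2) {
    stop("degenerate point configuration: points are collinear", call. = FALSE)
  }
  h <- crossprod(s0, t0)           # 3x3 cross-covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ct - as.numeric(r %*% cs)
  tr <- rigid_transform(r, t)
  res <- rt_apply(tr, source) - target
  list(transform = tr, rms = sqrt(mean(rowSums(res^2))))
}

#' Convert between rotation matrices and unit quaternions
#'
#' Quaternions are used in the calibration file format (`w, x, y, z`, unit
#' norm, `w >= 0`).
#'
#' @param r 3x3 proper rotation matrix.
#' @return `rot_to_quat()`: numeric length-4 `(w, x, y, z)`;
#'   `quat_to_rot()`: 3x3 rotation matrix.
#' @export
rot_to_quat <- function(r) {
  tr <- sum(diag(r))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (r[3, 2] - r[2, 3]) / s, (r[1, 3] - r[3, 1]) / s,
           (r[2, 1] - r[1, 2]) / s)
  } else {
    i <- which.max(diag(r))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(r[i, i] - r[j, j] - r[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (r[k, j] - r[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (r[j, i] + r[i, j]) / s
    q[k + 1] <- (r[k, i] + r[i, k]) / s
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' @rdname rot_to_quat
#' @param q numeric length-4 unit quaternion `(w, x, y, z)`.
#' @export
quat_to_rot <- function(q) {
  stopifnot(length(q) == 4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Random proper rotation (uniform on SO(3))
#'
#' Drawn via normalised Gaussian quaternions; used by the simulator and tests.
#'
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  quat_to_rot(stats::rnorm(4))
}

#' Rotation about a coordinate axis
#'
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param angle angle in radians.
#' @return 3x3 rotation matrix.
#' @export
axis_rotation <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  c1 <- cos(angle); s1 <- sin(angle)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c1, -s1, 0, s1, c1), 3, 3, byrow = TRUE),
    y = matrix(c(c1, 0, s1, 0, 1, 0, -s1, 0, c1), 3, 3, byrow = TRUE),
    z = matrix(c(c1, -s1, 0, s1, c1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  )
}
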
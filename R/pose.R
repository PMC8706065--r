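# Head pose from 2D facial landmarks, and rotation-error metrics.
#
# Euler convention (documented, since per-axis comparisons depend on it):
# intrinsic yaw-pitch-roll, applied in that order. Yaw rotates about the
# vertical (y) axis, positive toward the subject's left; pitch about the
# lateral (x) axis, positive looking up; roll about the frontal (z) axis.
# R = Ry(yaw) %*% Rx(pitch) %*% Rz(roll), angles in degrees. The pose
# solver and the geodesic metric are convention-independent; only the
# labelling of the recovered angle triple depends on it.

#' Yaw/pitch/roll rotation triple
#'
#' @param yaw,pitch,roll angles in degrees, each within `[-90, 90]` (the
#'   supported head-pose envelope; gimbal lock at ±90 pitch is excluded by
#'   construction in practice).
#' @return numeric vector of class `rotation_triple` with named components.
#' @examples
#' rotation_triple(20, -10, 5)
#' @export
rotation_triple <- function(yaw = 0, pitch = 0, roll = 0) {
  for (a in list(yaw = yaw, pitch = pitch, roll = roll)) {
    if (!is.numeric(a) || length(a) != 1L || !is.finite(a)) {
      stop("angles must be single finite numbers (degrees)", call. = FALSE)
    }
  }
  if (abs(yaw) > 90 || abs(pitch) > 90 || abs(roll) > 90) {
    stop("angles must lie within [-90, 90] degrees", call. = FALSE)
  }
  structure(c(yaw = unname(yaw), pitch = unname(pitch), roll = unname(roll)),
            class = "rotation_triple")
}

#' Rotation matrix of a pose
#'
#' @param pose a [rotation_triple()].
#' @return 3x3 rotation matrix `Ry(yaw) Rx(pitch) Rz(roll)`.
#' @export
rotation_matrix <- function(pose) {
  stopifnot(inherits(pose, "rotation_triple"))
  a <- pose * pi / 180
  cy <- cos(a[["yaw"]]);   sy <- sin(a[["yaw"]])
  cp <- cos(a[["pitch"]]); sp <- sin(a[["pitch"]])
  cr <- cos(a[["roll"]]);  sr <- sin(a[["roll"]])
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cp, -sp, 0, sp, cp), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cr, -sr, 0, sr, cr, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry %*% Rx %*% Rz
}

# Inverse of rotation_matrix for |pitch| < 90.
# M = Ry Rx Rz gives M[2,3] = -sin(pitch), M[1,3]/M[3,3] = tan(yaw),
# M[2,1]/M[2,2] = tan(roll).
euler_from_matrix <- function(M) {
  pitch <- asin(max(-1, min(1, -M[2, 3])))
  yaw <- atan2(M[1, 3], M[3, 3])
  roll <- atan2(M[2, 1], M[2, 2])
  rotation_triple(yaw * 180 / pi, pitch * 180 / pi, roll * 180 / pi)
}

#' Unit quaternion of a pose
#'
#' Converts a yaw/pitch/roll triple to its unit quaternion (Shepperd's
#' matrix-to-quaternion method), with the sign fixed so that `w >= 0`.
#'
#' @param rt a [rotation_triple()].
#' @return numeric vector of class `unit_quaternion`, components
#'   `w, x, y, z`, unit norm.
#' @examples
#' euler_to_quaternion(rotation_triple(0, 0, 0))  # identity: (1,0,0,0)
#' @export
euler_to_quaternion <- function(rt) {
  M <- rotation_matrix(rt)
  tr <- sum(diag(M))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (M[3, 2] - M[2, 3]) / s, (M[1, 3] - M[3, 1]) / s,
           (M[2, 1] - M[1, 2]) / s)
  } else {
    i <- which.max(diag(M))
    if (i == 1) {
      s <- sqrt(1 + M[1, 1] - M[2, 2] - M[3, 3]) * 2
      q <- c((M[3, 2] - M[2, 3]) / s, s / 4, (M[1, 2] + M[2, 1]) / s,
             (M[1, 3] + M[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + M[2, 2] - M[1, 1] - M[3, 3]) * 2
      q <- c((M[1, 3] - M[3, 1]) / s, (M[1, 2] + M[2, 1]) / s, s / 4,
             (M[2, 3] + M[3, 2]) / s)
    } else {
      s <- sqrt(1 + M[3, 3] - M[1, 1] - M[2, 2]) * 2
      q <- c((M[2, 1] - M[1, 2]) / s, (M[1, 3] + M[3, 1]) / s,
             (M[2, 3] + M[3, 2]) / s, s / 4)
    }
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  structure(c(w = q[1], x = q[2], y = q[3], z = q[4]),
            class = "unit_quaternion")
}

#' Geodesic angle between two rotations
#'
#' The smallest rotation angle taking one orientation to the other:
#' `2 * acos(|q1 . q2|)` in degrees. Symmetric, in `[0, 180]`.
#'
#' @param q1,q2 [euler_to_quaternion()] outputs (or any unit-norm
#'   `w,x,y,z` vectors).
#' @param tol unit-norm tolerance.
#' @return geodesic distance in degrees.
#' @examples
#' geodesic_deg(euler_to_quaternion(rotation_triple(30, 0, 0)),
#'              euler_to_quaternion(rotation_triple(10, 0, 0)))  # 20
#' @export
geodesic_deg <- function(q1, q2, tol = 1e-6) {
  q1 <- as.numeric(q1); q2 <- as.numeric(q2)
  if (length(q1) != 4L || length(q2) != 4L ||
      abs(sum(q1^2) - 1) > tol || abs(sum(q2^2) - 1) > tol) {
    stop("geodesic_deg: inputs must be unit quaternions", call. = FALSE)
  }
  d <- abs(sum(q1 * q2))
  2 * acos(min(1, d)) * 180 / pi
}

#' Estimate head pose from 2D landmarks
#'
#' Scaled-orthographic (weak-perspective) Procrustes fit: landmark names
#' establish 2D-3D correspondence with the canonical model; both sets are
#' centred; the 2x3 linear map taking model to image is solved in least
#' squares and projected onto the nearest scaled row-orthonormal matrix by
#' SVD; the third rotation row is completed by cross product (determinant
#' +1 by construction) and Euler angles are extracted under the package
#' convention. No camera intrinsics are required.
#'
#' @param landmarks2d data.frame with columns `name`, `x`, `y` (pixels);
#'   at least 4 points with names present in the model.
#' @param model a [canonical_face_model()].
#' @return a [rotation_triple()] with attribute `scale` (pixels per model
#'   unit).
#' @examples
#' lm <- simulate_landmarks(rotation_triple(20, -10, 5))
#' estimate_pose(lm)
#' @export
estimate_pose <- function(landmarks2d, model = canonical_face_model()) {
  stopifnot(inherits(model, "canonical_face_model"))
  if (!is.data.frame(landmarks2d) ||
      !all(c("name", "x", "y") %in% names(landmarks2d))) {
    stop("landmarks2d must be a data.frame with columns name, x, y",
         call. = FALSE)
  }
  common <- intersect(landmarks2d$name, rownames(model))
  if (length(common) < 4L) {
    stop("estimate_pose: need at least 4 landmarks matching the model",
         call. = FALSE)
  }
  X <- unclass(model)[common, , drop = FALSE]
  P <- as.matrix(landmarks2d[match(common, landmarks2d$name), c("x", "y")])
  X <- sweep(X, 2, colMeans(X))
  P <- sweep(P, 2, colMeans(P))
  XtX <- crossprod(X)
  if (qr(X)$rank < 3L || rcond(XtX) < 1e-12) {
    stop("estimate_pose: degenerate landmark configuration (rank < 3)",
         call. = FALSE)
  }
  A <- t(P) %*% X %*% solve(XtX)          # 2x3 least-squares map
  sv <- svd(A)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1)) {
    stop("estimate_pose: degenerate projection (rank < 2); pose ambiguous",
         call. = FALSE)
  }
  B <- sv$u %*% t(sv$v)                   # nearest row-orthonormal 2x3
  r3 <- c(B[1, 2] * B[2, 3] - B[1, 3] * B[2, 2],
          B[1, 3] * B[2, 1] - B[1, 1] * B[2, 3],
          B[1, 1] * B[2, 2] - B[1, 2] * B[2, 1])
  R <- rbind(B, r3)
  if (det(R) < 0) {
    stop("estimate_pose: reflection-only solution; landmark set inconsistent with a rigid rotation",
         call. = FALSE)
  }
  out <- euler_from_matrix(R)
  attr(out, "scale") <- mean(sv$d)
  out
}

#' Summarise rotation errors between true and estimated poses
#'
#' Per-axis mean absolute Euler error, mean squared error pooled over all
#' three angles and all frames, and the mean quaternion geodesic.
#'
#' @param truth,est lists of [rotation_triple()]s (or data.frames/matrices
#'   with columns `yaw`, `pitch`, `roll`), equal length `>= 1`.
#' @return list of class `rotation_error_summary` with elements
#'   `avg_abs_pitch_err`, `avg_abs_yaw_err`, `avg_abs_roll_err` (degrees),
#'   `mse_all_angles` (degrees^2), `avg_geodesic` (degrees), `n`.
#' @examples
#' rotation_errors(list(rotation_triple(10, 0, 0)),
#'                 list(rotation_triple(13, 4, 0)))
#' @export
rotation_errors <- function(truth, est) {
  tm <- as_pose_matrix(truth)
  em <- as_pose_matrix(est)
  if (nrow(tm) != nrow(em)) {
    stop("rotation_errors: truth and est must have equal length", call. = FALSE)
  }
  if (nrow(tm) < 1L) stop("rotation_errors: need at least one pose", call. = FALSE)
  d <- em - tm
  geo <- vapply(seq_len(nrow(tm)), function(i) {
    geodesic_deg(euler_to_quaternion(rotation_triple(tm[i, 1], tm[i, 2], tm[i, 3])),
                 euler_to_quaternion(rotation_triple(em[i, 1], em[i, 2], em[i, 3])))
  }, numeric(1))
  structure(list(
    avg_abs_yaw_err = mean(abs(d[, 1])),
    avg_abs_pitch_err = mean(abs(d[, 2])),
    avg_abs_roll_err = mean(abs(d[, 3])),
    mse_all_angles = mean(d^2),
    avg_geodesic = mean(geo),
    n = nrow(tm)
  ), class = "rotation_error_summary")
}

# Coerce a list of rotation_triples / data.frame / matrix into an
# n x 3 matrix with columns yaw, pitch, roll.
as_pose_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (!length(x)) return(matrix(numeric(0), 0, 3,
                                  dimnames = list(NULL, c("yaw", "pitch", "roll"))))
    m <- do.call(rbind, lapply(x, function(p) {
      stopifnot(inherits(p, "rotation_triple"))
      as.numeric(p)
    }))
  } else {
    m <- as.matrix(as.data.frame(x)[, c("yaw", "pitch", "roll")])
  }
  colnames(m) <- c("yaw", "pitch", "roll")
  m
}
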
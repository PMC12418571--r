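#' Rigid-body transform from realignment parameters
#'
#' Converts one row of realignment parameters (3 translations in mm, 3
#' rotations in radians) into a 4x4 homogeneous rigid-body transform. The
#' composition order is translation times `Rx %*% Ry %*% Rz`, with
#' right-handed, counterclockwise rotation matrices and rotation about the
#' world origin of the parameter frame — the frame realignment reports in,
#' not the voxel centre.
#'
#' @param p Numeric vector of length 6: `(tx, ty, tz, rx, ry, rz)`,
#'   translations in mm, rotations in radians (pitch, roll, yaw).
#' @return A 4x4 numeric matrix; the upper-left 3x3 block is orthonormal with
#'   determinant +1 and the last row is `(0, 0, 0, 1)`.
#' @examples
#' params_to_transform(c(1, 2, 3, 0, 0, 0))
#' # a quarter-turn yaw carries (65, 0, 0) to (0, 65, 0):
#' params_to_transform(c(0, 0, 0, 0, 0, pi / 2)) %*% c(65, 0, 0, 1)
#' @export
params_to_transform <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 6L || !all(is.finite(p))) {
    abort("`p` must be 6 finite values (tx, ty, tz, rx, ry, rz).")
  }
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3L, 3L)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3L, 3L)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3L, 3L)
  out <- diag(4)
  out[1:3, 1:3] <- rx %*% ry %*% rz
  out[1:3, 4] <- p[1:3]
  out
}

is_rigid_transform <- function(m, tol = 1e-10) {
  is.matrix(m) && all(dim(m) == c(4L, 4L)) &&
    all(abs(m[4, ] - c(0, 0, 0, 1)) <= tol) &&
    max(abs(crossprod(m[1:3, 1:3]) - diag(3))) <= tol &&
    abs(det(m[1:3, 1:3]) - 1) <= tol
}

#' Relative rigid transform between two timepoints
#'
#' Motion of a volume expressed against an arbitrary reference volume:
#' `relative_transform(T_t, T_ref)` returns `T_t %*% solve(T_ref)`, the
#' transform that carries material points from their reference-volume
#' position to their position at time t.
#'
#' @param t_cur,t_ref 4x4 rigid transforms (see [params_to_transform()]).
#' @return A 4x4 rigid transform.
#' @export
relative_transform <- function(t_cur, t_ref) {
  stopifnot(is_rigid_transform(t_cur), is_rigid_transform(t_ref))
  # closed-form rigid inverse: R' , -R't
  inv <- diag(4)
  r <- t_ref[1:3, 1:3]
  inv[1:3, 1:3] <- t(r)
  inv[1:3, 4] <- -crossprod(r, t_ref[1:3, 4])
  t_cur %*% inv
}

#' Euclidean displacement of a material point under a rigid transform
#'
#' @param transform 4x4 rigid transform.
#' @param point Numeric length-3 position in mm.
#' @return Non-negative displacement in mm, `||T(point) - point||`.
#' @export
point_displacement <- function(transform, point) {
  point <- as.numeric(point)
  stopifnot(length(point) == 3L, all(is.finite(point)))
  moved <- transform[1:3, 1:3] %*% point + transform[1:3, 4]
  sqrt(sum((moved - point)^2))
}

#' Conventional displacement series (TD / STS)
#'
#' Total displacement (TD) measures each volume against the first volume of
#' the series and captures slow drift; scan-to-scan displacement (STS)
#' measures against the immediately preceding volume and captures motion
#' spikes. Because rotations translate material points in proportion to their
#' distance from the origin, displacement is evaluated at representative
#' points 65 mm from the origin (the average adult cortical distance) — by
#' default the median over the six axis points, so that the conventional
#' series is summarised at the same locations as the overlap metrics. The
#' `"rss"` aggregate instead combines the six parameters directly as the
#' root-sum-square of the three shifts and the three arc lengths
#' `angle * radius`, for comparability studies.
#'
#' @param motion A motion-parameter data frame (see [read_motion()]): one row
#'   per volume, columns `trans_x..rot_z`.
#' @param mode `"TD"` (reference = first volume) or `"STS"` (reference =
#'   preceding volume).
#' @param radius Lever-arm distance in mm; default 65.
#' @param aggregate `"median6"` (default) or `"rss"`.
#' @return A tibble with columns `volume`, `displacement` (mm), and
#'   attributes `mode`, `radius`. The first timepoint is 0 by convention.
#' @examples
#' m <- pure_shift_series(c(1, 2), axis = "x")
#' displacement_series(m, "TD")
#' @export
displacement_series <- function(motion, mode = c("TD", "STS"), radius = 65,
                                aggregate = c("median6", "rss")) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    abort("`radius` must be a single positive number (mm).")
  }
  params <- motion_params_matrix(motion)
  n <- nrow(params)
  transforms <- lapply(seq_len(n), function(i) params_to_transform(params[i, ]))
  centers <- representative_centers(radius)
  pts <- as.matrix(centers[, c("x", "y", "z")])
  disp <- vapply(seq_len(n), function(t) {
    if (t == 1L) return(0)
    ref <- if (mode == "TD") transforms[[1L]] else transforms[[t - 1L]]
    rel <- relative_transform(transforms[[t]], ref)
    if (aggregate == "median6") {
      median(vapply(seq_len(nrow(pts)), function(i) {
        point_displacement(rel, pts[i, ])
      }, numeric(1)))
    } else {
      p_rel <- c(rel[1:3, 4], rotation_angles_rss(rel[1:3, 1:3]))
      sqrt(sum(p_rel[1:3]^2) + radius^2 * sum(p_rel[4:6]^2))
    }
  }, numeric(1))
  out <- tibble::tibble(volume = seq_len(n), displacement = disp)
  attr(out, "mode") <- mode
  attr(out, "radius") <- radius
  out
}

# Euler angles for R = Rx(a) Ry(b) Rz(c): R[1,3] = sin(b),
# R[2,3] = -sin(a)cos(b), R[3,3] = cos(a)cos(b), R[1,2] = -cos(b)sin(c).
rotation_angles_rss <- function(r) {
  ry <- asin(max(-1, min(1, r[1, 3])))
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(-r[2, 3], r[3, 3])
    rz <- atan2(-r[1, 2], r[1, 1])
  } else {
    rx <- atan2(r[3, 2], r[2, 2])
    rz <- 0
  }
  c(rx, ry, rz)
}

# inverse of params_to_transform (canonical 6-vector from a rigid transform)
transform_to_params <- function(m) {
  stopifnot(is_rigid_transform(m, tol = 1e-8))
  c(m[1:3, 4], rotation_angles_rss(m[1:3, 1:3]))
}
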
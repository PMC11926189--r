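.deg2rad <- pi / 180

.Rz <- function(a) {
  a <- a * .deg2rad
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

.Ry <- function(a) {
  a <- a * .deg2rad
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Rotation matrix from ZYZ Euler angles
#'
#' Composes \code{R = Rz(rot) \%*\% Ry(tilt) \%*\% Rz(psi)} in the
#' intrinsic ZYZ convention used by RELION particle metadata. The result
#' is a proper orthonormal rotation (det = +1).
#'
#' @param rot,tilt,psi angles in degrees.
#' @return a 3x3 rotation matrix.
#' @examples
#' eulerToRotation(0, 0, 0)        # identity
#' eulerToRotation(0, 180, 0)      # diag(-1, 1, -1)
#' @export
eulerToRotation <- function(rot, tilt, psi) {
  stopifnot(is.finite(rot), is.finite(tilt), is.finite(psi))
  .Rz(rot) %*% .Ry(tilt) %*% .Rz(psi)
}

#' Normalise ZYZ Euler angles to canonical ranges
#'
#' Maps an arbitrary (rot, tilt, psi) triple onto the equivalent triple
#' with tilt in [0, 180] and rot, psi in (-180, 180], leaving the
#' rotation matrix unchanged (uses the identity
#' Ry(-t) = Rz(180) Ry(t) Rz(180)).
#'
#' @param rot,tilt,psi numeric vectors of angles in degrees.
#' @return data.frame with columns rot, tilt, psi.
#' @export
normalizeEuler <- function(rot, tilt, psi) {
  wrap <- function(a) {           # into (-180, 180]
    a <- a %% 360
    ifelse(a > 180, a - 360, a)
  }
  tilt <- tilt %% 360
  flip <- tilt > 180
  tilt[flip] <- 360 - tilt[flip]
  rot[flip] <- rot[flip] + 180
  psi[flip] <- psi[flip] + 180
  data.frame(rot = wrap(rot), tilt = tilt, psi = wrap(psi))
}

# ZYZ decomposition of a rotation matrix; inverse of eulerToRotation.
# Near the gimbal singularities (tilt ~ 0 or ~ 180) psi is set to 0.
.matrixToEuler <- function(R) {
  ct <- min(1, max(-1, R[3, 3]))
  tilt <- acos(ct) / .deg2rad
  if (abs(ct) < 1 - 1e-12) {
    rot <- atan2(R[2, 3], R[1, 3]) / .deg2rad
    psi <- atan2(R[3, 2], -R[3, 1]) / .deg2rad
  } else if (ct > 0) {            # tilt ~ 0: R = Rz(rot + psi)
    rot <- atan2(R[2, 1], R[1, 1]) / .deg2rad
    psi <- 0
  } else {                        # tilt ~ 180: R = Rz(rot - psi) Ry(180)
    rot <- atan2(-R[2, 1], -R[1, 1]) / .deg2rad
    psi <- 0
  }
  normalizeEuler(rot, tilt, psi)
}

# Uniform random rotation matrix (quaternion method), and a small random
# rotation with angle <= maxDeg about a uniform random axis.
.randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  .quatToMatrix(q)
}

.randomJitterRotation <- function(maxDeg) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, maxDeg) * .deg2rad
  .axisAngleToMatrix(ax, ang)
}

.quatToMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

.axisAngleToMatrix <- function(axis, angle) {
  c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}
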
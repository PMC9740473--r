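# Quaternion and Euler-angle algebra.
#
# Quaternions are numeric length-4 vectors c(w, x, y, z) with unit norm;
# they encode the rotation of body-frame vectors into the parent (lab)
# frame. Euler-angle conventions follow the scipy naming scheme: an
# order string such as "ZYX" denotes intrinsic rotations (about the
# moving axes, applied left to right), lower case such as "zyx" denotes
# extrinsic rotations about the fixed axes.

#' Quaternion product
#'
#' Composes two rotations: \code{quat_mul(q1, q2)} first applies
#' \code{q2}, then \code{q1} (matrix convention \code{R(q1) \%*\% R(q2)}).
#'
#' @param q1,q2 quaternions \code{c(w, x, y, z)}.
#' @return the product quaternion.
#' @export
quat_mul <- function(q1, q2) {
  w1 <- q1[1]; x1 <- q1[2]; y1 <- q1[3]; z1 <- q1[4]
  w2 <- q2[1]; x2 <- q2[2]; y2 <- q2[3]; z2 <- q2[4]
  c(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
}

#' @rdname quat_mul
#' @param q quaternion.
#' @export
quat_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n < 1e-300) stop("cannot normalize zero quaternion")
  q <- q / n
  if (q[1] < 0) q <- -q   # canonical hemisphere
  q
}

#' Rotation matrix of a quaternion
#'
#' @param q unit quaternion \code{c(w, x, y, z)}.
#' @return 3x3 rotation matrix mapping body-frame to lab-frame vectors.
#' @export
quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)
  ), nrow = 3, byrow = TRUE)
}

#' @rdname quat_to_mat
#' @param R 3x3 rotation matrix.
#' @export
mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_normalize(q)
}

axis_quat <- function(axis, angle) {
  h <- angle / 2
  s <- sin(h)
  switch(axis,
         X = , x = c(cos(h), s, 0, 0),
         Y = , y = c(cos(h), 0, s, 0),
         Z = , z = c(cos(h), 0, 0, s),
         stop("unknown axis ", axis))
}

#' Convert Euler angles to a quaternion
#'
#' @param angles numeric length 3 (alpha, beta, gamma) in radians; the
#'   i-th angle rotates about the i-th axis letter of \code{order}.
#' @param order three-letter axis order, upper case for intrinsic
#'   (moving-axes) rotations, lower case for extrinsic (fixed-axes),
#'   e.g. \code{"ZYX"} (default) or \code{"xyz"}.
#' @return unit quaternion.
#' @export
euler_to_quat <- function(angles, order = "ZYX") {
  ax <- strsplit(order, "")[[1]]
  if (length(ax) != 3) stop("order must have three axis letters")
  intrinsic <- order == toupper(order)
  qs <- lapply(seq_len(3), function(i) axis_quat(ax[i], angles[i]))
  q <- if (intrinsic) quat_mul(quat_mul(qs[[1]], qs[[2]]), qs[[3]])
       else           quat_mul(quat_mul(qs[[3]], qs[[2]]), qs[[1]])
  quat_normalize(q)
}

#' @rdname euler_to_quat
#' @param q unit quaternion.
#' @return \code{quat_to_euler}: angles (alpha, beta, gamma) in radians,
#'   wrapped into (-pi, pi].
#' @export
quat_to_euler <- function(q, order = "ZYX") {
  intrinsic <- order == toupper(order)
  ord <- toupper(order)
  R <- quat_to_mat(q)
  if (!intrinsic) {
    # extrinsic abc == intrinsic reversed with swapped angle slots
    e <- .mat_to_euler_intrinsic(R, paste(rev(strsplit(ord, "")[[1]]), collapse = ""))
    return(wrap_angle(rev(e)))
  }
  wrap_angle(.mat_to_euler_intrinsic(R, ord))
}

# Intrinsic Tait-Bryan / proper-Euler extraction from a rotation matrix.
.mat_to_euler_intrinsic <- function(R, ord) {
  idx <- function(a) match(a, c("X", "Y", "Z"))
  ax <- strsplit(ord, "")[[1]]
  i <- idx(ax[1]); j <- idx(ax[2]); k <- idx(ax[3])
  if (i != k) {
    # Tait-Bryan (all axes distinct)
    sign <- if ((j - i) %% 3 == 1) 1 else -1   # cyclic => +1
    sb <- sign * R[i, k]
    sb <- max(-1, min(1, sb))
    beta <- asin(sb)
    if (abs(sb) < 1 - 1e-10) {
      alpha <- atan2(-sign * R[j, k], R[k, k])
      gamma <- atan2(-sign * R[i, j], R[i, i])
    } else {
      alpha <- atan2(sign * R[k, j], R[j, j])
      gamma <- 0
    }
  } else {
    # proper Euler (first and third axes equal), e.g. ZYZ
    l <- 6 - i - j    # remaining axis
    sign <- if ((j - i) %% 3 == 1) 1 else -1
    cb <- max(-1, min(1, R[i, i]))
    beta <- acos(cb)
    if (abs(cb) < 1 - 1e-10) {
      alpha <- atan2(R[j, i], -sign * R[l, i])
      gamma <- atan2(R[i, j], sign * R[i, l])
    } else {
      alpha <- atan2(sign * R[l, j], R[j, j])
      gamma <- 0
    }
  }
  c(alpha, beta, gamma)
}

#' Uniform random unit quaternions
#'
#' Draws rotations uniformly over SO(3) (Shoemake's method); consumes
#' the R RNG stream so results are reproducible under \code{set.seed}.
#'
#' @param n number of quaternions.
#' @return an \code{n x 4} matrix of unit quaternions.
#' @export
random_quat <- function(n = 1) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  a <- sqrt(1 - u1); b <- sqrt(u1)
  q <- cbind(a * sin(2 * pi * u2), a * cos(2 * pi * u2),
             b * sin(2 * pi * u3), b * cos(2 * pi * u3))
  # canonical hemisphere, column order (w,x,y,z)
  q <- q[, c(2, 1, 3, 4), drop = FALSE]
  flip <- q[, 1] < 0
  q[flip, ] <- -q[flip, ]
  q
}

# Rotation angle (radians, in [0, pi]) of a quaternion.
quat_angle <- function(q) 2 * acos(pmin(1, abs(q[1])))

# Quaternion for a small rotation vector (axis * angle).
rotvec_quat <- function(v) {
  th <- sqrt(sum(v * v))
  if (th < 1e-300) return(c(1, 0, 0, 0))
  c(cos(th / 2), sin(th / 2) * v / th)
}
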
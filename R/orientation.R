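# Quaternion helpers. Quaternions are length-4 numeric vectors (w, x, y, z)
# representing the rotation from device axes to the world frame.

quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) return(c(1, 0, 0, 0))
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

# Rotate a device-frame vector into the world frame.
quat_rotate <- function(q, v) {
  w <- q[1]; u <- q[2:4]
  2 * sum(u * v) * u + (w * w - sum(u * u)) * v + 2 * w * c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

quat_conjugate <- function(q) c(q[1], -q[2:4])

# Rotation matrix (device -> world) from a unit quaternion.
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Intrinsic Z-Y'-X'' (yaw-pitch-roll) Euler angles from a unit quaternion.
quat_to_euler <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2))
  s <- 2 * (w * y - z * x)
  pitch <- asin(pmin(1, pmax(-1, s)))
  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2))
  c(roll = roll, pitch = pitch, yaw = yaw)
}

#' Estimate sensor orientation from gyroscope and accelerometer
#'
#' Propagates a device-to-world quaternion by integrating the gyroscope and
#' corrects the inclination (roll/pitch) with the accelerometer via a
#' complementary scheme: the measured specific-force direction is compared
#' with the direction gravity should have in the device frame and a small
#' fraction (`correction_gain`) of the misalignment is applied at every step.
#' Yaw is unobservable from the accelerometer, so it follows the integrated
#' gyroscope alone.
#'
#' The world frame is x = anterior-posterior, y = medial-lateral,
#' z = vertical (up); the device frame follows the axis convention of the
#' trial configuration (by default x = ML, y = V, z = AP for a waist-worn
#' device, see [default_config()]).
#'
#' During dynamic phases the specific force is dominated by linear
#' acceleration rather than gravity, so the correction is gated: it is only
#' applied when the accelerometer norm has stayed within `accept_tol` of
#' gravity over the surrounding 0.3 s (brief coincidental returns of the
#' norm to g mid-movement do not open the gate).
#' The default gain (0.002 per step, a ~5 s time constant at 100 Hz) keeps
#' the correction from cancelling genuine oscillatory sway acceleration
#' while still pinning the inclination over the trial; initial roll/pitch
#' come from aligning the first accelerometer sample with gravity.
#'
#' @param trial A `uniform_trial` (see [resample_uniform()]), accelerometer in
#'   m/s^2, gyroscope in rad/s.
#' @param correction_gain Dimensionless accelerometer correction gain per
#'   step (default 0.002).
#' @param accept_tol Gate half-width on the accelerometer norm (m/s^2).
#' @param axes Integer vector naming which device column is ML, V and AP.
#' @return An `orientation_track`: list with `quaternions` (N x 4, unit
#'   norm), `euler` (N x 3: roll, pitch, yaw in rad) and `rate`.
#' @export
estimate_orientation <- function(trial, correction_gain = 0.002,
                                 accept_tol = 0.15,
                                 axes = c(ml = 1L, v = 2L, ap = 3L)) {
  acc <- trial$acc; gyr <- trial$gyr
  n <- nrow(acc)
  dt <- 1 / trial$rate
  # Map device columns into the (AP, ML, V) working order used internally.
  ord <- c(axes[["ap"]], axes[["ml"]], axes[["v"]])
  a <- acc[, ord, drop = FALSE]
  g <- gyr[, ord, drop = FALSE]
  q <- c(1, 0, 0, 0)
  # Initialise roll/pitch from the first accelerometer sample: align measured
  # gravity with world +z.
  a0 <- a[1, ]
  n0 <- sqrt(sum(a0^2))
  if (n0 > 1e-6) {
    v <- a0 / n0
    target <- c(0, 0, 1)
    axis <- c(v[2] * target[3] - v[3] * target[2],
              v[3] * target[1] - v[1] * target[3],
              v[1] * target[2] - v[2] * target[1])
    ang <- acos(pmin(1, pmax(-1, sum(v * target))))
    q <- quat_from_axis_angle(axis, ang)
  }
  norms <- sqrt(rowSums(a^2))
  quiet <- moving_max(abs(norms - GRAVITY), round(0.3 * trial$rate)) < accept_tol
  quats <- matrix(0, n, 4L)
  eulers <- matrix(0, n, 3L)
  quats[1, ] <- q
  eulers[1, ] <- quat_to_euler(q)
  skipped <- 0L
  for (i in 2:n) {
    w <- g[i, ]
    ang <- sqrt(sum(w^2)) * dt
    if (ang > 0) {
      dq <- quat_from_axis_angle(w, ang)
      q <- quat_multiply(q, dq)
    }
    am <- a[i, ]
    na <- norms[i]
    if (na > 1e-6 && quiet[i]) {
      # gravity direction predicted in device frame vs measured specific force
      pred <- quat_rotate(quat_conjugate(q), c(0, 0, 1))
      meas <- am / na
      err <- c(meas[2] * pred[3] - meas[3] * pred[2],
               meas[3] * pred[1] - meas[1] * pred[3],
               meas[1] * pred[2] - meas[2] * pred[1])
      ea <- sqrt(sum(err^2))
      if (ea > 0) {
        # r rotates the measured gravity direction onto the predicted one in
        # the device frame; composing on the right nudges the prediction
        # toward the measurement by `correction_gain` of the misalignment.
        q <- quat_multiply(q, quat_from_axis_angle(err, correction_gain * ea))
      }
    } else if (na <= 1e-6) {
      skipped <- skipped + 1L
    }
    q <- q / sqrt(sum(q^2))
    quats[i, ] <- q
    eulers[i, ] <- quat_to_euler(q)
  }
  if (skipped > 0L) {
    message(sprintf("orientation: accelerometer correction skipped at %d zero-norm samples", skipped))
  }
  colnames(eulers) <- c("roll", "pitch", "yaw")
  structure(list(quaternions = quats, euler = eulers, rate = trial$rate,
                 axes = axes),
            class = "orientation_track")
}

#' Gravity-free linear acceleration in the world frame
#'
#' Rotates the device accelerometer into the world frame using an estimated
#' orientation track and removes gravity from the vertical component. The
#' world anterior-posterior axis is anchored to the mean heading over the
#' first second of quiet standing, so AP/ML components are expressed relative
#' to the participant's initial facing direction.
#'
#' @param trial A `uniform_trial`.
#' @param orient The matching `orientation_track`.
#' @return N x 3 matrix (columns `ap`, `ml`, `v`) in m/s^2.
#' @export
world_linear_acceleration <- function(trial, orient) {
  acc <- trial$acc
  n <- nrow(acc)
  if (nrow(orient$quaternions) != n) {
    stop("trial and orientation track have different lengths", call. = FALSE)
  }
  axes <- orient$axes
  ord <- c(axes[["ap"]], axes[["ml"]], axes[["v"]])
  a <- acc[, ord, drop = FALSE]
  out <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    out[i, ] <- quat_rotate(orient$quaternions[i, ], a[i, ])
  }
  out[, 3] <- out[, 3] - GRAVITY
  # Re-anchor the horizontal axes to the initial heading.
  n0 <- min(n, as.integer(orient$rate))
  yaw0 <- mean(orient$euler[seq_len(n0), "yaw"])
  c0 <- cos(yaw0); s0 <- sin(yaw0)
  ap <- c0 * out[, 1] + s0 * out[, 2]
  ml <- -s0 * out[, 1] + c0 * out[, 2]
  out[, 1] <- ap
  out[, 2] <- ml
  colnames(out) <- c("ap", "ml", "v")
  out
}
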
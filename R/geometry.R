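# Angular geometry helpers shared by the generator, preprocessing and event
# detection. Internal canonical frame is right-handed: +X right, +Y up,
# +Z forward. Azimuth is positive rightward, elevation positive upward, both
# in degrees.

deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)

#' Convert azimuth/elevation (degrees) to unit direction vectors
#'
#' @param az azimuth in degrees, positive rightward.
#' @param el elevation in degrees, positive upward.
#' @return n x 3 matrix of unit vectors (columns x, y, z) in the canonical
#'   right-handed frame (+X right, +Y up, +Z forward).
#' @keywords internal
azel_to_vec <- function(az, el) {
  a <- deg2rad(az)
  e <- deg2rad(el)
  cbind(x = sin(a) * cos(e), y = sin(e), z = cos(a) * cos(e))
}

#' Convert unit direction vectors to azimuth/elevation (degrees)
#' @param v n x 3 matrix of direction vectors.
#' @return list with numeric vectors `az` and `el` in degrees.
#' @keywords internal
vec_to_azel <- function(v) {
  v <- as.matrix(v)
  list(
    az = rad2deg(atan2(v[, 1], v[, 3])),
    el = rad2deg(asin(pmin(1, pmax(-1, v[, 2] / sqrt(rowSums(v^2))))))
  )
}

# Great-circle angle (deg) between paired rows of two n x 3 matrices.
angle_between <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d <- rowSums(a * b) / sqrt(rowSums(a^2) * rowSums(b^2))
  rad2deg(acos(pmin(1, pmax(-1, d))))
}

# Angle (deg) between consecutive rows of an n x 3 matrix; length n - 1.
consecutive_angles <- function(v) {
  n <- nrow(v)
  if (n < 2) return(numeric(0))
  angle_between(v[-n, , drop = FALSE], v[-1, , drop = FALSE])
}

# Renormalize rows to unit length; zero rows are left untouched.
normalize_rows <- function(v) {
  n <- sqrt(rowSums(v^2))
  n[n == 0] <- 1
  v / n
}

# Quaternions (w, x, y, z) from head yaw/pitch-equivalent angles. The head
# orientation is parameterized as azimuth (yaw about +Y), elevation (pitch of
# the forward axis) and roll about the forward axis, applied in that order.
head_quaternion <- function(az, el, roll) {
  ha <- deg2rad(az) / 2
  he <- deg2rad(el) / 2
  hr <- deg2rad(roll) / 2
  # q = q_yaw(Y) * q_pitch(X') * q_roll(Z'') composed in the canonical frame;
  # elevation up corresponds to a rotation of -el about +X.
  cy <- cos(ha); sy <- sin(ha)
  cp <- cos(-he); sp <- sin(-he)
  cr <- cos(hr); sr <- sin(hr)
  # yaw * pitch
  w1 <- cy * cp; x1 <- cy * sp; y1 <- sy * cp; z1 <- -sy * sp
  # (yaw*pitch) * roll about z
  cbind(
    w = w1 * cr - z1 * sr,
    x = x1 * cr + y1 * sr,
    y = y1 * cr - x1 * sr,
    z = w1 * sr + z1 * cr
  )
}

# Rotation angle (deg) between consecutive orientations given as Euler angles.
consecutive_rotation_angles <- function(az, el, roll) {
  q <- head_quaternion(az, el, roll)
  n <- nrow(q)
  if (n < 2) return(numeric(0))
  d <- abs(rowSums(q[-n, , drop = FALSE] * q[-1, , drop = FALSE]))
  2 * rad2deg(acos(pmin(1, d)))
}

# Minimum-jerk position profile on tau in [0, 1] (0 at 0, 1 at 1).
minimum_jerk <- function(tau) {
  tau <- pmin(1, pmax(0, tau))
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

# Fraction of a minimum-jerk movement elapsed when speed first crosses a
# fraction r of peak speed: solves 16 t^2 (1-t)^2 = r on [0, 1/2].
minimum_jerk_crossing <- function(r) {
  r <- pmin(1, pmax(0, r))
  (1 - sqrt(pmax(0, 1 - sqrt(r)))) / 2
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
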
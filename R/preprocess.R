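# Validity handling, gap interpolation, timebase alignment and angular
# differentiation. All internal angles use a single right-handed frame
# (+X right, +Y up, +Z forward); the eye stream's recorded +X-left axis is
# negated on ingest so per-axis features share sign conventions across
# effectors. Axis naming for features: X = pitch, Y = yaw, Z = roll.

#' Mark sample validity from pupil diameter
#'
#' A sample is valid iff its recorded pupil diameter is strictly positive.
#' No sample values are altered.
#'
#' @param stream eye-sample data.frame with a `pupil` column.
#' @return the stream with a logical `valid` column (and `usable` initialized
#'   to `valid`).
#' @export
mark_validity <- function(stream) {
  if (is.null(stream$pupil)) stop("stream has no 'pupil' column")
  stream$valid <- stream$pupil > 0
  stream$usable <- stream$valid
  stream
}

#' Repair short tracking gaps and mask long ones
#'
#' Maximal runs of invalid samples shorter than 50 ms are filled by linear
#' interpolation of the eye direction between the flanking valid samples
#' (renormalized to unit length) and marked usable; runs of 50 ms or longer,
#' plus the neighbouring 2 samples on each side, are marked unusable. Runs
#' touching a trial boundary have no flank and are always masked, never
#' extrapolated. Idempotent. A run's duration is its sample count divided by
#' the sampling rate.
#'
#' @param stream eye-sample data.frame with `t`, `x`, `y`, `z`, `pupil` and a
#'   `valid` column (see [mark_validity()]).
#' @param max_gap_s gaps strictly shorter than this are interpolated.
#' @param margin unusable margin (samples) on each side of a long gap.
#' @return the stream with interpolated directions, an updated `usable`
#'   column and a logical `interpolated` column.
#' @export
repair_gaps <- function(stream, max_gap_s = 0.05, margin = 2L) {
  if (is.null(stream$valid)) stop("run mark_validity() first")
  n <- nrow(stream)
  stream$interpolated <- rep(FALSE, n)
  stream$usable <- stream$valid
  if (n == 0 || all(stream$valid)) return(stream)
  fs <- 1 / stats::median(diff(stream$t))
  r <- rle(!stream$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    len <- i1 - i0 + 1
    at_edge <- i0 == 1 || i1 == n
    if (!at_edge && len / fs < max_gap_s) {
      a <- i0 - 1; b <- i1 + 1
      w <- (stream$t[i0:i1] - stream$t[a]) / (stream$t[b] - stream$t[a])
      for (col in c("x", "y", "z")) {
        stream[[col]][i0:i1] <- (1 - w) * stream[[col]][a] + w * stream[[col]][b]
      }
      nrm <- sqrt(stream$x[i0:i1]^2 + stream$y[i0:i1]^2 + stream$z[i0:i1]^2)
      nrm[nrm == 0] <- 1
      stream$x[i0:i1] <- stream$x[i0:i1] / nrm
      stream$y[i0:i1] <- stream$y[i0:i1] / nrm
      stream$z[i0:i1] <- stream$z[i0:i1] / nrm
      stream$pupil[i0:i1] <- (1 - w) * stream$pupil[a] + w * stream$pupil[b]
      stream$usable[i0:i1] <- TRUE
      stream$interpolated[i0:i1] <- TRUE
    } else {
      lo <- max(1, i0 - margin); hi <- min(n, i1 + margin)
      stream$usable[lo:hi] <- FALSE
    }
  }
  stream
}

# Spherical linear interpolation of unit vectors v (n x 3) sampled at times t
# onto query times tq. Assumes tq within range(t).
slerp_rows <- function(t, v, tq) {
  i <- findInterval(tq, t, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1), length(t) - 1)
  u <- (tq - t[i]) / (t[i + 1] - t[i])
  a <- v[i, , drop = FALSE]; b <- v[i + 1, , drop = FALSE]
  d <- pmin(1, pmax(-1, rowSums(a * b)))
  om <- acos(d)
  small <- om < 1e-6
  w1 <- ifelse(small, 1 - u, sin((1 - u) * om) / sin(pmax(om, 1e-12)))
  w2 <- ifelse(small, u, sin(u * om) / sin(pmax(om, 1e-12)))
  normalize_rows(w1 * a + w2 * b)
}

lerp <- function(t, x, tq) {
  stats::approx(t, x, xout = tq, rule = 1)$y
}

#' Align eye and head streams onto a common uniform clock
#'
#' Resamples both effectors to a uniform grid (default 120 Hz) spanning the
#' overlap of the two streams: eye directions by spherical interpolation, head
#' angles by linear interpolation. The eye stream is canonicalized to the
#' internal right-handed frame (+X right) and head pitch converted to
#' elevation (positive up). A resampled point is usable only if both
#' neighbouring source eye samples are usable.
#'
#' @param eye_stream eye data.frame (`t`, `x`, `y`, `z`, `pupil`, optional
#'   `usable`/`valid`/`interpolated` and gaze-label columns) in the recorded
#'   +X-left frame.
#' @param head_stream head data.frame (`t`, `yaw`, `pitch`, `roll`), pitch
#'   positive downward as recorded.
#' @param target_rate output sampling rate in Hz.
#' @return an `aligned_stream` data.frame with columns `t`, `ex`, `ey`, `ez`
#'   (canonical eye-in-head direction), `h_az`, `h_el`, `h_roll` (deg),
#'   `pupil`, `valid`, `usable` and gaze labels; the sampling rate is stored
#'   in attribute `fs`.
#' @export
align_timebase <- function(eye_stream, head_stream, target_rate = 120) {
  t0 <- max(min(eye_stream$t), min(head_stream$t))
  t1 <- min(max(eye_stream$t), max(head_stream$t))
  if (t1 <= t0) stop("eye and head streams do not overlap in time")
  tq <- seq(t0, t0 + floor((t1 - t0) * target_rate) / target_rate,
            by = 1 / target_rate)

  ev <- cbind(-eye_stream$x, eye_stream$y, eye_stream$z)  # canonicalize
  ei <- slerp_rows(eye_stream$t, ev, tq)

  usable_src <- if (is.null(eye_stream$usable)) rep(TRUE, nrow(eye_stream)) else eye_stream$usable
  valid_src <- if (is.null(eye_stream$valid)) usable_src else eye_stream$valid
  i <- pmin(pmax(findInterval(tq, eye_stream$t, rightmost.closed = TRUE), 1),
            nrow(eye_stream) - 1)
  usable <- usable_src[i] & usable_src[i + 1]
  valid <- valid_src[i] & valid_src[i + 1]

  nearest <- ifelse(tq - eye_stream$t[i] <= eye_stream$t[i + 1] - tq, i, i + 1)
  gid <- if (!is.null(eye_stream$gazed_object_id))
    eye_stream$gazed_object_id[nearest] else rep(NA_integer_, length(tq))
  gkind <- if (!is.null(eye_stream$gazed_object_kind))
    eye_stream$gazed_object_kind[nearest] else rep("none", length(tq))

  out <- data.frame(
    t = tq,
    ex = ei[, 1], ey = ei[, 2], ez = ei[, 3],
    h_az = lerp(head_stream$t, head_stream$yaw, tq),
    h_el = -lerp(head_stream$t, head_stream$pitch, tq),
    h_roll = lerp(head_stream$t, head_stream$roll, tq),
    pupil = lerp(eye_stream$t, eye_stream$pupil, tq),
    valid = valid, usable = usable,
    gazed_object_id = gid, gazed_object_kind = gkind,
    stringsAsFactors = FALSE
  )
  attr(out, "fs") <- target_rate
  class(out) <- c("aligned_stream", "data.frame")
  out
}

# Central finite differences (forward/backward at the edges) of columns of m
# with spacing dt; returns a matrix of the same size.
finite_diff <- function(m, dt) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2) return(matrix(NA_real_, n, ncol(m)))
  d <- matrix(NA_real_, n, ncol(m))
  if (n > 2) d[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) / (2 * dt)
  d[1, ] <- (m[2, ] - m[1, ]) / dt
  d[n, ] <- (m[n, ] - m[n - 1, ]) / dt
  d
}

# Erode a logical mask so only samples whose full central-difference stencil
# is usable remain TRUE.
erode_mask <- function(u) {
  n <- length(u)
  if (n < 3) return(rep(FALSE, n))
  out <- u
  out[2:(n - 1)] <- u[1:(n - 2)] & u[2:(n - 1)] & u[3:n]
  out[1] <- u[1] & u[2]
  out[n] <- u[n - 1] & u[n]
  out
}

#' Angular derivatives of an aligned stream
#'
#' Computes per-axis angular velocity (order 1) and higher derivatives by
#' repeated central differencing, masked (`NA`) across unusable spans. For the
#' eye, per-axis values are time-derivatives of the three eye-direction unit
#' vector components scaled by 180/pi, so their vector norm equals the total
#' angular speed in deg/s; for the head they are derivatives of the pitch/yaw/
#' roll angles (X = pitch, Y = yaw, Z = roll). The `speed` column holds total
#' angular speed: the angle between consecutive directions (eye) or
#' orientations (head) divided by the sample interval.
#'
#' @param stream an [align_timebase()] result.
#' @param effector `"eye"` or `"head"`.
#' @param order derivative order 1 (velocity), 2 (acceleration) or
#'   3 (jerk).
#' @param mask `"stream"` to mask derivatives across unusable spans (the head
#'   inherits the eye's usable mask after alignment, keeping event epochs
#'   comparable across effectors), or `"none"` for an all-usable mask
#'   (head-only workflows).
#' @return a `velocity_series` data.frame with columns `t`, `x`, `y`, `z`,
#'   `speed` (deg/s^order) and attribute `fs`.
#' @export
differentiate <- function(stream, effector = c("eye", "head"), order = 1,
                          mask = c("stream", "none")) {
  effector <- match.arg(effector)
  mask <- match.arg(mask)
  stopifnot(order %in% 1:3)
  fs <- attr(stream, "fs")
  if (is.null(fs)) fs <- 1 / stats::median(diff(stream$t))
  dt <- 1 / fs
  n <- nrow(stream)
  usable <- if (mask == "stream" && !is.null(stream$usable))
    stream$usable else rep(TRUE, n)

  if (effector == "eye") {
    dirs <- cbind(stream$ex, stream$ey, stream$ez)
    axes <- dirs * (180 / pi)
    step <- consecutive_angles(dirs)
  } else {
    axes <- cbind(stream$h_el, stream$h_az, stream$h_roll)  # X, Y, Z
    step <- consecutive_rotation_angles(stream$h_az, stream$h_el, stream$h_roll)
  }
  speed <- c(step, step[length(step)]) * fs

  v <- finite_diff(axes, dt)
  mask <- erode_mask(usable)
  sp_mask <- usable & c(usable[-1], usable[n])
  k <- 1
  while (k < order) {
    v <- finite_diff(v, dt)
    speed <- finite_diff(matrix(speed, ncol = 1), dt)[, 1]
    mask <- erode_mask(mask)
    sp_mask <- erode_mask(sp_mask)
    k <- k + 1
  }
  v[!mask, ] <- NA_real_
  speed[!sp_mask] <- NA_real_

  out <- data.frame(t = stream$t, x = v[, 1], y = v[, 2], z = v[, 3],
                    speed = speed)
  attr(out, "fs") <- fs
  attr(out, "order") <- order
  attr(out, "effector") <- effector
  class(out) <- c("velocity_series", "data.frame")
  out
}

#' Ingest a synthetic trial into an aligned stream
#'
#' Convenience wrapper: marks validity, repairs gaps, and aligns the eye and
#' head streams of a [generate_trial()] bundle onto the target clock.
#'
#' @param trial a `foraging_trial`.
#' @param target_rate output rate in Hz.
#' @return an `aligned_stream`.
#' @export
ingest_trial <- function(trial, target_rate = 120) {
  eye <- repair_gaps(mark_validity(trial$eye))
  align_timebase(eye, trial$head, target_rate = target_rate)
}
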
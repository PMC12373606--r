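# Independent brute-force recomputations used as oracles. Everything here is
# written with explicit loops and scalar arithmetic (rotation matrices instead
# of quaternions, acos dots instead of vectorized geometry) so it shares no
# code path with the package implementation.

oracle_rotmat <- function(az, el, roll) {
  a <- az * pi / 180; e <- -el * pi / 180; r <- roll * pi / 180
  Ry <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
               byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(e), -sin(e), 0, sin(e), cos(e)), 3, 3,
               byrow = TRUE)
  Rz <- matrix(c(cos(r), -sin(r), 0, sin(r), cos(r), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Ry %*% Rx %*% Rz
}

oracle_rot_angle <- function(az1, el1, r1, az2, el2, r2) {
  R <- t(oracle_rotmat(az1, el1, r1)) %*% oracle_rotmat(az2, el2, r2)
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

oracle_vec_angle <- function(a, b) {
  d <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, max(-1, d))) * 180 / pi
}

# Central differences with one-sided edges, by loop.
oracle_diff <- function(x, dt) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < 2) return(out)
  for (i in seq_len(n)) {
    out[i] <- if (i == 1) (x[2] - x[1]) / dt
    else if (i == n) (x[n] - x[n - 1]) / dt
    else (x[i + 1] - x[i - 1]) / (2 * dt)
  }
  out
}

oracle_erode <- function(u) {
  n <- length(u)
  out <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    out[i] <- all(u[lo:hi])
  }
  if (n >= 2) {
    out[1] <- u[1] && u[2]
    out[n] <- u[n - 1] && u[n]
  } else out[] <- FALSE
  out
}

oracle_abs_stats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(c(0, 0))
  m <- sum(abs(x)) / length(x)
  s <- if (length(x) < 2) 0 else
    sqrt(sum((abs(x) - m)^2) / (length(x) - 1))
  c(m, s)
}

# Brute-force recomputation of the full 76-feature vector.
oracle_features <- function(events, stream, record) {
  fs <- attr(stream, "fs")
  dt <- 1 / fs
  n <- nrow(stream)
  duration <- record$duration
  u <- stream$usable
  fx <- events$fixations
  sc <- attribute_saccade_objects(events$saccades, fx)
  hm <- events$head_movements
  hf <- events$head_fixations
  out <- c()

  # fixation features
  n_t <- 0; n_d <- 0; dur_t <- 0; dur_d <- 0; dur_all <- 0
  for (k in seq_len(nrow(fx))) {
    dur_all <- dur_all + fx$duration[k]
    if (fx$object_kind[k] == "target") {
      n_t <- n_t + 1; dur_t <- dur_t + fx$duration[k]
    } else if (fx$object_kind[k] == "distractor") {
      n_d <- n_d + 1; dur_d <- dur_d + fx$duration[k]
    }
  }
  avg <- function(s, k) if (k == 0) 0 else s / k
  out <- c(out,
    fixation_frequency = nrow(fx) / duration,
    avg_fixation_duration = avg(dur_all, nrow(fx)),
    fixation_duration_proportion = dur_all / duration,
    target_fixation_frequency = n_t / duration,
    avg_target_fixation_duration = avg(dur_t, n_t),
    target_fixation_duration_proportion = dur_t / duration,
    distractor_fixation_frequency = n_d / duration,
    avg_distractor_fixation_duration = avg(dur_d, n_d),
    distractor_fixation_duration_proportion = dur_d / duration,
    target_fixations_per_target = n_t / record$n_targets,
    distractor_fixations_per_distractor = n_d / record$n_distractors,
    target_distractor_fixation_ratio = n_t / max(1, nrow(fx) - n_t),
    target_distractor_fixation_duration_ratio =
      dur_t / max(dur_all - dur_t, 0.075))

  # saccade features
  st <- 0; sd_ <- 0; samp <- 0; n_st <- 0; n_sd <- 0
  for (k in seq_len(nrow(sc))) {
    samp <- samp + sc$amplitude[k]
    if (sc$object_kind[k] == "target") { st <- st + sc$amplitude[k]; n_st <- n_st + 1 }
    if (sc$object_kind[k] == "distractor") { sd_ <- sd_ + sc$amplitude[k]; n_sd <- n_sd + 1 }
  }
  out <- c(out,
    saccade_frequency = nrow(sc) / duration,
    avg_saccade_size = avg(samp, nrow(sc)),
    saccade_size_per_second = samp / duration,
    avg_target_saccade_size = avg(st, n_st),
    avg_distractor_saccade_size = avg(sd_, n_sd))

  # coordination
  dirs <- cbind(stream$ex, stream$ey, stream$ez)
  fwd <- c(0, 0, 1)
  eih <- 0; n_eih <- 0; glob_e <- 0; propsum <- 0; n_prop <- 0
  for (i in seq_len(n)) {
    ea <- oracle_vec_angle(dirs[i, ], fwd)
    hv <- oracle_rotmat(stream$h_az[i], stream$h_el[i], 0) %*% fwd
    ha <- oracle_vec_angle(as.numeric(hv), fwd)
    if (u[i]) { eih <- eih + ea; n_eih <- n_eih + 1 }
    if (u[i] && (ea >= 0.5 || ha >= 0.5)) {
      propsum <- propsum + ea / (ea + ha); n_prop <- n_prop + 1
    }
    if (i < n && u[i] && u[i + 1]) {
      glob_e <- glob_e + oracle_vec_angle(dirs[i, ], dirs[i + 1, ])
    }
  }
  out <- c(out,
    avg_eye_in_head_angle = eih / n_eih,
    global_eye_movement_per_second = glob_e / duration,
    avg_eye_to_gaze_proportion = avg(propsum, n_prop))

  # kinematics (eye then head) with the package's masking conventions
  kin_block <- function(axes, speed1, effector) {
    vals <- c()
    ax <- axes; sp <- speed1
    mask <- oracle_erode(u)
    spm <- u & c(u[-1], u[n])
    for (ord in 1:3) {
      if (ord > 1) {
        for (j in 1:3) ax[, j] <- oracle_diff(ax[, j], dt)
        sp <- oracle_diff(sp, dt)
        mask <- oracle_erode(mask)
        spm <- oracle_erode(spm)
      }
      lab <- c("velocity", "acceleration", "jerk")[ord]
      spv <- sp; spv[!spm] <- NA
      axv <- ax; for (j in 1:3) axv[!mask, j] <- NA
      ov <- oracle_abs_stats(spv)
      xs <- oracle_abs_stats(axv[, 1]); ys <- oracle_abs_stats(axv[, 2])
      zs <- oracle_abs_stats(axv[, 3])
      block <- c(ov[1], ov[2], xs[1], ys[1], zs[1], xs[2], ys[2], zs[2])
      names(block) <- c(paste0(c("avg_", "std_"), effector, "_", lab),
                        paste0("avg_", effector, "_", lab, "_", c("x", "y", "z")),
                        paste0("std_", effector, "_", lab, "_", c("x", "y", "z")))
      vals <- c(vals, block)
    }
    vals
  }

  eye_axes <- matrix(NA_real_, n, 3)
  for (j in 1:3) eye_axes[, j] <- oracle_diff(dirs[, j] * 180 / pi, dt)
  eye_speed <- rep(NA_real_, n)
  for (i in seq_len(n - 1)) {
    eye_speed[i] <- oracle_vec_angle(dirs[i, ], dirs[i + 1, ]) * fs
  }
  eye_speed[n] <- eye_speed[n - 1]
  out <- c(out, kin_block(eye_axes, eye_speed, "eye"))

  # head events
  hm_amp <- 0
  for (k in seq_len(nrow(hm))) hm_amp <- hm_amp + hm$amplitude[k]
  hf_dur <- 0
  for (k in seq_len(nrow(hf))) hf_dur <- hf_dur + hf$duration[k]
  glob_h <- 0
  for (i in seq_len(n - 1)) {
    if (u[i] && u[i + 1]) {
      glob_h <- glob_h + oracle_rot_angle(
        stream$h_az[i], stream$h_el[i], stream$h_roll[i],
        stream$h_az[i + 1], stream$h_el[i + 1], stream$h_roll[i + 1])
    }
  }
  out <- c(out,
    head_movement_frequency = nrow(hm) / duration,
    avg_head_movement_size = avg(hm_amp, nrow(hm)),
    head_movement_size_per_second = hm_amp / duration,
    avg_head_fixation_duration = avg(hf_dur, nrow(hf)),
    head_fixation_duration_proportion = hf_dur / duration,
    head_fixation_frequency = nrow(hf) / duration,
    global_head_movement_per_second = glob_h / duration)

  head_axes <- matrix(NA_real_, n, 3)
  head_axes[, 1] <- oracle_diff(stream$h_el, dt)
  head_axes[, 2] <- oracle_diff(stream$h_az, dt)
  head_axes[, 3] <- oracle_diff(stream$h_roll, dt)
  head_speed <- rep(NA_real_, n)
  for (i in seq_len(n - 1)) {
    head_speed[i] <- oracle_rot_angle(
      stream$h_az[i], stream$h_el[i], stream$h_roll[i],
      stream$h_az[i + 1], stream$h_el[i + 1], stream$h_roll[i + 1]) * fs
  }
  head_speed[n] <- head_speed[n - 1]
  out <- c(out, kin_block(head_axes, head_speed, "head"))

  out[feature_schema()$name]
}

# Naive reference saccade detector: tests every sample against the ellipse
# and scans runs with an explicit loop.
naive_detect_saccades <- function(velocity, threshold, stream,
                                  min_dur = 0.012) {
  fs <- attr(velocity, "fs")
  n <- nrow(velocity)
  over <- logical(n); usable <- logical(n)
  for (i in seq_len(n)) {
    v <- c(velocity$x[i], velocity$y[i], velocity$z[i])
    usable[i] <- !any(is.na(v)) && !is.na(velocity$speed[i])
    over[i] <- usable[i] &&
      sum(((v - threshold$mu) / threshold$radius)^2) > 1
  }
  res <- list(); m <- 0; i <- 1
  while (i <= n) {
    if (over[i]) {
      j <- i
      while (j < n && over[j + 1]) j <- j + 1
      ok <- (j - i + 1) / fs >= min_dur
      if (i > 1 && !usable[i - 1]) ok <- FALSE
      if (j < n && !usable[j + 1]) ok <- FALSE
      if (ok) {
        a <- c(stream$ex[i], stream$ey[i], stream$ez[i])
        b <- c(stream$ex[j], stream$ey[j], stream$ez[j])
        m <- m + 1
        res[[m]] <- data.frame(
          onset_idx = i, offset_idx = j, duration = (j - i + 1) / fs,
          amplitude = oracle_vec_angle(a, b),
          peak_velocity = max(velocity$speed[i:j]))
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (m == 0) data.frame(onset_idx = integer(0), offset_idx = integer(0),
                         duration = numeric(0), amplitude = numeric(0),
                         peak_velocity = numeric(0))
  else do.call(rbind, res)
}
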
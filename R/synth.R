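# Synthetic foraging-session generator. Emulates a head-mounted-display
# foraging search session: a frontal-180-degree scene of camouflaged targets
# and distractors, a scanpath of fixations and main-sequence saccades, head
# recruitment for large gaze shifts, pupil dropouts, and per-condition shifts
# in movement statistics. Every generated trial carries exact ground-truth
# events so detector recovery can be measured.

#' Construct generator parameters for one task condition
#'
#' Bundles the generative knobs of the synthetic session generator for a
#' single cell of the 2 x 2 design (target discriminability x time pressure).
#' The trial time limit defaults to 45 s under Low and 18 s under High time
#' pressure, matching the task design the generator emulates.
#'
#' @param discriminability `"Easy"` or `"Hard"` target/distractor similarity.
#' @param pressure `"Low"` or `"High"` time pressure.
#' @param time_limit trial time limit in seconds (default 45 for Low, 18 for
#'   High pressure).
#' @param saccade_rate target gaze-shift rate in Hz; onset-to-onset intervals
#'   are lognormal with mean `1/saccade_rate` (clamped so fixations stay
#'   above the plausibility floor), so fixation durations are the interval
#'   minus the movement time.
#' @param amp_mean,amp_shape mean (deg) and shape of the gamma distribution of
#'   gaze-shift amplitudes.
#' @param amp_range truncation bounds (deg) for gaze-shift amplitudes.
#' @param fix_dur_cv coefficient of variation of the lognormal fixation
#'   duration distribution.
#' @param distractor_refix_p probability that a gaze shift targets a
#'   distractor rather than continuing target pursuit.
#' @param target_engage_p probability that a gaze shift seeks an unengaged
#'   target when one is available at a reachable eccentricity.
#' @param hit_p,fa_p per-fixation probability of shooting a fixated unshot
#'   target (hit) or distractor (false alarm).
#' @param head_recruit_deg eye-in-head eccentricity (deg) beyond which a gaze
#'   shift recruits a head movement. `Inf` disables head movements.
#' @param eye_vmax,eye_a0 main-sequence parameters for saccades: peak velocity
#'   is `eye_vmax * (1 - exp(-A / eye_a0))` deg/s at amplitude `A` deg.
#' @param head_vmax,head_a0 main-sequence parameters for head movements
#'   (slower and more prolonged than saccades).
#' @param eye_park_range range (deg) of the post-recruitment eye-in-head
#'   eccentricity: after a combined eye-head shift the eye settles at this
#'   eccentricity so eye-in-head stays within roughly 15 deg of head centre.
#' @param min_saccade_deg minimum eye-saccade amplitude (deg); a recruited
#'   shift whose eye component would be smaller becomes a head-only gaze
#'   shift with the eye stable in the head.
#' @param eye_noise_deg,head_noise_deg per-sample angular jitter SD (deg).
#' @param pupil_mm,pupil_noise_mm simulated pupil diameter mean and SD (mm).
#' @param dropout_rate expected tracking dropouts per second (see
#'   [inject_dropouts()]).
#' @param dropout_dur range (s) of dropout durations.
#' @param eye_rate,head_rate nominal sampling rates (Hz) of the eye and head
#'   streams.
#' @return an object of class `condition_params`.
#' @export
condition_params <- function(discriminability = c("Easy", "Hard"),
                             pressure = c("Low", "High"),
                             time_limit = NULL,
                             saccade_rate = 2.2,
                             amp_mean = 10, amp_shape = 6,
                             amp_range = c(1.5, 40),
                             fix_dur_cv = 0.45,
                             distractor_refix_p = 0.15,
                             target_engage_p = 0.75,
                             hit_p = 0.95, fa_p = 0.03,
                             head_recruit_deg = 16,
                             eye_vmax = 600, eye_a0 = 14,
                             head_vmax = 260, head_a0 = 25,
                             eye_park_range = c(4, 12),
                             min_saccade_deg = 1.2,
                             eye_noise_deg = 0.03, head_noise_deg = 0.02,
                             pupil_mm = 3, pupil_noise_mm = 0.05,
                             dropout_rate = 0.05, dropout_dur = c(0.008, 0.12),
                             eye_rate = 120, head_rate = 90) {
  discriminability <- match.arg(discriminability)
  pressure <- match.arg(pressure)
  if (is.null(time_limit)) time_limit <- if (pressure == "Low") 45 else 18
  stopifnot(
    time_limit > 0, saccade_rate > 0, amp_mean > 0, amp_shape > 0,
    fix_dur_cv > 0, length(amp_range) == 2, amp_range[1] > 1,
    hit_p >= 0, hit_p <= 1, fa_p >= 0, fa_p <= 1,
    distractor_refix_p >= 0, distractor_refix_p <= 1,
    target_engage_p >= 0, target_engage_p <= 1,
    head_recruit_deg > 0, dropout_rate >= 0
  )
  if (1 / saccade_rate <= 0.15) {
    stop("saccade_rate too high: mean inter-saccade interval must exceed 150 ms")
  }
  structure(list(
    discriminability = discriminability, pressure = pressure,
    time_limit = time_limit, saccade_rate = saccade_rate,
    fix_dur_cv = fix_dur_cv,
    amp_mean = amp_mean, amp_shape = amp_shape, amp_range = amp_range,
    distractor_refix_p = distractor_refix_p, target_engage_p = target_engage_p,
    hit_p = hit_p, fa_p = fa_p,
    head_recruit_deg = head_recruit_deg,
    eye_vmax = eye_vmax, eye_a0 = eye_a0,
    head_vmax = head_vmax, head_a0 = head_a0,
    eye_park_range = eye_park_range, min_saccade_deg = min_saccade_deg,
    eye_noise_deg = eye_noise_deg, head_noise_deg = head_noise_deg,
    pupil_mm = pupil_mm, pupil_noise_mm = pupil_noise_mm,
    dropout_rate = dropout_rate, dropout_dur = dropout_dur,
    eye_rate = eye_rate, head_rate = head_rate
  ), class = "condition_params")
}

#' Default study conditions for the 2 x 2 design
#'
#' Returns the four `condition_params` cells used as the study conditions of
#' the synthetic dataset. The shifts follow the qualitative direction of
#' foraging findings: harder discrimination slows and focalizes search (longer
#' fixations, smaller saccades, more distractor refixations, lower hit and
#' higher false-alarm probability, steadier head) while high time pressure
#' speeds it up (higher saccade rate, larger shifts, earlier head recruitment,
#' faster head movements).
#'
#' @return named list with elements `EasyLow`, `EasyHigh`, `HardLow`,
#'   `HardHigh`.
#' @export
default_condition_params <- function() {
  list(
    EasyLow = condition_params("Easy", "Low",
      saccade_rate = 2.2, amp_mean = 10, distractor_refix_p = 0.15,
      target_engage_p = 0.75, hit_p = 0.95, fa_p = 0.03,
      head_recruit_deg = 16, head_vmax = 270),
    EasyHigh = condition_params("Easy", "High",
      saccade_rate = 2.9, amp_mean = 12, distractor_refix_p = 0.12,
      target_engage_p = 0.85, hit_p = 0.90, fa_p = 0.06,
      head_recruit_deg = 13, head_vmax = 300),
    HardLow = condition_params("Hard", "Low",
      saccade_rate = 1.9, amp_mean = 8, distractor_refix_p = 0.45,
      target_engage_p = 0.55, hit_p = 0.80, fa_p = 0.18,
      head_recruit_deg = 17, head_vmax = 255),
    HardHigh = condition_params("Hard", "High",
      saccade_rate = 2.6, amp_mean = 9.5, distractor_refix_p = 0.40,
      target_engage_p = 0.70, hit_p = 0.70, fa_p = 0.28,
      head_recruit_deg = 14.5, head_vmax = 285)
  )
}

#' Null study conditions (no condition effects)
#'
#' All four cells share identical generative parameters, so condition labels
#' are independent of every feature by construction. Used to calibrate chance
#' performance of the classifiers.
#'
#' @param time_limit common time limit in seconds for all cells.
#' @return named list of four identical-parameter `condition_params` cells.
#' @export
null_condition_params <- function(time_limit = 18) {
  cells <- list(c("Easy", "Low"), c("Easy", "High"),
                c("Hard", "Low"), c("Hard", "High"))
  out <- lapply(cells, function(cl) {
    condition_params(cl[1], cl[2], time_limit = time_limit,
      saccade_rate = 2.4, amp_mean = 10, distractor_refix_p = 0.2,
      target_engage_p = 0.85, hit_p = 0.95, fa_p = 0.05,
      head_recruit_deg = 15, head_vmax = 280)
  })
  names(out) <- c("EasyLow", "EasyHigh", "HardLow", "HardHigh")
  out
}

#' Noise-free sparse-scanning condition for detector validation
#'
#' A clean configuration for ground-truth recovery tests: zero angular jitter,
#' no dropouts, sparse large saccades with fast dynamics. Event spacing and
#' amplitudes are chosen so that the participant-adaptive elliptical velocity
#' threshold (whose variance is dominated by the saccade samples themselves on
#' noise-free data) stays well below every injected peak velocity, making the
#' recovery test well-posed.
#'
#' @return a `condition_params` object.
#' @export
clean_condition_params <- function() {
  condition_params("Easy", "Low",
    saccade_rate = 0.5, amp_mean = 15, amp_shape = 30, amp_range = c(10, 28),
    eye_vmax = 900, eye_a0 = 10, head_vmax = 350, head_a0 = 15,
    head_recruit_deg = 14, min_saccade_deg = 8,
    eye_noise_deg = 0, head_noise_deg = 0,
    pupil_noise_mm = 0, dropout_rate = 0, distractor_refix_p = 0.2,
    target_engage_p = 0.6, hit_p = 0.3, fa_p = 0)
}

#' Generate a scene layout
#'
#' A scene holds 12 to 18 targets (uniformly distributed count) and exactly 12
#' distractors, spawned within the frontal 180 degrees at distances between 10
#' and 100 m.
#'
#' @param seed integer seed; scenes are deterministic given the seed.
#' @param n_targets optional fixed target count (must lie in 12..18).
#' @return object of class `scene_layout` with a data.frame `objects`
#'   (columns `id`, `kind`, `az`, `el`, `dist`).
#' @export
generate_scene <- function(seed, n_targets = NULL) {
  with_seed(seed, {
    if (is.null(n_targets)) n_targets <- sample(12:18, 1)
    stopifnot(n_targets >= 12, n_targets <= 18)
    n_distractors <- 12
    n <- n_targets + n_distractors
    objects <- data.frame(
      id = seq_len(n),
      kind = c(rep("target", n_targets), rep("distractor", n_distractors)),
      az = stats::runif(n, -90, 90),
      el = stats::runif(n, -8, 4),
      dist = stats::runif(n, 10, 100),
      stringsAsFactors = FALSE
    )
    structure(list(objects = objects, n_targets = n_targets,
                   n_distractors = n_distractors, seed = seed),
              class = "scene_layout")
  })
}

# Saturating main sequence: peak velocity (deg/s) as a function of amplitude.
main_sequence_vpeak <- function(amplitude, vmax, a0) {
  vmax * (1 - exp(-amplitude / a0))
}

# Movement duration implied by a minimum-jerk profile whose peak speed follows
# the main sequence; capped so saccades stay within plausible duration bounds.
movement_duration <- function(amplitude, vmax, a0, cap = Inf) {
  vp <- main_sequence_vpeak(amplitude, vmax, a0)
  pmin(cap, 1.875 * amplitude / vp)
}

rtrunc_gamma <- function(n, shape, mean, range) {
  rate <- shape / mean
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rgamma(2 * n + 8, shape = shape, rate = rate)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

rtrunc_lnorm <- function(n, mean, cv, range = c(0.08, 3)) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * n + 8, meanlog, sdlog)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Generate one synthetic foraging trial
#'
#' Simulates a scanpath of alternating fixations and saccades over the scene.
#' Saccade peak velocities follow a saturating main-sequence function of
#' amplitude, trajectories are minimum-jerk ramps, and gaze shifts that would
#' push the eye beyond the head-recruitment eccentricity trigger a concurrent,
#' slower head movement that re-centres the eye in the head. The trial ends at
#' the completion button press (all targets shot plus a decision delay) or at
#' the time limit, whichever comes first.
#'
#' @param condition a [condition_params()] object.
#' @param scene a [generate_scene()] layout.
#' @param seed integer seed; trials are deterministic given the seed.
#' @param participant,trial identifiers stored in the trial record.
#' @return object of class `foraging_trial`: list with elements
#'   * `eye`: data.frame at `eye_rate` Hz with `t`, raw eye-in-head unit
#'     vector `x`,`y`,`z` (recorded with +X left, as HMD eye trackers report),
#'     `pupil`, `gazed_object_id`, `gazed_object_kind`;
#'   * `head`: data.frame at `head_rate` Hz with `t`, `yaw`, `pitch`, `roll`
#'     in degrees (positive yaw rightward, positive pitch downward);
#'   * `record`: trial metadata (condition labels, duration, end cause, shot
#'     events, scene counts);
#'   * `truth`: injected ground-truth events (saccades, fixations, head
#'     movements, dropouts) with exact onset/offset times.
#' @export
generate_trial <- function(condition, scene, seed, participant = 1L, trial = 1L) {
  stopifnot(inherits(condition, "condition_params"))
  if (!inherits(scene, "scene_layout") || nrow(scene$objects) == 0) {
    stop("scene must be a non-empty scene_layout")
  }
  p <- condition
  with_seed(seed, {
    objs <- scene$objects
    obj_vec <- azel_to_vec(objs$az, objs$el)
    is_target <- objs$kind == "target"
    shot <- rep(FALSE, nrow(objs))
    limit <- p$time_limit

    g <- c(0, 0)   # gaze az/el (deg, world)
    h <- c(0, 0)   # head az/el
    t <- stats::runif(1, 0.15, 0.35)  # first-saccade latency from scene onset
    sacc <- vector("list", 256); n_s <- 0
    hmov <- vector("list", 256); n_h <- 0
    fixs <- vector("list", 256); n_f <- 0
    shots <- vector("list", 64); n_shot <- 0
    fix_start <- 0; fix_obj <- NA_integer_
    end_cause <- "timeout"; duration <- limit; last_shot_t <- NA_real_
    button_t <- Inf  # decided once all targets are down; scanning continues

    repeat {
      eff_limit <- min(limit, button_t)
      e <- g - h
      # --- choose the next gaze point ---
      A <- rtrunc_gamma(1, p$amp_shape, p$amp_mean, p$amp_range)
      gv <- azel_to_vec(g[1], g[2])
      dist_to <- angle_between(
        matrix(gv, nrow(objs), 3, byrow = TRUE), obj_vec)
      band <- dist_to >= 0.55 * A & dist_to <= 1.45 * A
      pick <- NA_integer_
      step_toward <- NA_integer_
      u <- stats::runif(1)
      cand_t <- which(band & is_target & !shot)
      cand_d <- which(band & !is_target)
      cand_any <- which(band)
      if (u < p$target_engage_p) {
        if (length(cand_t) > 0) {
          pick <- cand_t[sample.int(length(cand_t), 1)]
        } else if (any(is_target & !shot)) {
          # pursue the nearest remaining target: jump to it if reachable,
          # otherwise traverse toward it with an amplitude-A saccade
          left <- which(is_target & !shot)
          nearest <- left[which.min(dist_to[left])]
          if (dist_to[nearest] <= p$amp_range[2]) pick <- nearest
          else step_toward <- nearest
        }
      } else if (u < p$target_engage_p + p$distractor_refix_p &&
                 length(cand_d) > 0) {
        pick <- cand_d[sample.int(length(cand_d), 1)]
      } else if (length(cand_any) > 0 && stats::runif(1) < 0.8) {
        pick <- cand_any[sample.int(length(cand_any), 1)]
      }
      if (!is.na(pick)) {
        g_new <- c(objs$az[pick] + stats::rnorm(1, 0, 0.3),
                   objs$el[pick] + stats::rnorm(1, 0, 0.3))
      } else if (!is.na(step_toward)) {
        dir <- c(objs$az[step_toward], objs$el[step_toward]) - g
        g_new <- g + A * dir / sqrt(sum(dir^2))
      } else {
        th <- stats::runif(1, 0, 2 * pi)
        g_new <- g + A * c(cos(th), sin(th))
      }
      g_new[1] <- min(88, max(-88, g_new[1]))
      g_new[2] <- min(20, max(-25, g_new[2]))
      dG <- g_new - g
      if (sqrt(sum(dG^2)) < p$amp_range[1]) next

      # --- split the shift between eye and head ---
      e_t <- e + dG
      if (sqrt(sum(e_t^2)) > p$head_recruit_deg) {
        park <- stats::runif(1, p$eye_park_range[1], p$eye_park_range[2])
        e_fin <- e_t / sqrt(sum(e_t^2)) * park
        dE <- e_fin - e
        if (sqrt(sum(dE^2)) < p$min_saccade_deg) {
          dE <- c(0, 0)  # head-only gaze shift, eye stable in the head
        }
        dH <- dG - dE
        if (sqrt(sum(dH^2)) <= 1.5 && any(dE != 0)) { dH <- c(0, 0); dE <- dG }
      } else {
        dE <- dG; dH <- c(0, 0)
      }

      A_e <- sqrt(sum(dE^2))
      D_e <- if (A_e > 0) movement_duration(A_e, p$eye_vmax, p$eye_a0, cap = 0.118) else 0
      A_h <- sqrt(sum(dH^2))
      D_h <- if (A_h > 0) movement_duration(A_h, p$head_vmax, p$head_a0) else 0
      move_end <- t + max(D_e, D_h)
      if (move_end + 0.075 > eff_limit) break

      # close the previous fixation, record the movement(s)
      n_f <- n_f + 1
      fixs[[n_f]] <- c(onset = fix_start, offset = t, obj = fix_obj)
      if (A_e > 0) {
        n_s <- n_s + 1
        sacc[[n_s]] <- c(onset = t, duration = D_e, amplitude = A_e,
                         vpeak = 1.875 * A_e / D_e,
                         daz = dE[1], del = dE[2])
      }
      if (A_h > 0) {
        vp_h <- 1.875 * A_h / D_h
        tau1 <- minimum_jerk_crossing(6 / vp_h)
        n_h <- n_h + 1
        hmov[[n_h]] <- c(onset = t, duration = D_h, amplitude = A_h,
                         vpeak = vp_h, daz = dH[1], del = dH[2],
                         cross_on = t + tau1 * D_h,
                         cross_off = t + (1 - tau1) * D_h)
      }
      g <- g_new; h <- h + dH
      fix_start <- t + D_e; fix_obj <- if (is.na(pick)) NA_integer_ else pick

      interval <- rtrunc_lnorm(1, 1 / p$saccade_rate, p$fix_dur_cv,
                               range = c(0.09, 8))
      t_next <- t + max(interval, D_e + 0.08,
                        if (A_h > 0) D_h + 0.09 else 0)
      fix_avail <- t_next - move_end

      # --- engagement: shoot fixated objects ---
      if (!is.na(pick) && !shot[pick]) {
        if (is_target[pick] && stats::runif(1) < p$hit_p) {
          st <- move_end + stats::runif(1, 0.08, max(0.1, 0.6 * fix_avail))
          if (st < eff_limit) {
            shot[pick] <- TRUE
            n_shot <- n_shot + 1
            shots[[n_shot]] <- list(time = st, object_id = objs$id[pick],
                                    kind = "target", outcome = "hit")
            last_shot_t <- st
          }
        } else if (!is_target[pick] && stats::runif(1) < p$fa_p) {
          st <- move_end + stats::runif(1, 0.08, max(0.1, 0.6 * fix_avail))
          if (st < eff_limit) {
            shot[pick] <- TRUE
            n_shot <- n_shot + 1
            shots[[n_shot]] <- list(time = st, object_id = objs$id[pick],
                                    kind = "distractor", outcome = "false_alarm")
          }
        }
      }

      if (!is.finite(button_t) && all(shot[is_target])) {
        button_t <- last_shot_t + stats::runif(1, 0.4, 1.2)
      }
      if (t_next >= min(limit, button_t)) break
      t <- t_next
    }
    if (button_t <= limit) {
      duration <- button_t; end_cause <- "button"
    } else {
      duration <- limit
    }
    n_f <- n_f + 1
    fixs[[n_f]] <- c(onset = fix_start, offset = duration, obj = fix_obj)

    sacc_df <- as.data.frame(do.call(rbind, sacc[seq_len(n_s)]))
    hmov_df <- as.data.frame(do.call(rbind, hmov[seq_len(n_h)]))
    fix_df <- as.data.frame(do.call(rbind, fixs[seq_len(n_f)]))
    if (n_s == 0) sacc_df <- data.frame(onset = numeric(0), duration = numeric(0),
      amplitude = numeric(0), vpeak = numeric(0), daz = numeric(0), del = numeric(0))
    if (n_h == 0) hmov_df <- data.frame(onset = numeric(0), duration = numeric(0),
      amplitude = numeric(0), vpeak = numeric(0), daz = numeric(0), del = numeric(0),
      cross_on = numeric(0), cross_off = numeric(0))

    # --- sample the streams ---
    n_e <- floor(duration * p$eye_rate) + 1
    t_e <- (seq_len(n_e) - 1) / p$eye_rate
    n_hs <- floor(duration * p$head_rate) + 1
    t_h <- (seq_len(n_hs) - 1) / p$head_rate

    ramp_sum <- function(tt, ev) {
      az <- numeric(length(tt)); el <- numeric(length(tt))
      if (nrow(ev) > 0) {
        for (k in seq_len(nrow(ev))) {
          m <- minimum_jerk((tt - ev$onset[k]) / ev$duration[k])
          az <- az + ev$daz[k] * m
          el <- el + ev$del[k] * m
        }
      }
      cbind(az, el)
    }

    eh_eye <- ramp_sum(t_e, sacc_df)       # eye-in-head az/el on the eye clock
    hd_eye <- ramp_sum(t_e, hmov_df)       # head az/el on the eye clock (labels)
    hd_head <- ramp_sum(t_h, hmov_df)      # head az/el on the head clock

    if (p$eye_noise_deg > 0) {
      eh_eye <- eh_eye + matrix(stats::rnorm(2 * n_e, 0, p$eye_noise_deg), ncol = 2)
    }
    hd_noise <- if (p$head_noise_deg > 0) {
      matrix(stats::rnorm(3 * n_hs, 0, p$head_noise_deg), ncol = 3)
    } else matrix(0, n_hs, 3)

    eye_vec <- azel_to_vec(eh_eye[, 1], eh_eye[, 2])
    gaze <- azel_to_vec(eh_eye[, 1] + hd_eye[, 1], eh_eye[, 2] + hd_eye[, 2])
    dots <- gaze %*% t(obj_vec)
    best <- max.col(dots, ties.method = "first")
    best_ang <- rad2deg(acos(pmin(1, dots[cbind(seq_len(n_e), best)])))
    gid <- ifelse(best_ang < 2, objs$id[best], NA_integer_)
    gkind <- ifelse(best_ang < 2, objs$kind[best], "none")

    pupil <- p$pupil_mm + if (p$pupil_noise_mm > 0)
      stats::rnorm(n_e, 0, p$pupil_noise_mm) else 0

    eye <- data.frame(
      t = t_e,
      x = -eye_vec[, 1],   # recorded frame has +X left
      y = eye_vec[, 2],
      z = eye_vec[, 3],
      pupil = pupil,
      gazed_object_id = gid,
      gazed_object_kind = gkind,
      stringsAsFactors = FALSE
    )
    head <- data.frame(
      t = t_h,
      yaw = hd_head[, 1] + hd_noise[, 1],
      pitch = -(hd_head[, 2] + hd_noise[, 2]),  # recorded pitch is positive down
      roll = hd_noise[, 3]
    )

    idx_after <- function(x) findInterval(x + 1e-12, t_e) + 1L
    idx_before <- function(x) findInterval(x - 1e-12, t_e)
    truth <- list(
      saccades = data.frame(
        onset = sacc_df$onset, offset = sacc_df$onset + sacc_df$duration,
        duration = sacc_df$duration, amplitude = sacc_df$amplitude,
        vpeak = sacc_df$vpeak,
        onset_idx = if (n_s) idx_after(sacc_df$onset) else integer(0),
        offset_idx = if (n_s) idx_before(sacc_df$onset + sacc_df$duration) else integer(0)
      ),
      fixations = data.frame(
        onset = fix_df$onset, offset = fix_df$offset,
        object_id = ifelse(is.na(fix_df$obj), NA_integer_, objs$id[fix_df$obj])
      ),
      head_movements = data.frame(
        onset = hmov_df$onset, offset = hmov_df$onset + hmov_df$duration,
        duration = hmov_df$duration, amplitude = hmov_df$amplitude,
        vpeak = hmov_df$vpeak,
        cross_on = hmov_df$cross_on, cross_off = hmov_df$cross_off
      ),
      dropouts = data.frame(start = numeric(0), end = numeric(0))
    )

    record <- list(
      participant = participant, trial = trial,
      discriminability = p$discriminability, pressure = p$pressure,
      time_limit = limit, duration = duration, end_cause = end_cause,
      n_targets = scene$n_targets, n_distractors = scene$n_distractors,
      shots = if (n_shot > 0) do.call(rbind, lapply(shots[seq_len(n_shot)],
        as.data.frame)) else data.frame(time = numeric(0),
        object_id = integer(0), kind = character(0), outcome = character(0)),
      seed = seed
    )

    structure(list(eye = eye, head = head, record = record, truth = truth,
                   scene = scene, condition = p),
              class = "foraging_trial")
  })
}

#' Inject tracking dropouts into a trial's eye stream
#'
#' Emulates eye-tracker signal loss by setting pupil diameter to zero over
#' random intervals; downstream validity marking treats those samples as
#' invalid. Intervals are recorded in the trial's ground truth.
#'
#' @param trial a `foraging_trial`.
#' @param rate expected dropouts per second (Poisson count over the trial).
#' @param dur_range dropout duration range in seconds.
#' @param seed integer seed.
#' @return the modified `foraging_trial`.
#' @export
inject_dropouts <- function(trial, rate, dur_range = c(0.008, 0.12), seed = 1) {
  stopifnot(inherits(trial, "foraging_trial"))
  if (rate < 0) stop("dropout rate must be non-negative")
  if (rate == 0) return(trial)
  with_seed(seed, {
    dur <- trial$record$duration
    k <- stats::rpois(1, rate * dur)
    if (k > 0) {
      starts <- sort(stats::runif(k, 0, dur))
      lens <- stats::runif(k, dur_range[1], dur_range[2])
      ends <- pmin(starts + lens, dur)
      for (i in seq_len(k)) {
        sel <- trial$eye$t >= starts[i] & trial$eye$t < ends[i]
        trial$eye$pupil[sel] <- 0
      }
      trial$truth$dropouts <- rbind(trial$truth$dropouts,
                                    data.frame(start = starts, end = ends))
    }
    trial
  })
}

# Per-participant tendency multipliers (e.g. "head movers" recruit earlier).
participant_jitter <- function(sd_general = 0.1, sd_head = 0.25) {
  list(
    rate = stats::rlnorm(1, 0, sd_general),
    amp = stats::rlnorm(1, 0, sd_general),
    recruit = stats::rlnorm(1, 0, sd_head),
    head_v = stats::rlnorm(1, 0, sd_general)
  )
}

apply_jitter <- function(p, j) {
  condition_params(
    p$discriminability, p$pressure, time_limit = p$time_limit,
    saccade_rate = p$saccade_rate * j$rate,
    amp_mean = p$amp_mean * j$amp, amp_shape = p$amp_shape,
    amp_range = p$amp_range, fix_dur_cv = p$fix_dur_cv,
    distractor_refix_p = p$distractor_refix_p,
    target_engage_p = p$target_engage_p,
    hit_p = p$hit_p, fa_p = p$fa_p,
    head_recruit_deg = p$head_recruit_deg * j$recruit,
    eye_vmax = p$eye_vmax, eye_a0 = p$eye_a0,
    head_vmax = p$head_vmax * j$head_v, head_a0 = p$head_a0,
    eye_park_range = p$eye_park_range, min_saccade_deg = p$min_saccade_deg,
    eye_noise_deg = p$eye_noise_deg, head_noise_deg = p$head_noise_deg,
    pupil_mm = p$pupil_mm, pupil_noise_mm = p$pupil_noise_mm,
    dropout_rate = p$dropout_rate, dropout_dur = p$dropout_dur,
    eye_rate = p$eye_rate, head_rate = p$head_rate
  )
}

#' Generate the trials of one synthetic participant
#'
#' Draws the participant's tendency multipliers once, then generates
#' `trials_per_cell` trials in each of the four conditions, each with its own
#' scene.
#'
#' @param participant participant id.
#' @param params_by_condition named list of four [condition_params()] objects
#'   (`EasyLow`, `EasyHigh`, `HardLow`, `HardHigh`).
#' @param trials_per_cell trials per condition cell.
#' @param seed integer seed.
#' @param jitter_sd SD of the lognormal per-participant multipliers (general,
#'   head-tendency).
#' @return list of `foraging_trial` objects.
#' @export
simulate_participant <- function(participant, params_by_condition,
                                 trials_per_cell, seed,
                                 jitter_sd = c(0.1, 0.25)) {
  stopifnot(trials_per_cell >= 1)
  with_seed(seed, {
    j <- participant_jitter(jitter_sd[1], jitter_sd[2])
    cells <- names(params_by_condition)
    seeds <- matrix(sample.int(.Machine$integer.max - 1,
                               2 * length(cells) * trials_per_cell),
                    ncol = 2)
    trials <- vector("list", length(cells) * trials_per_cell)
    k <- 0
    for (ci in seq_along(cells)) {
      pj <- apply_jitter(params_by_condition[[ci]], j)
      for (tr in seq_len(trials_per_cell)) {
        k <- k + 1
        scene <- generate_scene(seeds[k, 1])
        trial <- generate_trial(pj, scene, seeds[k, 2],
                                participant = participant, trial = k)
        if (pj$dropout_rate > 0) {
          trial <- inject_dropouts(trial, pj$dropout_rate, pj$dropout_dur,
                                   seed = seeds[k, 2] %% 1000003L + 1L)
        }
        trials[[k]] <- trial
      }
    }
    trials
  })
}

#' Generate a balanced synthetic dataset
#'
#' A balanced 2 x 2 design per participant with per-participant parameter
#' jitter drawn once per participant.
#'
#' @inheritParams simulate_participant
#' @param n_participants number of participants.
#' @param seed master integer seed.
#' @return list with `trials` (list of `foraging_trial`) and `index`
#'   (data.frame of participant, trial, condition labels).
#' @export
generate_dataset <- function(n_participants, trials_per_cell,
                             params_by_condition = default_condition_params(),
                             seed = 1, jitter_sd = c(0.1, 0.25)) {
  stopifnot(trials_per_cell >= 1, n_participants >= 1)
  pseeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_participants))
  trials <- list()
  for (pid in seq_len(n_participants)) {
    trials <- c(trials, simulate_participant(pid, params_by_condition,
                                             trials_per_cell, pseeds[pid],
                                             jitter_sd))
  }
  index <- do.call(rbind, lapply(trials, function(tr) data.frame(
    participant = tr$record$participant, trial = tr$record$trial,
    discriminability = tr$record$discriminability,
    pressure = tr$record$pressure,
    duration = tr$record$duration, end_cause = tr$record$end_cause,
    stringsAsFactors = FALSE)))
  list(trials = trials, index = index)
}
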
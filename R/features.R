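# Trial-level feature battery: 45 eye features (fixation, saccade,
# eye-head coordination, kinematics) and 31 head features (events,
# kinematics), one vector per trial. Count- and sum-based features are
# normalized by trial duration so trials of different lengths are comparable.

#' The feature schema
#'
#' Names, effector assignment and group of the 76 trial-level features, in the
#' stable column order used by [assemble_features()].
#'
#' @return data.frame with columns `name`, `effector` (`"eye"`/`"head"`) and
#'   `group`.
#' @export
feature_schema <- function() {
  kin <- function(eff) {
    out <- character(0)
    for (ord in c("velocity", "acceleration", "jerk")) {
      out <- c(out,
               paste0(c("avg_", "std_"), eff, "_", ord),
               paste0("avg_", eff, "_", ord, "_", c("x", "y", "z")),
               paste0("std_", eff, "_", ord, "_", c("x", "y", "z")))
    }
    out
  }
  eye_fix <- c("fixation_frequency", "avg_fixation_duration",
               "fixation_duration_proportion",
               "target_fixation_frequency", "avg_target_fixation_duration",
               "target_fixation_duration_proportion",
               "distractor_fixation_frequency", "avg_distractor_fixation_duration",
               "distractor_fixation_duration_proportion",
               "target_fixations_per_target", "distractor_fixations_per_distractor",
               "target_distractor_fixation_ratio",
               "target_distractor_fixation_duration_ratio")
  sac <- c("saccade_frequency", "avg_saccade_size", "saccade_size_per_second",
           "avg_target_saccade_size", "avg_distractor_saccade_size")
  coord <- c("avg_eye_in_head_angle", "global_eye_movement_per_second",
             "avg_eye_to_gaze_proportion")
  head_ev <- c("head_movement_frequency", "avg_head_movement_size",
               "head_movement_size_per_second", "avg_head_fixation_duration",
               "head_fixation_duration_proportion", "head_fixation_frequency",
               "global_head_movement_per_second")
  data.frame(
    name = c(eye_fix, sac, coord, kin("eye"), head_ev, kin("head")),
    effector = c(rep("eye", length(eye_fix) + length(sac) + length(coord) + 24),
                 rep("head", length(head_ev) + 24)),
    group = c(rep("fixation", length(eye_fix)), rep("saccade", length(sac)),
              rep("coordination", length(coord)), rep("eye_kinematic", 24),
              rep("head_event", length(head_ev)), rep("head_kinematic", 24)),
    stringsAsFactors = FALSE
  )
}

#' Names of the eye-only or head-only feature subsets
#' @param effector `"eye"` or `"head"`.
#' @return character vector of feature names.
#' @export
feature_subset <- function(effector = c("eye", "head")) {
  effector <- match.arg(effector)
  sc <- feature_schema()
  sc$name[sc$effector == effector]
}

mean0 <- function(x) if (length(x) == 0) 0 else mean(x)

#' Fixation features of one trial
#'
#' Frequency, average duration and duration proportion overall and split by
#' fixated object kind, fixations per available target/distractor, and two
#' target-preference ratios: a count-based ratio (target fixations over other
#' fixations) and its duration-based analogue. Empty subsets contribute zeros
#' so the feature matrix stays dense.
#'
#' @param fixations labeled fixation data.frame (see
#'   [label_fixation_objects()]).
#' @param duration trial duration in seconds (> 0).
#' @param n_targets,n_distractors scene object counts.
#' @param ratio_mode denominator of the target-preference ratios: all
#'   non-target fixations (`"other"`, default) or distractor fixations only
#'   (`"distractor"`).
#' @param empty value emitted for averages over empty subsets (0 keeps the
#'   feature matrix dense; `NA_real_` leaves them missing).
#' @return named numeric vector of 13 values.
#' @export
fixation_features <- function(fixations, duration, n_targets, n_distractors,
                              ratio_mode = c("other", "distractor"),
                              empty = 0) {
  if (duration <= 0) stop("trial duration must be positive")
  ratio_mode <- match.arg(ratio_mode)
  f <- fixations
  tf <- f[f$object_kind == "target", , drop = FALSE]
  df_ <- f[f$object_kind == "distractor", , drop = FALSE]
  if (ratio_mode == "other") {
    other_n <- nrow(f) - nrow(tf)
    other_dur <- sum(f$duration) - sum(tf$duration)
  } else {
    other_n <- nrow(df_)
    other_dur <- sum(df_$duration)
  }
  avg <- function(x) if (length(x) == 0) empty else mean(x)
  c(
    fixation_frequency = nrow(f) / duration,
    avg_fixation_duration = avg(f$duration),
    fixation_duration_proportion = sum(f$duration) / duration,
    target_fixation_frequency = nrow(tf) / duration,
    avg_target_fixation_duration = avg(tf$duration),
    target_fixation_duration_proportion = sum(tf$duration) / duration,
    distractor_fixation_frequency = nrow(df_) / duration,
    avg_distractor_fixation_duration = avg(df_$duration),
    distractor_fixation_duration_proportion = sum(df_$duration) / duration,
    target_fixations_per_target = nrow(tf) / n_targets,
    distractor_fixations_per_distractor = nrow(df_) / n_distractors,
    target_distractor_fixation_ratio = nrow(tf) / max(1, other_n),
    target_distractor_fixation_duration_ratio =
      sum(tf$duration) / max(other_dur, 0.075)
  )
}

#' Attribute each saccade to the object of the following fixation
#'
#' @param saccades filtered saccade data.frame.
#' @param fixations labeled fixation data.frame.
#' @return the saccades with an `object_kind` column (`"none"` when no
#'   labeled fixation follows).
#' @export
attribute_saccade_objects <- function(saccades, fixations) {
  saccades$object_kind <- rep("none", nrow(saccades))
  if (nrow(fixations) == 0) return(saccades)
  for (k in seq_len(nrow(saccades))) {
    nxt <- which(fixations$onset_idx > saccades$offset_idx[k])
    if (length(nxt)) saccades$object_kind[k] <- fixations$object_kind[nxt[1]]
  }
  saccades
}

#' Saccade features of one trial
#'
#' Frequency, average size, summed size per second, and the average size of
#' saccades landing on targets and on distractors (destination taken from the
#' following fixation's label). All five are 0 when the trial has no
#' surviving saccades.
#'
#' @param saccades filtered saccades with an `object_kind` column (see
#'   [attribute_saccade_objects()]).
#' @param duration trial duration in seconds.
#' @param empty value emitted for averages over empty subsets.
#' @return named numeric vector of 5 values.
#' @export
saccade_features <- function(saccades, duration, empty = 0) {
  s <- saccades
  avg <- function(x) if (length(x) == 0) empty else mean(x)
  c(
    saccade_frequency = nrow(s) / duration,
    avg_saccade_size = avg(s$amplitude),
    saccade_size_per_second = sum(s$amplitude) / duration,
    avg_target_saccade_size =
      avg(s$amplitude[s$object_kind == "target"]),
    avg_distractor_saccade_size =
      avg(s$amplitude[s$object_kind == "distractor"])
  )
}

#' Head event features of one trial
#'
#' Head-movement frequency/size statistics, head-fixation duration statistics,
#' and the classification-independent global head movement per second (total
#' angular path length of the head divided by trial time).
#'
#' @param movements,head_fixations head event data.frames.
#' @param stream the `aligned_stream` (for the global path length).
#' @param duration trial duration in seconds.
#' @return named numeric vector of 7 values.
#' @export
head_event_features <- function(movements, head_fixations, stream, duration) {
  disp <- consecutive_rotation_angles(stream$h_az, stream$h_el, stream$h_roll)
  u <- stream$usable
  disp <- disp[u[-length(u)] & u[-1]]
  c(
    head_movement_frequency = nrow(movements) / duration,
    avg_head_movement_size = mean0(movements$amplitude),
    head_movement_size_per_second = sum(movements$amplitude) / duration,
    avg_head_fixation_duration = mean0(head_fixations$duration),
    head_fixation_duration_proportion = sum(head_fixations$duration) / duration,
    head_fixation_frequency = nrow(head_fixations) / duration,
    global_head_movement_per_second = sum(disp) / duration
  )
}

#' Eye-head coordination features of one trial
#'
#' Average eye-in-head angle (eye eccentricity from the head's forward axis),
#' the classification-independent global eye movement per second, and the
#' average proportion of eye contribution to the gaze angle (gaze angle = eye
#' angle + head angle, both measured from the forward reference; samples
#' where both are below 0.5 degrees are skipped).
#'
#' @param stream the `aligned_stream`.
#' @param duration trial duration in seconds.
#' @return named numeric vector of 3 values.
#' @export
coordination_features <- function(stream, duration) {
  u <- stream$usable
  if (!any(u)) stop("no usable samples")
  dirs <- cbind(stream$ex, stream$ey, stream$ez)
  eye_ang <- rad2deg(acos(pmin(1, pmax(-1, dirs[, 3]))))
  head_fwd <- azel_to_vec(stream$h_az, stream$h_el)
  head_ang <- rad2deg(acos(pmin(1, pmax(-1, head_fwd[, 3]))))
  step <- consecutive_angles(dirs)
  n <- nrow(dirs)
  pair_u <- u[-n] & u[-1]
  keep <- u & (eye_ang >= 0.5 | head_ang >= 0.5)
  prop <- eye_ang[keep] / (eye_ang[keep] + head_ang[keep])
  c(
    avg_eye_in_head_angle = mean(eye_ang[u]),
    global_eye_movement_per_second = sum(step[pair_u]) / duration,
    avg_eye_to_gaze_proportion = mean0(prop)
  )
}

#' Kinematic features of one effector
#'
#' Mean and standard deviation of absolute velocity, acceleration and jerk,
#' overall (total angular) and per axis (X = pitch, Y = yaw, Z = roll), over
#' usable samples: 24 values per effector.
#'
#' @param stream the `aligned_stream`.
#' @param effector `"eye"` or `"head"`.
#' @return named numeric vector of 24 values.
#' @export
kinematic_features <- function(stream, effector = c("eye", "head")) {
  effector <- match.arg(effector)
  out <- numeric(0)
  for (ord in 1:3) {
    d <- differentiate(stream, effector, ord)
    lab <- c("velocity", "acceleration", "jerk")[ord]
    vals <- c(
      mean(abs(d$speed), na.rm = TRUE), stats::sd(abs(d$speed), na.rm = TRUE),
      mean(abs(d$x), na.rm = TRUE), mean(abs(d$y), na.rm = TRUE),
      mean(abs(d$z), na.rm = TRUE),
      stats::sd(abs(d$x), na.rm = TRUE), stats::sd(abs(d$y), na.rm = TRUE),
      stats::sd(abs(d$z), na.rm = TRUE)
    )
    vals[is.na(vals)] <- 0
    names(vals) <- c(paste0(c("avg_", "std_"), effector, "_", lab),
                     paste0("avg_", effector, "_", lab, "_", c("x", "y", "z")),
                     paste0("std_", effector, "_", lab, "_", c("x", "y", "z")))
    out <- c(out, vals)
  }
  out
}

#' Assemble the full 76-feature vector of one trial
#'
#' @param events event list from [detect_trial_events()].
#' @param stream the trial's `aligned_stream`.
#' @param record the trial record (for duration, condition and scene counts).
#' @return named numeric vector of 76 features in [feature_schema()] order,
#'   with the trial keys in attributes.
#' @export
assemble_features <- function(events, stream, record) {
  duration <- record$duration
  sacc <- attribute_saccade_objects(events$saccades, events$fixations)
  v <- c(
    fixation_features(events$fixations, duration,
                      record$n_targets, record$n_distractors),
    saccade_features(sacc, duration),
    coordination_features(stream, duration),
    kinematic_features(stream, "eye"),
    head_event_features(events$head_movements, events$head_fixations,
                        stream, duration),
    kinematic_features(stream, "head")
  )
  sc <- feature_schema()
  stopifnot(setequal(names(v), sc$name))
  v <- v[sc$name]
  attr(v, "keys") <- list(participant = record$participant,
                          trial = record$trial,
                          discriminability = record$discriminability,
                          pressure = record$pressure)
  v
}
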
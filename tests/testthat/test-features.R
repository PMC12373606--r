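# Feature battery arithmetic, invariants and oracle equivalence.

fix_row <- function(onset_idx, offset_idx, kind = "none", fs = 120) {
  data.frame(kind = "fixation", onset = (onset_idx - 1) / fs,
             offset = (offset_idx - 1) / fs, onset_idx = onset_idx,
             offset_idx = offset_idx, duration = (offset_idx - onset_idx + 1) / fs,
             dir_x = 0, dir_y = 0, dir_z = 1, object_kind = kind,
             object_id = NA_integer_, stringsAsFactors = FALSE)
}

test_that("fixation features follow the normalization arithmetic", {
  # 30 fixations in a 10 s trial -> 3.0 per second
  fx <- do.call(rbind, lapply(1:30, function(k) fix_row(k * 30, k * 30 + 11)))
  f <- fixation_features(fx, duration = 10, n_targets = 14, n_distractors = 12)
  expect_equal(unname(f["fixation_frequency"]), 3.0)

  # 21 target fixations with 14 targets -> 1.5 fixations per target
  fx2 <- do.call(rbind, lapply(1:21, function(k) fix_row(k * 30, k * 30 + 11,
                                                         "target")))
  f2 <- fixation_features(fx2, 10, 14, 12)
  expect_equal(unname(f2["target_fixations_per_target"]), 1.5)
  # all fixations on targets -> ratio uses max(1, other)
  expect_equal(unname(f2["target_distractor_fixation_ratio"]), 21)

  # durations 0.2 + 0.3 + 0.5 in 10 s -> proportion 0.1
  fx3 <- rbind(fix_row(1, 24), fix_row(100, 135), fix_row(300, 359))
  f3 <- fixation_features(fx3, 10, 14, 12)
  expect_equal(unname(f3["fixation_duration_proportion"]), 0.1)

  # empty set -> zero counts and averages
  f0 <- fixation_features(fix_row(1, 12)[0, ], 10, 14, 12)
  expect_true(all(f0 == 0 | names(f0) == "target_distractor_fixation_ratio"))
  expect_error(fixation_features(fx3, 0, 14, 12), "positive")
})

test_that("saccade features average and normalize sizes", {
  s <- data.frame(kind = "saccade", onset = c(0.1, 1.0), offset = c(0.14, 1.04),
                  onset_idx = c(13, 121), offset_idx = c(17, 125),
                  duration = 0.04, amplitude = c(2, 4),
                  peak_velocity = 300,
                  object_kind = c("target", "distractor"),
                  stringsAsFactors = FALSE)
  f <- saccade_features(s, duration = 2)
  expect_equal(unname(f["saccade_frequency"]), 1.0)
  expect_equal(unname(f["avg_saccade_size"]), 3.0)
  expect_equal(unname(f["saccade_size_per_second"]), 3.0)
  expect_equal(unname(f["avg_target_saccade_size"]), 2)
  expect_equal(unname(f["avg_distractor_saccade_size"]), 4)

  f0 <- saccade_features(s[0, ], duration = 2)
  expect_true(all(f0 == 0))
})

test_that("saccades inherit the following fixation's object", {
  s <- data.frame(kind = "saccade", onset = 0.1, offset = 0.14,
                  onset_idx = 13, offset_idx = 17, duration = 0.04,
                  amplitude = 3, peak_velocity = 300, stringsAsFactors = FALSE)
  fx <- fix_row(20, 40, kind = "distractor")
  expect_equal(attribute_saccade_objects(s, fx)$object_kind, "distractor")
  expect_equal(attribute_saccade_objects(s, fx[0, ])$object_kind, "none")
})

test_that("head event features match hand-computed values", {
  fs <- 120
  n <- 1201  # 10 s
  # still head: zero global movement, one trial-long head fixation
  al <- make_aligned(rep(0, n), fs = fs)
  hf_all <- derive_head_fixations(gazeforage:::empty_head_events(), al)
  f0 <- head_event_features(gazeforage:::empty_head_events(), hf_all, al, 10)
  expect_equal(unname(f0["global_head_movement_per_second"]), 0)
  expect_equal(unname(f0["head_fixation_frequency"]), 0.1)

  # yaw 0 -> 30 -> 0 over 10 s: path length 60 deg -> 6 deg/s
  yaw <- c(seq(0, 30, length.out = 601), seq(30, 0, length.out = 601)[-1])
  al2 <- make_aligned(rep(0, n), h_az = yaw, fs = fs)
  f2 <- head_event_features(gazeforage:::empty_head_events(), hf_all, al2, 10)
  expect_equal(unname(f2["global_head_movement_per_second"]), 6,
               tolerance = 1e-6)

  # two 5-degree movements in 10 s
  mv <- data.frame(kind = "movement", onset = c(1, 5), offset = c(1.3, 5.3),
                   onset_idx = c(121, 601), offset_idx = c(157, 637),
                   duration = 0.3, amplitude = 5, peak_speed = 40,
                   stringsAsFactors = FALSE)
  f3 <- head_event_features(mv, hf_all[0, ], al2, 10)
  expect_equal(unname(f3["head_movement_frequency"]), 0.2)
  expect_equal(unname(f3["avg_head_movement_size"]), 5)
  expect_equal(unname(f3["head_movement_size_per_second"]), 1)
})

test_that("coordination features capture the eye/head split", {
  n <- 600
  # eye locked to head centre
  al <- make_aligned(rep(0, n), h_az = seq(0, 20, length.out = n))
  f <- coordination_features(al, 5)
  expect_equal(unname(f["avg_eye_in_head_angle"]), 0)
  expect_equal(unname(f["avg_eye_to_gaze_proportion"]), 0)

  # head at world forward, eye at 10 deg -> proportion 1
  al2 <- make_aligned(rep(10, n))
  f2 <- coordination_features(al2, 5)
  expect_equal(unname(f2["avg_eye_in_head_angle"]), 10, tolerance = 1e-9)
  expect_equal(unname(f2["avg_eye_to_gaze_proportion"]), 1)

  # eye 5 deg and head 5 deg -> proportion 0.5
  al3 <- make_aligned(rep(5, n), h_az = rep(5, n))
  f3 <- coordination_features(al3, 5)
  expect_equal(unname(f3["avg_eye_to_gaze_proportion"]), 0.5, tolerance = 1e-9)
})

test_that("kinematic features reproduce closed forms", {
  fs <- 120
  n <- 1201
  tt <- (0:(n - 1)) / fs

  al <- make_aligned(rep(0, n), h_az = 6 * tt, fs = fs)
  k <- kinematic_features(al, "head")
  expect_equal(unname(k["avg_head_velocity_y"]), 6, tolerance = 1e-9)
  expect_lt(unname(k["avg_head_acceleration"]), 1e-6)
  expect_lt(unname(k["avg_head_jerk_y"]), 1e-6)

  # mean |velocity| of A sin(2 pi f t) is (2/pi) A 2 pi f
  A <- 5; fr <- 1
  al2 <- make_aligned(rep(0, n), h_az = A * sin(2 * pi * fr * tt), fs = fs)
  k2 <- kinematic_features(al2, "head")
  expect_lt(abs(k2["avg_head_velocity_y"] - (2 / pi) * A * 2 * pi * fr) /
              ((2 / pi) * A * 2 * pi * fr), 0.01)

  k3 <- kinematic_features(make_aligned(rep(3, n), fs = fs), "eye")
  expect_true(all(abs(k3) < 1e-6))
})

test_that("assembled vectors have 76 features with consistent subsets", {
  sc <- feature_schema()
  expect_equal(nrow(sc), 76)
  expect_equal(sum(sc$effector == "eye"), 45)
  expect_equal(sum(sc$effector == "head"), 31)
  expect_equal(length(feature_subset("eye")), 45)
  expect_equal(length(feature_subset("head")), 31)

  p <- default_condition_params()$EasyLow
  tr <- generate_trial(p, generate_scene(8), seed = 321)
  al <- ingest_trial(tr)
  vel <- differentiate(al, "eye", 1)
  thr <- estimate_threshold(vel)
  ev <- detect_trial_events(al, thr, vel)
  v <- assemble_features(ev, al, tr$record)
  expect_equal(length(v), 76)
  expect_equal(names(v), sc$name)
  expect_true(all(is.finite(v)))

  # count decomposition and duration proportions
  fx <- ev$fixations
  n_t <- sum(fx$object_kind == "target")
  n_d <- sum(fx$object_kind == "distractor")
  n_n <- sum(fx$object_kind == "none")
  expect_equal(n_t + n_d + n_n, nrow(fx))
  expect_equal(unname(v["target_fixation_frequency"] +
                      v["distractor_fixation_frequency"]),
               unname((n_t + n_d) / tr$record$duration))
  expect_lte(v["target_fixation_duration_proportion"] +
             v["distractor_fixation_duration_proportion"],
             v["fixation_duration_proportion"] + 1e-12)
  expect_lte(v["fixation_duration_proportion"], 1)

  # classification-independent path length dominates the classified subset
  expect_gte(v["global_head_movement_per_second"] + 1e-9,
             v["head_movement_size_per_second"])
})

test_that("features equal the brute-force oracle on generated trials", {
  p <- default_condition_params()$HardHigh
  trials <- lapply(1:2, function(i) generate_trial(p, generate_scene(40 + i),
                                                   seed = 900 + i))
  aligned <- lapply(trials, ingest_trial)
  vels <- lapply(aligned, differentiate, effector = "eye", order = 1)
  thr <- estimate_threshold(vels)
  for (i in seq_along(trials)) {
    ev <- detect_trial_events(aligned[[i]], thr, vels[[i]])
    got <- as.numeric(assemble_features(ev, aligned[[i]], trials[[i]]$record))
    want <- as.numeric(oracle_features(ev, aligned[[i]], trials[[i]]$record))
    expect_lt(max(abs(got - want) / pmax(abs(want), 1e-12)), 1e-9)
  }
})
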
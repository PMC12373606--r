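# Elliptical threshold, saccade/fixation detection, plausibility filters,
# head movement classification and object labeling.

test_that("threshold exceedance matches the chi-square tail for Gaussian noise", {
  set.seed(42)
  v <- matrix(rnorm(3 * 1e5, 0, 10), ncol = 3)
  thr <- estimate_threshold(v)
  # 6-SD ellipse: P(chi2_3 > 36) < 1e-6, so expect no exceedances in 1e5
  expect_lt(mean(exceeds_threshold(thr, v)), 1e-6)
  expect_equal(thr$n, 1e5)
})

test_that("the threshold is scale-equivariant and floors degenerate axes", {
  set.seed(7)
  v <- matrix(rnorm(3 * 5000, 0, c(4, 9, 2)), ncol = 3, byrow = TRUE)
  t1 <- estimate_threshold(v)
  t3 <- estimate_threshold(3 * v)
  expect_equal(t3$radius, 3 * t1$radius, tolerance = 1e-12)
  expect_equal(exceeds_threshold(t1, v), exceeds_threshold(t3, 3 * v))

  const <- matrix(5, 200, 3)
  expect_warning(tc <- estimate_threshold(const), "floor")
  expect_equal(unname(tc$radius), rep(0.6, 3))
  expect_false(any(exceeds_threshold(tc, const)))

  expect_error(estimate_threshold(matrix(rnorm(30), ncol = 3)), "100")
})

test_that("detect_saccades agrees exactly with the naive reference detector", {
  fs <- 120
  for (s in 1:10) {
    set.seed(s)
    n <- sample(300:2000, 1)
    # velocity with bursts; some unusable spans
    x <- rnorm(n, 0, 5)
    burst_at <- sample(20:(n - 20), 8)
    for (b in burst_at) x[b:(b + sample(1:6, 1))] <- rnorm(1, 300, 50)
    u <- rep(TRUE, n)
    u[sample(n, round(0.05 * n))] <- FALSE
    vel <- make_velocity(x, y = rnorm(n, 0, 5), z = rnorm(n, 0, 5), fs = fs)
    vel$x[!u] <- NA; vel$y[!u] <- NA; vel$z[!u] <- NA; vel$speed[!u] <- NA
    al <- make_aligned(cumsum(x) / fs, fs = fs, usable = u)
    thr <- estimate_threshold(cbind(rnorm(500, 0, 5), rnorm(500, 0, 5),
                                    rnorm(500, 0, 5)))
    got <- detect_saccades(vel, thr, al)
    ref <- naive_detect_saccades(vel, thr, al)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(got) > 0) {
      expect_equal(got$onset_idx, ref$onset_idx)
      expect_equal(got$offset_idx, ref$offset_idx)
      expect_equal(got$amplitude, ref$amplitude, tolerance = 1e-9)
      expect_equal(got$peak_velocity, ref$peak_velocity)
    }
  }
})

test_that("single-sample runs are rejected and empty input yields no events", {
  fs <- 120
  x <- rep(0, 200); x[100] <- 500  # one 8.3 ms supra-threshold sample
  vel <- make_velocity(x, fs = fs)
  al <- make_aligned(rep(0, 200), fs = fs)
  thr <- list(mu = c(0, 0, 0), radius = c(60, 60, 60))
  class(thr) <- "elliptical_threshold"
  expect_equal(nrow(detect_saccades(vel, thr, al)), 0)
  expect_equal(nrow(detect_saccades(make_velocity(rep(0, 200)), thr, al)), 0)
})

test_that("plausibility filters remove each violation for its stated reason", {
  ev <- data.frame(
    kind = "saccade",
    onset = 1:5, offset = 1:5 + 0.05, onset_idx = 1:5, offset_idx = 2:6,
    duration = c(0.130, 0.040, 0.040, 0.040, 0.040),
    amplitude = c(5, 2, 2, 0.9, 5),
    peak_velocity = c(300, 20, 1100, 300, 300),
    stringsAsFactors = FALSE
  )
  out <- filter_saccades(ev)
  expect_equal(out$onset, 5)  # only the last survives
  removed <- attr(out, "removed")
  expect_equal(removed$filter_reason,
               c("duration", "peak_velocity", "peak_velocity", "amplitude"))
})

test_that("fixations are the usable inter-saccade intervals of >= 75 ms", {
  fs <- 120
  al <- make_aligned(rep(0, 1200), fs = fs)  # 10 s fully usable

  # no saccades -> one trial-long fixation
  f0 <- derive_fixations(gazeforage:::empty_gaze_events(), al)
  expect_equal(nrow(f0), 1)
  expect_equal(f0$duration, 1200 / fs)

  sacc <- function(i0, i1) data.frame(
    kind = "saccade", onset = (i0 - 1) / fs, offset = (i1 - 1) / fs,
    onset_idx = i0, offset_idx = i1, duration = (i1 - i0 + 1) / fs,
    amplitude = 5, peak_velocity = 300, stringsAsFactors = FALSE)

  # two saccades 80 ms apart -> one >= 75 ms fixation between them
  s2 <- rbind(sacc(100, 104), sacc(115, 119))
  f2 <- derive_fixations(s2, al)
  between <- f2[f2$onset_idx == 105 & f2$offset_idx == 114, ]
  expect_equal(nrow(between), 1)
  expect_equal(between$duration, 10 / fs)

  # 60 ms gap (7 samples) -> no fixation emitted between
  s3 <- rbind(sacc(100, 104), sacc(112, 116))
  f3 <- derive_fixations(s3, al)
  expect_false(any(f3$onset_idx > 104 & f3$offset_idx < 112))
})

test_that("fixation object labels follow the modal rule with ties to none", {
  fs <- 120
  kinds <- rep("none", 100)
  kinds[11:28] <- "target"; kinds[29:30] <- "distractor"   # 90% target
  kinds[41:50] <- rep(c("target", "distractor"), 5)        # 50/50 tie
  ids <- rep(NA_integer_, 100); ids[11:28] <- 3L
  al <- make_aligned(rep(0, 100), fs = fs, gazed_kind = kinds, gazed_id = ids)
  fx <- data.frame(
    kind = "fixation", onset = c(10, 40, 60) / fs, offset = c(29, 49, 79) / fs,
    onset_idx = c(11, 41, 61), offset_idx = c(30, 50, 80),
    duration = 20 / fs, dir_x = 0, dir_y = 0, dir_z = 1,
    object_kind = "none", object_id = NA_integer_, stringsAsFactors = FALSE)
  out <- label_fixation_objects(fx, al)
  expect_equal(out$object_kind, c("target", "none", "none"))
  expect_equal(out$object_id[1], 3L)

  al2 <- make_aligned(rep(0, 100), fs = fs)
  al2$gazed_object_kind <- NULL
  expect_warning(out2 <- label_fixation_objects(fx, al2), "label")
  expect_equal(out2$object_kind, rep("none", 3))
})

test_that("head movements are traced within one sample on a step profile", {
  fs <- 120
  n <- 400
  sp <- rep(0, n)
  sp[101:160] <- 10  # 500 ms at 10 deg/s
  vel <- make_velocity(sp, speed = sp, fs = fs)
  attr(vel, "effector") <- "head"
  yaw <- cumsum(sp) / fs
  al <- make_aligned(rep(0, n), h_az = yaw, fs = fs)
  hm <- detect_head_movements(vel, al)
  expect_equal(nrow(hm), 1)
  expect_lte(abs(hm$onset_idx - 101), 1)
  expect_lte(abs(hm$offset_idx - 161), 1)
  expect_gt(hm$amplitude, 1)

  # zero speed: nothing
  expect_equal(nrow(detect_head_movements(
    make_velocity(rep(0, n), speed = rep(0, n)), al)), 0)

  # supra-threshold drift of only 0.5 deg amplitude is removed by the filter
  sp2 <- rep(0, n); sp2[101:106] <- 10  # 50 ms * 10 deg/s = 0.5 deg
  yaw2 <- cumsum(sp2) / fs
  al2 <- make_aligned(rep(0, n), h_az = yaw2, fs = fs)
  # (50 ms burst cannot fill a 100 ms window; embed it in a longer slow ramp)
  sp3 <- rep(0, n); sp3[101:130] <- 7; yaw3 <- cumsum(sp3 * 0.1) / fs
  al3 <- make_aligned(rep(0, n), h_az = yaw3, fs = fs)
  hm3 <- detect_head_movements(make_velocity(sp3, speed = sp3, fs = fs), al3)
  expect_equal(nrow(hm3), 0)  # amplitude 0.7 deg/s * ... <= 1 deg
})

test_that("head fixations complement the movement list", {
  fs <- 120
  al <- make_aligned(rep(0, 1200), fs = fs)
  mv <- function(i0, i1) data.frame(
    kind = "movement", onset = (i0 - 1) / fs, offset = (i1 - 1) / fs,
    onset_idx = i0, offset_idx = i1, duration = (i1 - i0 + 1) / fs,
    amplitude = 5, peak_speed = 50, stringsAsFactors = FALSE)

  one <- derive_head_fixations(mv(500, 560), al)
  expect_equal(nrow(one), 2)
  expect_equal(one$onset_idx, c(1, 561))

  close_pair <- rbind(mv(500, 560), mv(567, 620))  # 50 ms apart
  two <- derive_head_fixations(close_pair, al)
  expect_false(any(two$onset_idx > 560 & two$offset_idx < 567))

  none <- derive_head_fixations(gazeforage:::empty_head_events(), al)
  expect_equal(nrow(none), 1)
  expect_equal(none$duration, 1200 / fs)
})

test_that("raising the head threshold never increases movement time", {
  trials <- make_clean_dataset(3, seed_base = 300)
  for (tr in trials) {
    al <- ingest_trial(tr)
    hv <- differentiate(al, "head", 1)
    lo <- detect_head_movements(hv, al, speed_threshold = 6)
    hi <- detect_head_movements(hv, al, speed_threshold = 12)
    expect_lte(sum(hi$duration), sum(lo$duration) + 1e-9)
  }
})

test_that("saccades and fixations tile the usable trial without overlap", {
  trials <- make_clean_dataset(4, seed_base = 600)
  d <- detect_all(trials)
  for (i in seq_along(trials)) {
    al <- d$aligned[[i]]
    ev <- d$events[[i]]
    n <- nrow(al)
    cover <- integer(n)
    for (k in seq_len(nrow(ev$saccades))) {
      idx <- ev$saccades$onset_idx[k]:ev$saccades$offset_idx[k]
      cover[idx] <- cover[idx] + 1L
    }
    for (k in seq_len(nrow(ev$fixations))) {
      idx <- ev$fixations$onset_idx[k]:ev$fixations$offset_idx[k]
      cover[idx] <- cover[idx] + 1L
    }
    expect_true(all(cover <= 1))            # never overlap
    # residue (uncovered usable samples) only in sub-75 ms fragments
    res <- rle(al$usable & cover == 0)
    frag <- res$lengths[res$values]
    expect_true(all(frag < 9))
  }
})

test_that("ground-truth events are recovered on clean data", {
  trials <- make_clean_dataset(6, seed_base = 100)
  d <- detect_all(trials)
  sm <- unlist(lapply(seq_along(trials), function(i)
    match_events(trials[[i]]$truth$saccades, d$events[[i]]$saccades)$matched))
  expect_gte(mean(sm), 0.95)
  hm <- unlist(lapply(seq_along(trials), function(i) {
    tt <- trials[[i]]$truth$head_movements
    tt$onset <- tt$cross_on; tt$offset <- tt$cross_off
    match_events(tt, d$events[[i]]$head_movements)$matched
  }))
  expect_gte(mean(hm), 0.95)
})
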
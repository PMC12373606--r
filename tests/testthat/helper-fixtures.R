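# Shared fixture builders: hand-made streams with known geometry, used to
# exercise preprocessing and event detection without the generator.

# Eye stream at `fs` Hz pointing along a given az/el path (deg), recorded in
# the raw +X-left frame with constant pupil.
make_eye_stream <- function(az, el = rep(0, length(az)), fs = 120, pupil = 3) {
  v <- gazeforage:::azel_to_vec(az, el)
  data.frame(
    t = (seq_along(az) - 1) / fs,
    x = -v[, 1], y = v[, 2], z = v[, 3],
    pupil = rep(pupil, length(az)),
    gazed_object_id = rep(NA_integer_, length(az)),
    gazed_object_kind = rep("none", length(az)),
    stringsAsFactors = FALSE
  )
}

make_head_stream <- function(yaw, pitch = rep(0, length(yaw)),
                             roll = rep(0, length(yaw)), fs = 90) {
  data.frame(t = (seq_along(yaw) - 1) / fs, yaw = yaw, pitch = pitch,
             roll = roll)
}

# Fully aligned stream built directly (bypassing resampling) from canonical
# eye az/el and head az/el paths.
make_aligned <- function(eye_az, eye_el = rep(0, length(eye_az)),
                         h_az = rep(0, length(eye_az)),
                         h_el = rep(0, length(eye_az)),
                         h_roll = rep(0, length(eye_az)),
                         fs = 120, usable = rep(TRUE, length(eye_az)),
                         gazed_kind = rep("none", length(eye_az)),
                         gazed_id = rep(NA_integer_, length(eye_az))) {
  v <- gazeforage:::azel_to_vec(eye_az, eye_el)
  out <- data.frame(
    t = (seq_along(eye_az) - 1) / fs,
    ex = v[, 1], ey = v[, 2], ez = v[, 3],
    h_az = h_az, h_el = h_el, h_roll = h_roll,
    pupil = 3, valid = TRUE, usable = usable,
    gazed_object_id = gazed_id, gazed_object_kind = gazed_kind,
    stringsAsFactors = FALSE
  )
  attr(out, "fs") <- fs
  class(out) <- c("aligned_stream", "data.frame")
  out
}

# Velocity series built directly from per-axis components.
make_velocity <- function(x, y = rep(0, length(x)), z = rep(0, length(x)),
                          speed = sqrt(x^2 + y^2 + z^2), fs = 120) {
  out <- data.frame(t = (seq_along(x) - 1) / fs, x = x, y = y, z = z,
                    speed = speed)
  attr(out, "fs") <- fs
  attr(out, "order") <- 1
  attr(out, "effector") <- "eye"
  class(out) <- c("velocity_series", "data.frame")
  out
}

# Clean detector-validation dataset shared by unit and acceptance tests.
make_clean_dataset <- function(n_trials, seed_base = 1000) {
  p <- clean_condition_params()
  lapply(seq_len(n_trials), function(i) {
    generate_trial(p, generate_scene(seed_base + 7 * i), seed = seed_base + i)
  })
}

detect_all <- function(trials) {
  aligned <- lapply(trials, ingest_trial)
  vels <- lapply(aligned, differentiate, effector = "eye", order = 1)
  thr <- estimate_threshold(vels)
  list(aligned = aligned, vels = vels, threshold = thr,
       events = lapply(seq_along(trials), function(i)
         detect_trial_events(aligned[[i]], thr, vels[[i]])))
}

# Four-class dataset with 5 strongly informative and d_noise pure-noise
# features: every informative feature spreads the four class means over
# 3 * strength (in noise-SD units), in a random class order.
make_informative <- function(n = 400, d_noise = 20, seed = 1, strength = 2) {
  with_seed <- gazeforage:::with_seed
  with_seed(seed, {
    y <- factor(rep(c("a", "b", "c", "d"), length.out = n))
    mu <- vapply(1:5, function(j) sample(c(-1.5, -0.5, 0.5, 1.5)) * strength,
                 numeric(4))
    X <- cbind(mu[as.integer(y), ] + matrix(rnorm(n * 5), n, 5),
               matrix(rnorm(n * d_noise), n, d_noise))
    colnames(X) <- c(paste0("inf", 1:5), paste0("noise", seq_len(d_noise)))
    list(X = X, y = y)
  })
}

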
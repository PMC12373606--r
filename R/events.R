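# Event classification: saccades and fixations from the eye velocity using a
# participant-adaptive elliptical threshold; head movements and head fixations
# from head angular speed using a sliding-window rule; biological-plausibility
# filters; object labeling of fixations.

#' Estimate the participant's elliptical velocity threshold
#'
#' Computes the per-axis mean and standard deviation of the eye angular
#' velocity over all usable samples (pooled across the participant's trials)
#' and sets the ellipse radius at six standard deviations from the mean in
#' each direction. A sample exceeds the threshold iff
#' `sum(((v - mu) / (6 sd))^2) > 1`.
#'
#' @param velocity a `velocity_series` (order 1) or a list of them, or a
#'   3-column matrix of per-axis velocities.
#' @param n_sd radius in standard deviations.
#' @param sd_floor minimum per-axis standard deviation (deg/s); substituted
#'   with a warning when an axis is degenerate.
#' @return object of class `elliptical_threshold` with fields `mu`, `radius`,
#'   `n` (samples used) and `floored`.
#' @export
estimate_threshold <- function(velocity, n_sd = 6, sd_floor = 0.1) {
  v <- if (is.matrix(velocity)) {
    velocity
  } else if (inherits(velocity, "velocity_series")) {
    cbind(velocity$x, velocity$y, velocity$z)
  } else {
    do.call(rbind, lapply(velocity, function(s) cbind(s$x, s$y, s$z)))
  }
  v <- v[stats::complete.cases(v), , drop = FALSE]
  if (nrow(v) < 100) stop("need at least 100 usable velocity samples")
  mu <- colMeans(v)
  sd_ <- apply(v, 2, stats::sd)
  floored <- sd_ < sd_floor
  if (any(floored)) {
    warning("velocity SD floor applied on axis ",
            paste(c("x", "y", "z")[floored], collapse = ", "))
    sd_[floored] <- sd_floor
  }
  structure(list(mu = mu, radius = n_sd * sd_, n = nrow(v),
                 floored = floored),
            class = "elliptical_threshold")
}

#' Which samples exceed an elliptical threshold
#'
#' @param threshold an [estimate_threshold()] object.
#' @param velocity a `velocity_series` or 3-column matrix.
#' @return logical vector (`NA` where velocity is masked).
#' @export
exceeds_threshold <- function(threshold, velocity) {
  v <- if (is.matrix(velocity)) velocity else
    cbind(velocity$x, velocity$y, velocity$z)
  q <- ((v[, 1] - threshold$mu[1]) / threshold$radius[1])^2 +
       ((v[, 2] - threshold$mu[2]) / threshold$radius[2])^2 +
       ((v[, 3] - threshold$mu[3]) / threshold$radius[3])^2
  q > 1
}

runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1, end = ends,
             value = r$values)[which(r$values %in% TRUE), c("start", "end")]
}

#' Detect candidate saccades from eye velocity
#'
#' Maximal runs of consecutive supra-threshold usable samples become candidate
#' saccades; runs shorter than `min_dur` (sample count / rate) are rejected
#' and runs adjacent to unusable samples are discarded. Amplitude is the
#' great-circle angle between the eye directions at onset and offset; peak
#' velocity is the maximum total angular speed within the run.
#'
#' @param velocity an order-1 eye `velocity_series`.
#' @param threshold an [estimate_threshold()] object.
#' @param stream the `aligned_stream` the velocity came from (for directions).
#' @param min_dur minimum saccade duration in seconds.
#' @return data.frame of events: `kind`, `onset`, `offset` (s), `onset_idx`,
#'   `offset_idx`, `duration`, `amplitude`, `peak_velocity`.
#' @export
detect_saccades <- function(velocity, threshold, stream, min_dur = 0.012) {
  fs <- attr(velocity, "fs")
  over <- exceeds_threshold(threshold, velocity)
  usable <- !is.na(over) & !is.na(velocity$speed)
  flag <- usable & over
  flag[is.na(flag)] <- FALSE
  rr <- runs_of(flag)
  if (nrow(rr) == 0) return(empty_gaze_events())
  n <- length(flag)
  keep <- rep(TRUE, nrow(rr))
  for (k in seq_len(nrow(rr))) {
    i0 <- rr$start[k]; i1 <- rr$end[k]
    if ((i1 - i0 + 1) / fs < min_dur) { keep[k] <- FALSE; next }
    if (i0 > 1 && !usable[i0 - 1]) keep[k] <- FALSE
    if (i1 < n && !usable[i1 + 1]) keep[k] <- FALSE
  }
  rr <- rr[keep, , drop = FALSE]
  if (nrow(rr) == 0) return(empty_gaze_events())
  dirs <- cbind(stream$ex, stream$ey, stream$ez)
  amp <- angle_between(dirs[rr$start, , drop = FALSE],
                       dirs[rr$end, , drop = FALSE])
  pv <- vapply(seq_len(nrow(rr)), function(k)
    max(velocity$speed[rr$start[k]:rr$end[k]], na.rm = TRUE), numeric(1))
  data.frame(
    kind = "saccade",
    onset = velocity$t[rr$start], offset = velocity$t[rr$end],
    onset_idx = rr$start, offset_idx = rr$end,
    duration = (rr$end - rr$start + 1) / fs,
    amplitude = amp, peak_velocity = pv,
    stringsAsFactors = FALSE
  )
}

empty_gaze_events <- function() {
  data.frame(kind = character(0), onset = numeric(0), offset = numeric(0),
             onset_idx = integer(0), offset_idx = integer(0),
             duration = numeric(0), amplitude = numeric(0),
             peak_velocity = numeric(0), stringsAsFactors = FALSE)
}

#' Remove biologically implausible saccades
#'
#' Candidates longer than 120 ms, with peak velocities below 25 or above
#' 1000 deg/s, or with amplitudes of 1 degree or less are removed. Removals
#' are returned with their reason.
#'
#' @param events candidate saccade data.frame from [detect_saccades()].
#' @param max_dur,vmin,vmax,min_amp filter bounds.
#' @return the surviving events, with the removed ones (plus a
#'   `filter_reason` column) in attribute `removed`.
#' @export
filter_saccades <- function(events, max_dur = 0.120, vmin = 25, vmax = 1000,
                            min_amp = 1) {
  reason <- rep(NA_character_, nrow(events))
  reason[events$duration > max_dur] <- "duration"
  reason[is.na(reason) &
         (events$peak_velocity < vmin | events$peak_velocity > vmax)] <- "peak_velocity"
  reason[is.na(reason) & events$amplitude <= min_amp] <- "amplitude"
  out <- events[is.na(reason), , drop = FALSE]
  removed <- events[!is.na(reason), , drop = FALSE]
  if (nrow(removed)) removed$filter_reason <- reason[!is.na(reason)]
  attr(out, "removed") <- removed
  out
}

#' Derive eye fixations from the inter-saccade intervals
#'
#' Fixations are maximal fully-usable intervals between filtered saccades
#' lasting at least `min_dur`; the mean direction is the normalized mean of
#' the eye directions over the interval.
#'
#' @param saccades filtered saccade data.frame.
#' @param stream the `aligned_stream`.
#' @param min_dur minimum fixation duration in seconds.
#' @return data.frame of fixation events with mean direction columns
#'   `dir_x`, `dir_y`, `dir_z`.
#' @export
derive_fixations <- function(saccades, stream, min_dur = 0.075) {
  fs <- attr(stream, "fs")
  n <- nrow(stream)
  free <- stream$usable
  if (nrow(saccades) > 0) {
    for (k in seq_len(nrow(saccades))) {
      free[saccades$onset_idx[k]:saccades$offset_idx[k]] <- FALSE
    }
  }
  rr <- runs_of(free)
  if (nrow(rr) == 0) return(empty_fixations())
  rr <- rr[(rr$end - rr$start + 1) / fs >= min_dur, , drop = FALSE]
  if (nrow(rr) == 0) return(empty_fixations())
  dirs <- cbind(stream$ex, stream$ey, stream$ez)
  md <- t(vapply(seq_len(nrow(rr)), function(k) {
    m <- colMeans(dirs[rr$start[k]:rr$end[k], , drop = FALSE])
    m / sqrt(sum(m^2))
  }, numeric(3)))
  data.frame(
    kind = "fixation",
    onset = stream$t[rr$start], offset = stream$t[rr$end],
    onset_idx = rr$start, offset_idx = rr$end,
    duration = (rr$end - rr$start + 1) / fs,
    dir_x = md[, 1], dir_y = md[, 2], dir_z = md[, 3],
    object_kind = "none", object_id = NA_integer_,
    stringsAsFactors = FALSE
  )
}

empty_fixations <- function() {
  data.frame(kind = character(0), onset = numeric(0), offset = numeric(0),
             onset_idx = integer(0), offset_idx = integer(0),
             duration = numeric(0), dir_x = numeric(0), dir_y = numeric(0),
             dir_z = numeric(0), object_kind = character(0),
             object_id = integer(0), stringsAsFactors = FALSE)
}

#' Label fixations with the gazed object kind
#'
#' Each fixation is labeled target/distractor/none by the modal gazed-object
#' kind over its samples; ties resolve to none.
#'
#' @param fixations data.frame from [derive_fixations()].
#' @param stream the `aligned_stream` carrying `gazed_object_kind` /
#'   `gazed_object_id` columns.
#' @return the fixations with `object_kind` and `object_id` filled in.
#' @export
label_fixation_objects <- function(fixations, stream) {
  if (is.null(stream$gazed_object_kind)) {
    warning("stream carries no gazed-object labels; all fixations labeled none")
    return(fixations)
  }
  for (k in seq_len(nrow(fixations))) {
    idx <- fixations$onset_idx[k]:fixations$offset_idx[k]
    kinds <- stream$gazed_object_kind[idx]
    kinds[is.na(kinds)] <- "none"
    tab <- table(factor(kinds, levels = c("target", "distractor", "none")))
    top <- names(tab)[tab == max(tab)]
    lab <- if (length(top) > 1) "none" else top
    fixations$object_kind[k] <- lab
    if (lab != "none") {
      ids <- stream$gazed_object_id[idx][kinds == lab]
      ids <- ids[!is.na(ids)]
      if (length(ids)) {
        fixations$object_id[k] <- as.integer(names(sort(table(ids),
                                                        decreasing = TRUE))[1])
      }
    }
  }
  fixations
}

#' Detect head movements with a sliding-window speed rule
#'
#' Motion onset requires a 100 ms window in which at least 72% of samples
#' exceed the speed threshold with fewer than three consecutive samples below
#' it; the onset is the first supra-threshold sample of that window. The
#' offset is found from the first subsequent 22 ms window with at least 72% of
#' samples below the threshold, taking the first sub-threshold sample within
#' it. Movements with amplitude of 1 degree or less are removed.
#'
#' @param head_speed an order-1 head `velocity_series` (its `speed` column is
#'   used).
#' @param stream the `aligned_stream` (for head orientation at onset/offset).
#' @param speed_threshold speed threshold in deg/s.
#' @param onset_window,offset_window window lengths in seconds.
#' @param frac required fraction of qualifying samples within a window.
#' @param min_amp minimum amplitude in degrees.
#' @return data.frame of head movement events.
#' @export
detect_head_movements <- function(head_speed, stream, speed_threshold = 6,
                                  onset_window = 0.1, offset_window = 0.022,
                                  frac = 0.72, min_amp = 1) {
  fs <- attr(head_speed, "fs")
  sp <- head_speed$speed
  sp[is.na(sp)] <- 0
  n <- length(sp)
  w_on <- max(2L, round(onset_window * fs))
  w_off <- max(2L, round(offset_window * fs))
  need_on <- ceiling(frac * w_on - 1e-9)
  need_off <- ceiling(frac * w_off - 1e-9)
  above <- sp > speed_threshold
  below <- !above
  if (n < w_on) return(empty_head_events())

  # windowed counts of supra-threshold samples
  ca <- cumsum(c(0, above))
  cnt_on <- ca[(w_on + 1):(n + 1)] - ca[1:(n - w_on + 1)]
  # windows containing a full run of >= 3 consecutive below samples
  b3 <- if (n >= 3) below[1:(n - 2)] & below[2:(n - 1)] & below[3:n] else logical(0)
  cb3 <- cumsum(c(0, b3))
  has_b3 <- if (n - w_on + 1 >= 1 && length(b3) > 0) {
    hi <- pmin(n - 2, (1:(n - w_on + 1)) + w_on - 3)
    lo <- 1:(n - w_on + 1)
    ok <- hi >= lo
    out <- rep(FALSE, n - w_on + 1)
    out[ok] <- (cb3[hi[ok] + 1] - cb3[lo[ok]]) > 0
    out
  } else rep(FALSE, max(0, n - w_on + 1))
  qual_on <- cnt_on >= need_on & !has_b3

  cb <- cumsum(c(0, below))
  n_off <- n - w_off + 1
  cnt_off <- cb[(w_off + 1):(n + 1)] - cb[1:n_off]
  qual_off <- cnt_off >= need_off

  events <- list(); ne <- 0
  cursor <- 1L
  repeat {
    s <- which(qual_on[cursor:length(qual_on)])[1]
    if (is.na(s)) break
    s <- s + cursor - 1L
    win <- s:(s + w_on - 1)
    onset <- win[above[win]][1]
    # offset search starts after the onset
    t0 <- onset + 1L
    off_candidates <- which(qual_off[min(t0, n_off):n_off])
    if (t0 > n_off || length(off_candidates) == 0) {
      offset <- n
    } else {
      ws <- off_candidates[1] + min(t0, n_off) - 1L
      wwin <- ws:(ws + w_off - 1)
      offset <- wwin[below[wwin]][1]
      if (is.na(offset)) offset <- ws
    }
    ne <- ne + 1
    events[[ne]] <- c(onset = onset, offset = offset)
    cursor <- offset + 1L
    if (cursor > length(qual_on)) break
  }
  if (ne == 0) return(empty_head_events())
  ev <- as.data.frame(do.call(rbind, events))
  fwd <- azel_to_vec(stream$h_az, stream$h_el)
  amp <- angle_between(fwd[ev$onset, , drop = FALSE],
                       fwd[ev$offset, , drop = FALSE])
  pv <- vapply(seq_len(nrow(ev)), function(k)
    max(sp[ev$onset[k]:ev$offset[k]]), numeric(1))
  out <- data.frame(
    kind = "movement",
    onset = head_speed$t[ev$onset], offset = head_speed$t[ev$offset],
    onset_idx = ev$onset, offset_idx = ev$offset,
    duration = (ev$offset - ev$onset + 1) / fs,
    amplitude = amp, peak_speed = pv,
    stringsAsFactors = FALSE
  )
  out[out$amplitude > min_amp, , drop = FALSE]
}

empty_head_events <- function() {
  data.frame(kind = character(0), onset = numeric(0), offset = numeric(0),
             onset_idx = integer(0), offset_idx = integer(0),
             duration = numeric(0), amplitude = numeric(0),
             peak_speed = numeric(0), stringsAsFactors = FALSE)
}

#' Derive head fixations between classified head movements
#'
#' Complement intervals of at least `min_dur` become head fixations.
#'
#' @param movements head movement data.frame.
#' @param stream the `aligned_stream` (defines the trial span).
#' @param min_dur minimum duration in seconds.
#' @return data.frame of head fixation events.
#' @export
derive_head_fixations <- function(movements, stream, min_dur = 0.075) {
  fs <- attr(stream, "fs")
  n <- nrow(stream)
  free <- rep(TRUE, n)
  if (nrow(movements) > 0) {
    for (k in seq_len(nrow(movements))) {
      free[movements$onset_idx[k]:movements$offset_idx[k]] <- FALSE
    }
  }
  rr <- runs_of(free)
  if (nrow(rr) == 0) return(empty_head_events())
  rr <- rr[(rr$end - rr$start + 1) / fs >= min_dur, , drop = FALSE]
  if (nrow(rr) == 0) return(empty_head_events())
  data.frame(
    kind = "fixation",
    onset = stream$t[rr$start], offset = stream$t[rr$end],
    onset_idx = rr$start, offset_idx = rr$end,
    duration = (rr$end - rr$start + 1) / fs,
    amplitude = NA_real_, peak_speed = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Detect all events of one trial
#'
#' Runs the full event battery on an aligned stream: saccade candidates
#' against the participant threshold, plausibility filters, fixation
#' derivation and labeling, head movement classification and head fixations.
#'
#' @param stream an `aligned_stream`.
#' @param threshold the participant's [estimate_threshold()] object.
#' @param eye_velocity optional precomputed order-1 eye velocity.
#' @return list with `saccades`, `fixations`, `head_movements`,
#'   `head_fixations`, `removed_saccades`.
#' @export
detect_trial_events <- function(stream, threshold, eye_velocity = NULL) {
  if (is.null(eye_velocity)) eye_velocity <- differentiate(stream, "eye", 1)
  head_v <- differentiate(stream, "head", 1)
  cand <- detect_saccades(eye_velocity, threshold, stream)
  sacc <- filter_saccades(cand)
  fix <- label_fixation_objects(derive_fixations(sacc, stream), stream)
  hm <- detect_head_movements(head_v, stream)
  hf <- derive_head_fixations(hm, stream)
  list(saccades = sacc, fixations = fix, head_movements = hm,
       head_fixations = hf, removed_saccades = attr(sacc, "removed"))
}

#' Match detected events to ground-truth events
#'
#' Greedy one-to-one matching on the sample grid. A truth event whose onset/
#' offset times are `(a, b)` is expected at the grid samples strictly inside
#' `(a, b)`; it counts as recovered when a detected event's onset and offset
#' sample indices both lie within `tol` samples of those.
#'
#' @param truth data.frame with `onset`/`offset` times (s) of the injected
#'   events (for head movements, pass the speed-criterion crossing times).
#' @param detected data.frame with `onset_idx`/`offset_idx` sample indices on
#'   the aligned grid.
#' @param fs sampling rate of the aligned grid (origin at t = 0).
#' @param tol tolerance in samples.
#' @return list with `matched` (logical per truth event) and `rate`.
#' @export
match_events <- function(truth, detected, fs = 120, tol = 1) {
  if (nrow(truth) == 0) return(list(matched = logical(0), rate = NA_real_))
  exp_on <- floor(truth$onset * fs + 1e-9) + 2
  exp_off <- floor(truth$offset * fs - 1e-9) + 1
  used <- rep(FALSE, nrow(detected))
  matched <- rep(FALSE, nrow(truth))
  for (k in seq_len(nrow(truth))) {
    if (nrow(detected) == 0) break
    d_on <- abs(detected$onset_idx - exp_on[k])
    d_off <- abs(detected$offset_idx - exp_off[k])
    ok <- !used & d_on <= tol & d_off <= tol
    if (any(ok)) {
      j <- which(ok)[which.min(d_on[ok])]
      used[j] <- TRUE
      matched[k] <- TRUE
    }
  }
  list(matched = matched, rate = mean(matched))
}
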
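# Trial-level behavioural performance: completion time, inter-target
# engagement time and signal-detection sensitivity (d-prime).

#' Trial completion time
#'
#' Time from scene onset to the completion button press or to the time limit,
#' whichever came first.
#'
#' @param record a trial record with `duration`, `time_limit` and `end_cause`.
#' @return completion time in seconds.
#' @export
completion_time <- function(record) {
  if (is.null(record$duration) || is.null(record$time_limit)) {
    stop("trial record has no end event")
  }
  min(record$duration, record$time_limit)
}

#' Average inter-target engagement time
#'
#' Mean of the time differences between successive target hits. Trials with
#' fewer than two hits yield `NA` (excluded downstream).
#'
#' @param record a trial record whose `shots` table has `time` and `outcome`.
#' @return mean inter-hit interval in seconds, or `NA`.
#' @export
inter_target_time <- function(record) {
  hits <- sort(record$shots$time[record$shots$outcome == "hit"])
  if (length(hits) < 2) return(NA_real_)
  mean(diff(hits))
}

#' Signal-detection sensitivity from hit and false-alarm rates
#'
#' `d' = qnorm(H) - qnorm(FA)`. Rates of exactly 0 or 1 give infinite
#' quantiles; use [trial_dprime()] for count data with a correction.
#'
#' @param hit_rate,fa_rate rates in (0, 1).
#' @return d-prime (unitless).
#' @export
dprime <- function(hit_rate, fa_rate) {
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

#' d-prime from trial counts with extreme-rate correction
#'
#' The log-linear correction adds 0.5 to each cell and 1 to each denominator,
#' keeping the rates inside (0, 1) for any counts; the `"halfcount"`
#' alternative replaces only extreme rates by `1/(2N)` or `1 - 1/(2N)`.
#'
#' @param hits,false_alarms counts.
#' @param n_targets,n_distractors numbers of signal/noise trials (> 0).
#' @param correction `"loglinear"` (default), `"halfcount"` or `"none"`.
#' @return d-prime.
#' @export
trial_dprime <- function(hits, n_targets, false_alarms, n_distractors,
                         correction = c("loglinear", "halfcount", "none")) {
  correction <- match.arg(correction)
  stopifnot(n_targets > 0, n_distractors > 0)
  if (correction == "loglinear") {
    h <- (hits + 0.5) / (n_targets + 1)
    f <- (false_alarms + 0.5) / (n_distractors + 1)
  } else {
    h <- hits / n_targets
    f <- false_alarms / n_distractors
    if (correction == "halfcount") {
      h <- min(max(h, 1 / (2 * n_targets)), 1 - 1 / (2 * n_targets))
      f <- min(max(f, 1 / (2 * n_distractors)), 1 - 1 / (2 * n_distractors))
    }
  }
  dprime(h, f)
}

#' Behavioural record of one trial
#'
#' @param trial a `foraging_trial` (or its record).
#' @param correction d-prime correction passed to [trial_dprime()].
#' @return one-row data.frame with completion time, inter-target time, hit/
#'   false-alarm counts, d-prime and end cause.
#' @export
behavioral_record <- function(trial, correction = "loglinear") {
  rec <- if (inherits(trial, "foraging_trial")) trial$record else trial
  hits <- sum(rec$shots$outcome == "hit")
  fas <- sum(rec$shots$outcome == "false_alarm")
  data.frame(
    participant = rec$participant, trial = rec$trial,
    discriminability = rec$discriminability, pressure = rec$pressure,
    completion_time = completion_time(rec),
    inter_target_time = inter_target_time(rec),
    hits = hits, misses = rec$n_targets - hits,
    false_alarms = fas, correct_rejections = rec$n_distractors - fas,
    dprime = trial_dprime(hits, rec$n_targets, fas, rec$n_distractors,
                          correction),
    end_cause = rec$end_cause,
    stringsAsFactors = FALSE
  )
}
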
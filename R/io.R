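# Stable file schemas: long-format sample CSV, event/feature/behaviour
# tables, and a declarative end-to-end pipeline driver with a run manifest.
# CSV is the canonical interchange; angles are degrees, time seconds.

sample_columns <- c("participant", "trial", "t_sec", "effector", "x", "y",
                    "z", "yaw", "pitch", "roll", "pupil_mm", "valid",
                    "gazed_object_id", "gazed_object_kind")

#' Write trials as a long-format sample table
#'
#' One row per sample, eye and head interleaved per trial, with the schema:
#' `participant, trial, t_sec, effector (eye/head), x, y, z, yaw, pitch,
#' roll, pupil_mm, valid, gazed_object_id, gazed_object_kind`.
#'
#' @param trials list of `foraging_trial` objects.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_samples <- function(trials, path) {
  rows <- lapply(trials, function(tr) {
    e <- tr$eye; h <- tr$head; r <- tr$record
    rbind(
      data.frame(participant = r$participant, trial = r$trial, t_sec = e$t,
                 effector = "eye", x = e$x, y = e$y, z = e$z,
                 yaw = NA_real_, pitch = NA_real_, roll = NA_real_,
                 pupil_mm = e$pupil, valid = e$pupil > 0,
                 gazed_object_id = e$gazed_object_id,
                 gazed_object_kind = e$gazed_object_kind,
                 stringsAsFactors = FALSE),
      data.frame(participant = r$participant, trial = r$trial, t_sec = h$t,
                 effector = "head", x = NA_real_, y = NA_real_, z = NA_real_,
                 yaw = h$yaw, pitch = h$pitch, roll = h$roll,
                 pupil_mm = NA_real_, valid = TRUE,
                 gazed_object_id = NA_integer_, gazed_object_kind = "none",
                 stringsAsFactors = FALSE)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format sample table
#'
#' Columns are matched by name (any order). Each (participant, trial) group
#' is split into its eye and head streams; non-monotonic timestamps or a
#' missing pupil column are hard errors.
#'
#' @param path CSV path following the [write_samples()] schema.
#' @return named list (one element per trial, name `participant.trial`) of
#'   lists with `eye` and `head` data.frames ready for [align_timebase()].
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(sample_columns, names(df))
  if (length(missing)) {
    stop("sample file lacks required column(s): ", paste(missing, collapse = ", "))
  }
  key <- paste(df$participant, df$trial, sep = ".")
  out <- lapply(split(df, key), function(g) {
    e <- g[g$effector == "eye", , drop = FALSE]
    h <- g[g$effector == "head", , drop = FALSE]
    if (any(diff(e$t_sec) <= 0) || any(diff(h$t_sec) <= 0)) {
      stop("non-monotonic timestamps in trial ", g$participant[1], ".",
           g$trial[1])
    }
    list(
      eye = data.frame(t = e$t_sec, x = e$x, y = e$y, z = e$z,
                       pupil = e$pupil_mm,
                       gazed_object_id = e$gazed_object_id,
                       gazed_object_kind = e$gazed_object_kind,
                       stringsAsFactors = FALSE),
      head = data.frame(t = h$t_sec, yaw = h$yaw, pitch = h$pitch,
                        roll = h$roll),
      participant = g$participant[1], trial = g$trial[1]
    )
  })
  out
}

#' Write an event table
#'
#' @param events list of per-trial event lists (from [detect_trial_events()])
#'   or a single event list; keys are recycled from `keys`.
#' @param keys data.frame with `participant` and `trial` per element.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_events <- function(events, keys, path) {
  if (!is.null(events$saccades)) events <- list(events)
  rows <- lapply(seq_along(events), function(i) {
    ev <- events[[i]]
    bind <- function(df, effector) {
      if (is.null(df) || nrow(df) == 0) return(NULL)
      data.frame(participant = keys$participant[i], trial = keys$trial[i],
                 effector = effector, kind = df$kind,
                 onset_s = df$onset, offset_s = df$offset,
                 duration_s = df$duration,
                 amplitude_deg = if ("amplitude" %in% names(df)) df$amplitude else NA,
                 peak_vel = if ("peak_velocity" %in% names(df)) df$peak_velocity
                            else if ("peak_speed" %in% names(df)) df$peak_speed else NA,
                 object_kind = if ("object_kind" %in% names(df)) df$object_kind else "none",
                 stringsAsFactors = FALSE)
    }
    rbind(bind(ev$saccades, "eye"), bind(ev$fixations, "eye"),
          bind(ev$head_movements, "head"), bind(ev$head_fixations, "head"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline from a declarative configuration
#'
#' Simulates the dataset, processes every participant (preprocess, detect,
#' features, behaviour), optionally runs the classification suite, writes all
#' tables under `out_dir` and returns a manifest of outputs, digests and
#' seeds. All randomness flows from the named seeds in the configuration.
#'
#' @param config list with `n_participants`, `trials_per_cell`, `seed` and
#'   optionally `params` (condition list), `out_dir`, `classify` (default
#'   TRUE), `rank`, and [run_study()] settings.
#' @return the run manifest (invisibly if `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$n_participants),
            !is.null(config$trials_per_cell), !is.null(config$seed))
  params <- if (is.null(config$params)) default_condition_params() else config$params
  sim <- simulate_study(config$n_participants, config$trials_per_cell,
                        params, seed = config$seed)
  out <- list(features = sim$features, behavior = sim$behavior)
  if (is.null(config$classify) || isTRUE(config$classify)) {
    out$study <- run_study(sim$features, seed = config$seed,
                           rank = !isFALSE(config$rank))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("gazeforage")),
    seed = config$seed,
    n_participants = config$n_participants,
    trials_per_cell = config$trials_per_cell,
    n_trials = nrow(sim$features),
    files = character(0)
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    fpath <- file.path(config$out_dir, "features.csv")
    bpath <- file.path(config$out_dir, "behavior.csv")
    utils::write.csv(sim$features, fpath, row.names = FALSE)
    utils::write.csv(sim$behavior, bpath, row.names = FALSE)
    files <- c(fpath, bpath)
    if (!is.null(out$study)) {
      spath <- file.path(config$out_dir, "study_result.json")
      jsonlite::write_json(study_result_summary(out$study), spath,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- c(files, spath)
    }
    manifest$files <- stats::setNames(as.character(tools::md5sum(files)), files)
    mpath <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  }
  out$manifest <- manifest
  out
}

#' Serializable summary of a study result
#'
#' @param study a [run_study()] result.
#' @return plain list (accuracies, statistics, selected features, top-10
#'   rankings, comparisons) suitable for JSON export.
#' @export
study_result_summary <- function(study) {
  models <- lapply(study$models, function(m) {
    list(scheme = m$scheme, effector = m$effector,
         n_selected = length(m$selected), selected = m$selected,
         accuracies = m$accuracies, mean = m$stats$mean, sd = m$stats$sd,
         p = m$stats$p, g = m$stats$g, chance = m$chance,
         top10 = if (!is.null(m$ranking))
           utils::head(m$ranking$feature, 10) else NULL)
  })
  list(models = models,
       comparisons = lapply(study$comparisons, function(cmp)
         lapply(seq_len(nrow(cmp)), function(i) as.list(cmp[i, ]))),
       seed = study$seed, config = study$config)
}
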
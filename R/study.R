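# End-to-end pipeline: raw streams -> events -> features -> behaviour ->
# classification suite. Processing is per participant because the saccade
# threshold is participant-adaptive and streams can be discarded once the
# trial features are extracted.

#' Process the trials of one participant
#'
#' Aligns each trial, pools the usable eye velocities to estimate the
#' participant's elliptical saccade threshold, detects events, and assembles
#' the feature vector and behavioural record of every trial.
#'
#' @param trials list of `foraging_trial` objects from one participant.
#' @param target_rate aligned sampling rate in Hz.
#' @return list with `features` (one row per trial: keys + 76 features),
#'   `behavior` (one row per trial), `threshold`, and per-trial `events`.
#' @export
process_participant <- function(trials, target_rate = 120) {
  aligned <- lapply(trials, ingest_trial, target_rate = target_rate)
  vels <- lapply(aligned, differentiate, effector = "eye", order = 1)
  threshold <- estimate_threshold(vels)
  feats <- vector("list", length(trials))
  events <- vector("list", length(trials))
  behav <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    ev <- detect_trial_events(aligned[[i]], threshold, vels[[i]])
    events[[i]] <- ev
    v <- assemble_features(ev, aligned[[i]], trials[[i]]$record)
    keys <- attr(v, "keys")
    feats[[i]] <- data.frame(
      participant = keys$participant, trial = keys$trial,
      discriminability = keys$discriminability, pressure = keys$pressure,
      as.list(v), check.names = FALSE, stringsAsFactors = FALSE)
    behav[[i]] <- behavioral_record(trials[[i]])
  }
  features <- do.call(rbind, feats)
  if (anyDuplicated(features[, c("participant", "trial")])) {
    stop("duplicate trial keys")
  }
  list(features = features, behavior = do.call(rbind, behav),
       threshold = threshold, events = events)
}

#' Simulate and process a full synthetic study
#'
#' Generates a balanced 2 x 2 dataset participant by participant (memory
#' stays bounded) and runs the full processing chain, returning the trial
#' feature matrix and behavioural table.
#'
#' @inheritParams generate_dataset
#' @param target_rate aligned sampling rate in Hz.
#' @return list with `features`, `behavior`.
#' @export
simulate_study <- function(n_participants, trials_per_cell,
                           params_by_condition = default_condition_params(),
                           seed = 1, jitter_sd = c(0.1, 0.25),
                           target_rate = 120) {
  pseeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_participants))
  feats <- vector("list", n_participants)
  behav <- vector("list", n_participants)
  for (pid in seq_len(n_participants)) {
    trials <- simulate_participant(pid, params_by_condition, trials_per_cell,
                                   pseeds[pid], jitter_sd)
    res <- process_participant(trials, target_rate)
    feats[[pid]] <- res$features
    behav[[pid]] <- res$behavior
  }
  list(features = do.call(rbind, feats), behavior = do.call(rbind, behav))
}

#' Extract the numeric feature matrix from a feature table
#'
#' @param features feature table from [simulate_study()]/[process_participant()].
#' @param effector `"both"`, `"eye"` or `"head"` feature subset.
#' @return numeric matrix with feature columns in schema order.
#' @export
study_feature_matrix <- function(features, effector = c("both", "eye", "head")) {
  effector <- match.arg(effector)
  cols <- if (effector == "both") feature_schema()$name else
    feature_subset(effector)
  as.matrix(features[, cols, drop = FALSE])
}

study_labels <- function(features, scheme = c("fourway", "discriminability",
                                              "pressure")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    fourway = factor(paste(features$discriminability, features$pressure,
                           sep = "-")),
    discriminability = factor(features$discriminability),
    pressure = factor(features$pressure))
}

#' Run the seven-model classification suite
#'
#' The full study suite: a 4-way condition model for each feature set
#' (eye + head, eye only, head only) and 2-way discriminability and time
#' pressure models for the eye-only and head-only sets. Each model runs
#' shadow selection, stratified 10-fold cross-validation of the scaled
#' RBF-SVM pipeline, a Wilcoxon comparison against chance with Hedges' g,
#' and (optionally) a Shapley-style feature ranking. All models of a label
#' scheme share one fold-partition seed so paired fold comparisons are valid.
#'
#' @param features feature table with keys and the 76 feature columns.
#' @param seed master seed for selection, folds and ranking.
#' @param n_iter,alpha,num_trees shadow-selection settings.
#' @param folds,cost cross-validation settings.
#' @param rank whether to compute feature rankings.
#' @param subset_frac,n_perm ranking settings.
#' @return object of class `study_result`: per-model blocks (`selection`,
#'   `accuracies`, `stats`, `ranking`, `chance`, `n`) plus pairwise
#'   comparison tables for the 4-way and 2-way families.
#' @export
run_study <- function(features, seed = 1, n_iter = 50, alpha = 0.05,
                      num_trees = 100, folds = 10, cost = 1, rank = TRUE,
                      subset_frac = 0.2, n_perm = 8) {
  spec <- list(
    fourway_eye_head = list(scheme = "fourway", effector = "both"),
    fourway_eye = list(scheme = "fourway", effector = "eye"),
    fourway_head = list(scheme = "fourway", effector = "head"),
    discriminability_eye = list(scheme = "discriminability", effector = "eye"),
    discriminability_head = list(scheme = "discriminability", effector = "head"),
    pressure_eye = list(scheme = "pressure", effector = "eye"),
    pressure_head = list(scheme = "pressure", effector = "head")
  )
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1,
                                      2 * length(spec) + 1))
  fold_seed <- seeds[1]
  models <- vector("list", length(spec))
  names(models) <- names(spec)
  for (m in seq_along(spec)) {
    sp <- spec[[m]]
    X <- study_feature_matrix(features, sp$effector)
    y <- study_labels(features, sp$scheme)
    sel <- shadow_select(X, y, n_iter = n_iter, alpha = alpha,
                         seed = seeds[2 * m], num_trees = num_trees)
    used <- sel$selected
    fallback <- length(used) == 0
    if (fallback) used <- colnames(X)
    acc <- fit_evaluate(X[, used, drop = FALSE], y, seed = fold_seed,
                        folds = folds, cost = cost)
    chance <- 1 / nlevels(y)
    ranking <- NULL
    if (rank) {
      fit <- fit_svm_model(X[, used, drop = FALSE], y, cost = cost)
      ranking <- rank_features(fit, X[, used, drop = FALSE], y,
                               subset_frac = subset_frac, n_perm = n_perm,
                               seed = seeds[2 * m + 1])
    }
    models[[m]] <- list(
      scheme = sp$scheme, effector = sp$effector,
      selection = sel, selected = used, selection_fallback = fallback,
      accuracies = as.numeric(acc), folds = attr(acc, "folds"),
      chance = chance, stats = compare_to_chance(as.numeric(acc), chance),
      ranking = ranking, n = nrow(features)
    )
  }
  acc4 <- lapply(models[1:3], `[[`, "accuracies")
  acc2 <- lapply(models[4:7], `[[`, "accuracies")
  structure(list(
    models = models,
    comparisons = list(fourway = compare_models(acc4),
                       binary = compare_models(acc2)),
    seed = seed,
    config = list(n_iter = n_iter, alpha = alpha, num_trees = num_trees,
                  folds = folds, cost = cost, subset_frac = subset_frac,
                  n_perm = n_perm)
  ), class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("Study classification suite (", length(x$models), " models)\n\n", sep = "")
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("%-22s M = %.3f, SD = %.3f, p = %.4g, g = %.2f (%d/%d features)\n",
                nm, m$stats$mean, m$stats$sd, m$stats$p, m$stats$g,
                length(m$selected), length(feature_subset_len(m$effector))))
  }
  invisible(x)
}

feature_subset_len <- function(effector) {
  if (effector == "both") feature_schema()$name else feature_subset(effector)
}
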
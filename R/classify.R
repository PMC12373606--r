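# Decoding task condition from trial features: shadow-feature selection
# (random-forest wrapper with shuffled copies as the importance baseline),
# standard scaling + RBF support vector classification under stratified
# 10-fold cross-validation, exact Wilcoxon comparisons with Holm correction
# and Hedges' g, and a permutation (Monte-Carlo Shapley) feature ranking.

#' Small-sample correction factor for Hedges' g
#'
#' Exact gamma-function form `J(m) = gamma(m/2) / (sqrt(m/2) gamma((m-1)/2))`
#' evaluated at `m = n`; approximately 0.9228 at n = 10.
#'
#' @param n number of paired observations.
#' @return correction factor in (0, 1).
#' @export
hedges_correction <- function(n) {
  exp(lgamma(n / 2) - 0.5 * log(n / 2) - lgamma((n - 1) / 2))
}

#' Shadow-feature selection
#'
#' Each iteration appends a shuffled copy of every feature ("shadow
#' features"), fits a random forest, and scores a hit for every real feature
#' whose impurity importance exceeds the maximum shadow importance. After
#' `n_iter` iterations a feature is selected when its hit count is
#' significantly above a Binomial(n_iter, 1/2) count (one-sided, level
#' `alpha`); undecided features count as not selected. Constant columns are
#' never selected above their shadows.
#'
#' @param X numeric matrix or data.frame of features.
#' @param y class labels (>= 2 classes).
#' @param n_iter number of random-forest iterations.
#' @param alpha binomial significance level.
#' @param seed integer seed (deterministic selection).
#' @param num_trees trees per forest.
#' @param adjust multiple-comparison adjustment of the per-feature binomial
#'   tests: `"bonferroni"` across the feature set (the canonical
#'   shadow-selection default, which keeps chance correlations of a fixed
#'   dataset from accumulating hits) or `"none"`.
#' @return object of class `shadow_selection`: list with `selected` (feature
#'   names), `hits`, `p_values`, `n_iter`.
#' @export
shadow_select <- function(X, y, n_iter = 50, alpha = 0.05, seed = 1,
                          num_trees = 100,
                          adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (anyNA(X)) stop("X must not contain missing values")
  d <- ncol(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("f", seq_len(d))
  with_seed(seed, {
    hits <- integer(d)
    for (it in seq_len(n_iter)) {
      Xs <- apply(X, 2, sample)
      colnames(Xs) <- paste0(".shadow_", nm)
      Xa <- cbind(X, Xs)
      colnames(Xa) <- c(nm, colnames(Xs))
      fit <- ranger::ranger(
        x = Xa, y = y, num.trees = num_trees, importance = "impurity",
        num.threads = 1, seed = sample.int(.Machine$integer.max - 1, 1),
        verbose = FALSE)
      imp <- fit$variable.importance
      hits <- hits + (imp[seq_len(d)] > max(imp[-seq_len(d)]))
    }
    p <- stats::pbinom(hits - 1, n_iter, 0.5, lower.tail = FALSE)
    cut <- if (adjust == "bonferroni") alpha / d else alpha
    structure(list(selected = nm[p < cut], hits = stats::setNames(hits, nm),
                   p_values = stats::setNames(p, nm), n_iter = n_iter,
                   alpha = alpha, adjust = adjust),
              class = "shadow_selection")
  })
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so fold sizes differ by at most one per class.
stratified_folds <- function(y, k = 10) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) {
      stop("class '", cl, "' has fewer than ", k, " members; cannot stratify")
    }
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

scale_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

scale_apply <- function(X, s) sweep(sweep(X, 2, s$center), 2, s$scale, "/")

#' Cross-validated accuracy of the scaled RBF-SVM pipeline
#'
#' Stratified k-fold cross-validation of a pipeline consisting of standard
#' scaling followed by a radial-basis-function support vector classifier.
#' Scaling is fit on the training folds only. The kernel width defaults to
#' `1 / (n_features * var)` of the scaled training data and the cost to 1.
#'
#' @param X numeric matrix/data.frame of (selected) features; must be
#'   non-empty.
#' @param y class labels.
#' @param seed integer seed controlling the fold partition.
#' @param folds number of folds.
#' @param cost SVM cost parameter.
#' @return numeric vector of per-fold accuracies with the fold assignment in
#'   attribute `folds`.
#' @export
fit_evaluate <- function(X, y, seed = 1, folds = 10, cost = 1) {
  X <- as.matrix(X)
  if (ncol(X) == 0) stop("no features selected")
  y <- factor(y)
  with_seed(seed, {
    fold <- stratified_folds(y, folds)
    acc <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- fold != k
      s <- scale_fit(X[tr, , drop = FALSE])
      Xtr <- scale_apply(X[tr, , drop = FALSE], s)
      Xte <- scale_apply(X[!tr, , drop = FALSE], s)
      g <- 1 / (ncol(X) * mean(apply(Xtr, 2, stats::var)))
      m <- e1071::svm(x = Xtr, y = y[tr], kernel = "radial", cost = cost,
                      gamma = g, scale = FALSE)
      acc[k] <- mean(predict(m, Xte) == y[!tr])
    }
    attr(acc, "folds") <- fold
    acc
  })
}

#' Fit the full-data scaled RBF-SVM pipeline
#'
#' @inheritParams fit_evaluate
#' @return list with the fitted `svm`, the scaler and the class levels.
#' @export
fit_svm_model <- function(X, y, cost = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  s <- scale_fit(X)
  Z <- scale_apply(X, s)
  g <- 1 / (ncol(X) * mean(apply(Z, 2, stats::var)))
  m <- e1071::svm(x = Z, y = y, kernel = "radial", cost = cost, gamma = g,
                  scale = FALSE)
  list(svm = m, scaler = s, levels = levels(y), features = colnames(X))
}

# Two-sided signed-rank p-value, exact when the data allow it.
signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  suppressWarnings(stats::wilcox.test(d, mu = 0, exact = TRUE)$p.value)
}

#' Compare fold accuracies to chance
#'
#' Two-sided one-sample Wilcoxon signed-rank test of the fold accuracies
#' against the chance level (exact null distribution at small n), with a
#' bias-corrected one-sample Hedges' g `= J(n) (mean - chance) / SD`.
#'
#' @param accuracies per-fold accuracies.
#' @param chance chance level (e.g. 0.25 four-way, 0.5 binary).
#' @return list with `p`, `g`, `mean`, `sd`, `n`. Zero fold variance flags
#'   `g` as infinite and derives `p` from the sign pattern.
#' @export
compare_to_chance <- function(accuracies, chance) {
  d <- accuracies - chance
  n <- length(d)
  s <- stats::sd(d)
  m <- mean(d)
  if (s == 0) {
    p <- if (m == 0) 1 else min(1, 2 * 0.5^n)
    g <- if (m == 0) 0 else sign(m) * Inf
  } else {
    p <- signed_rank_p(d)
    g <- hedges_correction(n) * m / s
  }
  list(p = p, g = g, mean = mean(accuracies), sd = s, n = n)
}

#' Pairwise model comparison with Holm correction
#'
#' Paired two-sided Wilcoxon signed-rank tests on the fold accuracies of every
#' model pair (models must share the fold partition), Holm-adjusted across the
#' family, with paired Hedges' g on the fold differences.
#'
#' @param acc_list named list of equal-length fold-accuracy vectors.
#' @return data.frame with `model_a`, `model_b`, `p_raw`, `p_holm`, `g`.
#' @export
compare_models <- function(acc_list) {
  stopifnot(length(acc_list) >= 2)
  ns <- lengths(acc_list)
  if (length(unique(ns)) != 1) stop("mismatched fold counts")
  nm <- names(acc_list)
  pairs <- utils::combn(length(acc_list), 2)
  out <- data.frame(
    model_a = nm[pairs[1, ]], model_b = nm[pairs[2, ]],
    p_raw = NA_real_, p_holm = NA_real_, g = NA_real_,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(pairs))) {
    d <- acc_list[[pairs[1, j]]] - acc_list[[pairs[2, j]]]
    s <- stats::sd(d)
    out$p_raw[j] <- if (all(d == 0)) 1
      else if (s == 0) min(1, 2 * 0.5^length(d))  # constant offset: sign pattern
      else signed_rank_p(d)
    out$g[j] <- if (s == 0) {
      if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else hedges_correction(length(d)) * mean(d) / s
  }
  out$p_holm <- stats::p.adjust(out$p_raw, method = "holm")
  out
}

#' Rank features by Monte-Carlo Shapley attribution
#'
#' Estimates per-feature attributions of the fitted pipeline on a stratified
#' subset of samples with a permutation-based Shapley approximation: features
#' are revealed one at a time in random order, replacing a background sample
#' (a shuffled copy of the subset), and the change in the model's
#' decision-value score for each sample's predicted class is credited to the
#' revealed feature. Ranking is by mean absolute attribution.
#'
#' @param model a [fit_svm_model()] fit.
#' @param X the feature matrix the model was trained on (unscaled).
#' @param y class labels (used for stratifying the subset).
#' @param subset_frac fraction of samples used (stratified by class).
#' @param n_perm number of random feature orderings.
#' @param seed integer seed (deterministic ranking).
#' @return data.frame with `feature` and `attribution`, sorted decreasing.
#' @export
rank_features <- function(model, X, y, subset_frac = 0.2, n_perm = 8,
                          seed = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  with_seed(seed, {
    idx <- unlist(lapply(levels(y), function(cl) {
      i <- which(y == cl)
      sort(i[sample.int(length(i), max(2, round(subset_frac * length(i))))])
    }))
    if (length(idx) < nlevels(y)) stop("subset smaller than number of classes")
    Z <- scale_apply(X[idx, , drop = FALSE], model$scaler)
    n <- nrow(Z); d <- ncol(Z)
    ref <- as.character(predict(model$svm, Z))
    bg <- Z[sample.int(n), , drop = FALSE]
    score <- function(M) {
      dv <- attr(predict(model$svm, M, decision.values = TRUE),
                 "decision.values")
      cn <- strsplit(colnames(dv), "/", fixed = TRUE)
      sc <- numeric(n); k <- numeric(n)
      for (j in seq_along(cn)) {
        a <- cn[[j]][1]; b <- cn[[j]][2]
        ia <- ref == a; ib <- ref == b
        sc[ia] <- sc[ia] + dv[ia, j]; k[ia] <- k[ia] + 1
        sc[ib] <- sc[ib] - dv[ib, j]; k[ib] <- k[ib] + 1
      }
      sc / pmax(k, 1)
    }
    phi <- matrix(0, n, d)
    for (p in seq_len(n_perm)) {
      ord <- sample.int(d)
      M <- bg
      prev <- score(M)
      for (j in ord) {
        M[, j] <- Z[, j]
        cur <- score(M)
        phi[, j] <- phi[, j] + (cur - prev)
        prev <- cur
      }
    }
    phi <- phi / n_perm
    att <- colMeans(abs(phi))
    out <- data.frame(feature = colnames(X), attribution = att,
                      stringsAsFactors = FALSE)
    out[order(-out$attribution), , drop = FALSE]
  })
}
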
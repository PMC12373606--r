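# Selection, cross-validated SVM pipeline, comparison statistics and ranking.

test_that("the Hedges correction factor matches the exact gamma form", {
  expect_equal(hedges_correction(10), 24 / (sqrt(5) * gamma(4.5)),
               tolerance = 1e-12)
  expect_equal(hedges_correction(10), 0.92276, tolerance = 1e-4)
  expect_true(all(diff(sapply(3:30, hedges_correction)) > 0))
})

test_that("comparison to chance uses the exact signed-rank distribution", {
  acc <- 0.25 + c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.07, 0.08, 0.09, 0.10)
  r <- compare_to_chance(acc, 0.25)
  expect_equal(r$p, 2 / 1024, tolerance = 1e-12)
  expect_gt(r$g, 0)

  # symmetric fold pattern: p near 1, g near 0
  sym <- 0.25 + c(-5:-1, 1:5) / 100
  rs <- compare_to_chance(sym, 0.25)
  expect_gt(rs$p, 0.9)
  expect_equal(rs$g, 0, tolerance = 1e-9)

  # mean - chance equal to the fold SD: g is the correction factor itself
  x <- 0.25 + 0.1 * (scale(1:10) / sd(scale(1:10)))[, 1] + 0.1
  rg <- compare_to_chance(x, 0.25)
  expect_equal(rg$g, hedges_correction(10), tolerance = 1e-9)

  # zero variance: sign-pattern p, flagged g
  rz <- compare_to_chance(rep(0.35, 10), 0.25)
  expect_equal(rz$p, 2 / 1024)
  expect_true(is.infinite(rz$g))
  expect_equal(compare_to_chance(rep(0.25, 10), 0.25)$p, 1)
})

test_that("pairwise comparisons apply the Holm step-down", {
  a <- c(0.61, 0.62, 0.63, 0.64, 0.65, 0.66, 0.67, 0.68, 0.69, 0.70)
  r <- compare_models(list(A = a, B = a))
  expect_equal(r$p_raw, 1)
  expect_equal(r$g, 0)

  b <- a - 0.05  # A dominates B on every fold
  r2 <- compare_models(list(A = a, B = b, C = a + rnorm(10, 0, 1e-4)))
  expect_equal(r2$p_raw[r2$model_a == "A" & r2$model_b == "B"], 2 / 1024)
  # Holm-adjusted p never below raw, monotone in raw rank
  expect_true(all(r2$p_holm >= r2$p_raw - 1e-12))
  o <- order(r2$p_raw)
  expect_true(all(diff(r2$p_holm[o]) >= -1e-12))

  expect_error(compare_models(list(A = a, B = a[1:9])), "fold counts")
})

test_that("cross-validation is stratified, deterministic and leak-free", {
  d <- make_informative(n = 200, d_noise = 3, seed = 3)
  acc1 <- fit_evaluate(d$X, d$y, seed = 11)
  acc2 <- fit_evaluate(d$X, d$y, seed = 11)
  expect_identical(as.numeric(acc1), as.numeric(acc2))
  expect_identical(attr(acc1, "folds"), attr(acc2, "folds"))
  fold <- attr(acc1, "folds")
  tab <- table(fold, d$y)
  expect_true(all(tab == 5))  # 200 / (10 folds x 4 classes)

  # perfectly separable classes
  y <- factor(rep(c("p", "q"), each = 100))
  Xs <- cbind(sep = c(rnorm(100, -5), rnorm(100, 5)),
              n1 = rnorm(200))
  expect_gte(mean(fit_evaluate(Xs, y, seed = 2)), 0.98)

  # scaling is fit on training folds only: corrupting one row of test fold 1
  # cannot move fold 1's transform or model, so at most that row's own
  # prediction (1/fold size) can change in fold 1
  Xc <- d$X
  i <- which(attr(acc1, "folds") == 1)[1]
  Xc[i, ] <- Xc[i, ] + 1000
  acc3 <- fit_evaluate(Xc, d$y, seed = 11)
  fold1_n <- sum(attr(acc1, "folds") == 1)
  expect_lte(abs(as.numeric(acc3)[1] - as.numeric(acc1)[1]),
             1 / fold1_n + 1e-12)

  expect_error(fit_evaluate(d$X[1:20, ], d$y[1:20], seed = 1), "stratify")
  expect_error(fit_evaluate(d$X[, 0], d$y, seed = 1), "features")
})

test_that("shadow selection finds real predictors and respects determinism", {
  d <- make_informative(n = 300, d_noise = 10, seed = 5, strength = 3)
  s1 <- shadow_select(d$X, d$y, n_iter = 25, seed = 9)
  s2 <- shadow_select(d$X, d$y, n_iter = 25, seed = 9)
  expect_identical(s1$selected, s2$selected)
  expect_true(all(paste0("inf", 1:5) %in% s1$selected))

  # a feature identical to the numeric class code is always selected
  X2 <- cbind(code = as.integer(d$y), matrix(rnorm(300 * 5), 300, 5))
  colnames(X2) <- c("code", paste0("n", 1:5))
  s3 <- shadow_select(X2, d$y, n_iter = 20, seed = 4)
  expect_true("code" %in% s3$selected)
  expect_false(any(paste0("n", 1:5) %in% s3$selected))

  expect_error(shadow_select(d$X, rep("a", 300)), "2 classes")
  Xna <- d$X; Xna[1, 1] <- NA
  expect_error(shadow_select(Xna, d$y), "missing")
})

test_that("feature ranking is deterministic and splits duplicated credit", {
  with_seed <- gazeforage:::with_seed
  d <- with_seed(21, {
    y <- factor(rep(c("p", "q"), each = 120))
    X <- cbind(sig = c(rnorm(120, -2), rnorm(120, 2)),
               matrix(rnorm(240 * 4), 240, 4))
    colnames(X) <- c("sig", paste0("n", 1:4))
    list(X = X, y = y)
  })
  fit <- fit_svm_model(d$X, d$y)
  r1 <- rank_features(fit, d$X, d$y, seed = 3)
  r2 <- rank_features(fit, d$X, d$y, seed = 3)
  expect_identical(r1, r2)
  expect_equal(r1$feature[1], "sig")

  # duplicating the informative column splits its attribution
  Xd <- cbind(d$X, sig2 = d$X[, "sig"])
  fit2 <- fit_svm_model(Xd, d$y)
  r3 <- rank_features(fit2, Xd, d$y, seed = 3, n_perm = 16)
  single <- r1$attribution[r1$feature == "sig"]
  pair <- sum(r3$attribution[r3$feature %in% c("sig", "sig2")])
  expect_lt(abs(pair - single) / single, 0.2)
})

test_that("the full suite runs end to end on a small effect dataset", {
  sim <- simulate_study(4, 3, seed = 5)
  st <- run_study(sim$features, seed = 2, n_iter = 10, num_trees = 50,
                  rank = TRUE, n_perm = 4)
  expect_equal(length(st$models), 7)
  for (m in st$models) {
    expect_equal(length(m$accuracies), 10)
    expect_true(all(m$accuracies >= 0 & m$accuracies <= 1))
    expect_false(is.null(m$stats$p))
  }
  expect_equal(nrow(st$comparisons$fourway), 3)
  expect_equal(nrow(st$comparisons$binary), 6)
  expect_true(all(st$comparisons$fourway$p_holm >=
                  st$comparisons$fourway$p_raw - 1e-12))
  # rankings exist and cover selected features
  m1 <- st$models$fourway_eye_head
  expect_equal(sort(m1$ranking$feature), sort(m1$selected))
})
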
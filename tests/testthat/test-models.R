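test_that("Tanimoto distance follows the set-overlap definition", {
  a <- c(1, 1, 0, 0, 1)
  expect_equal(tanimoto_distance(a, a), 0)
  expect_equal(tanimoto_distance(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  # |intersection| = 1, |union| = 5
  expect_equal(tanimoto_distance(c(1, 1, 1, 0, 0, 0),
                                 c(1, 0, 0, 1, 1, 0)), 0.8)
  # all-zero convention: identical
  expect_equal(tanimoto_distance(c(0, 0), c(0, 0)), 0)
  expect_error(tanimoto_distance(c(1, 0), c(1, 0, 1)), "width")
  # matrix form agrees with the scalar form
  set.seed(3)
  A <- matrix(rbinom(40, 1, 0.4), 5)
  B <- matrix(rbinom(24, 1, 0.4), 3)
  D <- tanimoto_distance_matrix(A, B)
  for (i in 1:5) for (j in 1:3) {
    expect_equal(D[i, j], tanimoto_distance(A[i, ], B[j, ]))
  }
})

test_that("splits partition the class at the requested fraction", {
  cls <- small_class(n = 300)
  sp <- split_data(cls, seed = 1)
  expect_length(sp$train_ids, 210L)
  expect_length(sp$test_ids, 90L)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0L)
  expect_setequal(c(sp$train_ids, sp$test_ids), cls$compound_id)
  expect_identical(split_data(cls, seed = 1), sp)
  expect_false(identical(split_data(cls, seed = 2)$train_ids, sp$train_ids))
  expect_error(split_data(cls, 1, train_fraction = 1.2), "in \\(0, 1\\)")
  # over 10 splits nearly every compound lands in a test set at least once
  tested <- unique(unlist(lapply(1:10, function(s) {
    split_data(cls, seed = s)$test_ids
  })))
  expect_gt(length(tested) / n_compounds(cls), 0.95)
})

test_that("ensemble aggregation is the member mean and population variance", {
  # arithmetic convention on a toy member matrix: {6,7,8} -> mean 7, var 2/3
  P <- matrix(c(6, 7, 8), 1, 3)
  expect_equal(rowMeans(P), 7)
  expect_equal(potencyUQ:::row_population_var(P), 2 / 3)

  # 3-member toy ensemble matches a brute-force loop over members
  cls <- small_class(n = 80, seed = 3)
  sp <- split_data(cls, 1)
  tr <- training_portion(cls, sp)
  te <- test_portion(cls, sp)[1:5]
  h <- fit_ensemble(ensemble_config("knn", n_estimators = 3,
                                    k_neighbors = 1), tr, seed = 7)
  ps <- predict_with_uncertainty(h, te)
  member_preds <- sapply(h$members, function(mb) {
    potencyUQ:::knn_regress(tr$fingerprints[mb$rows, mb$bits, drop = FALSE],
                            mb$y, te$fingerprints[, mb$bits, drop = FALSE],
                            1L)
  })
  expect_equal(ps$y_pred, rowMeans(member_preds), tolerance = 1e-12)
  expect_equal(ps$variance,
               apply(member_preds, 1, function(v) mean((v - mean(v))^2)),
               tolerance = 1e-12)
})

test_that("ensembles honour their configuration", {
  cls <- small_class(n = 60, seed = 4)
  h <- fit_ensemble(ensemble_config("knn", n_estimators = 100,
                                    max_samples = 0.5), cls, seed = 1)
  expect_length(h$members, 100L)
  expect_length(h$members[[1]]$rows, 30L)
  expect_length(h$members[[1]]$bits, 128L)
  expect_error(fit_ensemble(ensemble_config("knn", k_neighbors = 5,
                                            max_samples = 0.05),
                            cls[1:20], seed = 1), "k_neighbors")
  expect_error(ensemble_config("dt", max_samples = 0.01), "max_samples")
  expect_error(ensemble_config("knn", k_neighbors = 4), "k_neighbors")
})

test_that("a degenerate one-member full-data ensemble has zero variance", {
  cls <- small_class(n = 100, seed = 6)
  h <- fit_ensemble(ensemble_config("dt", n_estimators = 1,
                                    max_samples = 1, max_features = 1),
                    cls, seed = 2)
  ps <- predict_with_uncertainty(h, cls)
  expect_true(all(ps$variance == 0))
})

test_that("1-NN memorises noise-free training data", {
  cls <- noise_free_class()
  h <- fit_ensemble(ensemble_config("knn", n_estimators = 5, k_neighbors = 1,
                                    max_samples = 1, max_features = 1),
                    cls, seed = 3)
  ps <- predict_with_uncertainty(h, cls)
  expect_lt(mse(ps), 1e-20)
  # the single-kNN control reproduces a memorised training label too
  hs <- fit_single_model("knn", cls, k_neighbors = 1)
  ps1 <- predict_with_uncertainty(hs, cls[7])
  expect_equal(ps1$y_pred, cls$pic50[7], tolerance = 1e-12)
})

test_that("single-model controls expose no uncertainty", {
  cls <- small_class(n = 80, seed = 8)
  sp <- split_data(cls, 2)
  h <- fit_single_model("dt", training_portion(cls, sp), seed = 1)
  ps <- predict_with_uncertainty(h, test_portion(cls, sp))
  expect_false(has_uncertainty(ps))
  expect_error(nll(ps), "no predicted variances")
  expect_error(calibration_curve(ps), "no predicted variances")
  expect_error(spearman_rho(ps), "no predicted variances")
})

test_that("ensemble fits and variances are seed-deterministic and order-invariant", {
  cls <- small_class(n = 80, seed = 9)
  sp <- split_data(cls, 3)
  tr <- training_portion(cls, sp); te <- test_portion(cls, sp)
  cfg <- ensemble_config("knn", n_estimators = 10)
  a <- predict_with_uncertainty(fit_ensemble(cfg, tr, seed = 5), te)
  b <- predict_with_uncertainty(fit_ensemble(cfg, tr, seed = 5), te)
  expect_identical(a, b)
  # variance unchanged when member order is permuted
  h <- fit_ensemble(cfg, tr, seed = 5)
  h$members <- rev(h$members)
  c_ <- predict_with_uncertainty(h, te)
  expect_equal(c_$variance, a$variance, tolerance = 1e-12)
})

test_that("grid search minimises cross-validated MSE deterministically", {
  # data where 1-NN is Bayes-optimal: every compound occurs in triplicate
  # with an identical fingerprint and label, so the nearest neighbour of a
  # held-out copy is an exact duplicate while k = 3 must mix in a
  # non-duplicate
  base <- noise_free_class(n = 50, seed = 10)
  idx <- rep(seq_len(50), each = 3)
  cls <- activity_class("tripled", sprintf("t%03d", seq_along(idx)),
                        base$fingerprints[idx, ], base$pic50[idx])
  best <- optimize_hyperparameters("knn", cls, grid = list(1L, 3L, 5L),
                                   folds = 5, seed = 2)
  expect_identical(as.integer(best), 1L)
  scores <- attr(best, "cv_mse")
  expect_length(scores, 3L)
  expect_equal(which.min(scores), 1L)
  # same seed, same fold assignment, same result
  best2 <- optimize_hyperparameters("knn", cls, grid = list(1L, 3L, 5L),
                                    folds = 5, seed = 2)
  expect_equal(attr(best2, "cv_mse"), scores)
  # grid of size one returns that candidate
  one <- ensemble_config("dt", n_estimators = 3)
  got <- optimize_hyperparameters("dt_ensemble", cls[1:60],
                                  grid = list(one), folds = 3, seed = 1)
  attr(got, "cv_mse") <- NULL
  expect_identical(got, one)
})
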
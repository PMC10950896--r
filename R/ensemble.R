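#' Ensemble model configuration
#'
#' Ensembles of kNN or decision-tree (DT) base learners provide
#' model-agnostic uncertainty estimates: each member is fit on a random
#' compound subsample and a random subset of fingerprint bits, and the
#' spread of member predictions yields a per-compound variance. A DT
#' ensemble is a random-forest-style model.
#'
#' @param base_learner `"knn"` or `"dt"`.
#' @param n_estimators Number of ensemble members (paper grid: 100, 150,
#'   200; default 100).
#' @param max_samples Fraction of training compounds per member, in
#'   `[0.05, 1]` (default 0.7).
#' @param max_features Fraction of fingerprint bits per member, in
#'   `[0.05, 1]` (default 0.5).
#' @param k_neighbors Number of neighbours for kNN members (1, 3 or 5;
#'   default 3). Ignored for DT.
#' @param replace Subsample compounds with replacement? Default `FALSE`.
#' @param min_node_size Minimum node size for DT members (default 5).
#' @return An `ensemble_config`.
#' @export
ensemble_config <- function(base_learner = c("knn", "dt"),
                            n_estimators = 100L, max_samples = 0.7,
                            max_features = 0.5, k_neighbors = 3L,
                            replace = FALSE, min_node_size = 5L) {
  base_learner <- match.arg(base_learner)
  if (max_samples < 0.05 || max_samples > 1) {
    stop("max_samples must be in [0.05, 1]")
  }
  if (max_features < 0.05 || max_features > 1) {
    stop("max_features must be in [0.05, 1]")
  }
  if (n_estimators < 1L) stop("n_estimators must be positive")
  if (base_learner == "knn" && !k_neighbors %in% c(1L, 3L, 5L)) {
    stop("k_neighbors must be 1, 3 or 5")
  }
  structure(list(base_learner = base_learner,
                 n_estimators = as.integer(n_estimators),
                 max_samples = max_samples, max_features = max_features,
                 k_neighbors = as.integer(k_neighbors),
                 replace = isTRUE(replace),
                 min_node_size = as.integer(min_node_size)),
            class = "ensemble_config")
}

# Tanimoto-kNN regression: mean label of the k nearest training compounds.
# Ties in distance are broken by training-set order (deterministic).
knn_regress <- function(train_fp, train_y, test_fp, k) {
  d <- tanimoto_distance_matrix(test_fp, train_fp)
  apply(d, 1L, function(row) mean(train_y[order(row)[seq_len(k)]]))
}

#' Fit an ensemble of kNN or DT regressors
#'
#' Each of the `n_estimators` members is fit on `ceiling(max_samples * n)`
#' compounds (without replacement by default) and `ceiling(max_features *
#' n_bits)` fingerprint bit positions, both drawn from member-specific
#' seeded streams, so the fit is fully deterministic given `seed`. DT
#' members are single `ranger` trees grown on the member's data; kNN
#' members store their subsample and predict by Tanimoto-distance
#' nearest-neighbour averaging.
#'
#' @param config An [ensemble_config()].
#' @param train An `activity_class` (the training portion).
#' @param seed Integer seed.
#' @return A `potency_ensemble` handle for [predict_with_uncertainty()].
#' @export
fit_ensemble <- function(config, train, seed = 1L) {
  stopifnot(inherits(config, "ensemble_config"),
            inherits(train, "activity_class"))
  n <- n_compounds(train)
  p <- n_bits(train)
  if (n < 2L) stop("training class too small")
  m_samples <- min(n, as.integer(ceiling(config$max_samples * n)))
  m_bits <- min(p, as.integer(ceiling(config$max_features * p)))
  if (config$base_learner == "knn" && m_samples < config$k_neighbors) {
    stop("member subsample smaller than k_neighbors")
  }
  fp <- train$fingerprints
  members <- vector("list", config$n_estimators)
  for (m in seq_len(config$n_estimators)) {
    ms <- derive_seed(seed, 100L + m)
    members[[m]] <- with_seed(ms, {
      rows <- sample.int(n, m_samples, replace = config$replace)
      bits <- sort(sample.int(p, m_bits))
      if (config$base_learner == "dt") {
        x <- fp[rows, bits, drop = FALSE]
        storage.mode(x) <- "double"
        colnames(x) <- paste0("b", bits)
        fit <- ranger::ranger(x = x, y = train$pic50[rows], num.trees = 1L,
                              mtry = length(bits),
                              min.node.size = config$min_node_size,
                              replace = FALSE, sample.fraction = 1,
                              num.threads = 1L, seed = ms)
        list(bits = bits, fit = fit)
      } else {
        list(bits = bits, rows = rows, y = train$pic50[rows])
      }
    })
  }
  structure(list(config = config, members = members,
                 train_fp = if (config$base_learner == "knn") fp else NULL,
                 class_id = train$class_id, seed = as.integer(seed)),
            class = "potency_ensemble")
}

#' Predict with per-compound uncertainty
#'
#' Generic over fitted model handles. The point prediction is the mean over
#' ensemble members (or Monte Carlo dropout passes), and the reported
#' variance is the population variance (1/n convention) over the same
#' values. Single-model controls produce `NA` variances; downstream metrics
#' that need uncertainties reject such sets.
#'
#' @param handle A fitted model handle.
#' @param test An `activity_class` of test compounds.
#' @param ... Method-specific arguments.
#' @return A [prediction_set()].
#' @export
predict_with_uncertainty <- function(handle, test, ...) {
  UseMethod("predict_with_uncertainty")
}

# population variance across the columns of a prediction matrix
row_population_var <- function(P) {
  mu <- rowMeans(P)
  rowMeans(P * P) - mu * mu
}

#' @rdname predict_with_uncertainty
#' @export
predict_with_uncertainty.potency_ensemble <- function(handle, test, ...) {
  stopifnot(inherits(test, "activity_class"))
  cfg <- handle$config
  test_fp <- test$fingerprints
  storage.mode(test_fp) <- "double"
  P <- vapply(handle$members, function(mb) {
    if (cfg$base_learner == "dt") {
      x <- test_fp[, mb$bits, drop = FALSE]
      colnames(x) <- paste0("b", mb$bits)
      predict(mb$fit, data = x, num.threads = 1L)$predictions
    } else {
      knn_regress(handle$train_fp[mb$rows, mb$bits, drop = FALSE], mb$y,
                  test_fp[, mb$bits, drop = FALSE], cfg$k_neighbors)
    }
  }, numeric(n_compounds(test)))
  P <- matrix(P, nrow = n_compounds(test))
  mu <- rowMeans(P)
  v <- pmax(row_population_var(P), 0)
  prediction_set(test$compound_id, test$pic50, mu, v,
                 model = paste0(cfg$base_learner, "_ensemble"),
                 split = handle$seed)
}

#' Fit a single (control) model
#'
#' Baselines without uncertainty estimates: a single Tanimoto-kNN regressor
#' or a single unpruned decision tree.
#'
#' @param base_learner `"knn"` or `"dt"`.
#' @param train An `activity_class`.
#' @param k_neighbors Number of neighbours for kNN (default 3; typically
#'   chosen by [optimize_hyperparameters()]).
#' @param min_node_size Minimum node size for the DT (default 5).
#' @param seed Integer seed (used by the DT fit).
#' @return A `potency_single` handle.
#' @export
fit_single_model <- function(base_learner = c("knn", "dt"), train,
                             k_neighbors = 3L, min_node_size = 5L,
                             seed = 1L) {
  base_learner <- match.arg(base_learner)
  stopifnot(inherits(train, "activity_class"))
  fit <- NULL
  if (base_learner == "dt") {
    x <- train$fingerprints
    storage.mode(x) <- "double"
    colnames(x) <- paste0("b", seq_len(ncol(x)))
    fit <- ranger::ranger(x = x, y = train$pic50, num.trees = 1L,
                          mtry = ncol(x), min.node.size = min_node_size,
                          replace = FALSE, sample.fraction = 1,
                          num.threads = 1L, seed = derive_seed(seed, 7L))
  }
  structure(list(base_learner = base_learner, fit = fit,
                 train_fp = if (base_learner == "knn") train$fingerprints,
                 train_y = train$pic50, k_neighbors = as.integer(k_neighbors),
                 class_id = train$class_id),
            class = "potency_single")
}

#' @rdname predict_with_uncertainty
#' @export
predict_with_uncertainty.potency_single <- function(handle, test, ...) {
  stopifnot(inherits(test, "activity_class"))
  test_fp <- test$fingerprints
  storage.mode(test_fp) <- "double"
  mu <- if (handle$base_learner == "dt") {
    x <- test_fp
    colnames(x) <- paste0("b", seq_len(ncol(x)))
    predict(handle$fit, data = x, num.threads = 1L)$predictions
  } else {
    knn_regress(handle$train_fp, handle$train_y, test_fp,
                handle$k_neighbors)
  }
  prediction_set(test$compound_id, test$pic50, mu, NA_real_,
                 model = paste0("single_", handle$base_learner), split = "")
}
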
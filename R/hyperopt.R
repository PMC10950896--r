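#' Grid search by k-fold cross-validated MSE
#'
#' Evaluates each candidate configuration by `folds`-fold cross-validation
#' on the training class, scoring with mean squared error, and returns the
#' candidate with the lowest mean CV MSE. Ties are broken by first
#' occurrence in the supplied grid order, and the fold assignment is
#' deterministic given `seed`.
#'
#' @param family `"knn"` (single Tanimoto-kNN; grid entries are values of
#'   `k`), `"knn_ensemble"` or `"dt_ensemble"` (grid entries are
#'   [ensemble_config()] objects).
#' @param train An `activity_class`.
#' @param grid A list of candidates. Defaults: `list(1, 3, 5)` for
#'   `"knn"`; a single default [ensemble_config()] for ensembles (the full
#'   published grid - `max_samples`/`max_features` over
#'   0.05/0.25/0.50/0.75/1.00 and 100/150/200 estimators - can be built
#'   with [ensemble_grid()]).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return The winning grid entry, with the CV MSE of every candidate in
#'   attribute `"cv_mse"`.
#' @export
optimize_hyperparameters <- function(family = c("knn", "knn_ensemble",
                                                "dt_ensemble"),
                                     train, grid = NULL, folds = 5L,
                                     seed = 1L) {
  family <- match.arg(family)
  stopifnot(inherits(train, "activity_class"))
  if (is.null(grid)) {
    grid <- switch(family,
                   knn = list(1L, 3L, 5L),
                   knn_ensemble = list(ensemble_config("knn")),
                   dt_ensemble = list(ensemble_config("dt")))
  }
  if (!length(grid)) stop("hyperparameter grid is empty")
  n <- n_compounds(train)
  if (n < 2L * folds) stop("training class too small for the fold count")
  fold_id <- with_seed(derive_seed(seed, 31L),
                       sample(rep_len(seq_len(folds), n)))
  scores <- vapply(seq_along(grid), function(g) {
    cand <- grid[[g]]
    fold_mse <- vapply(seq_len(folds), function(f) {
      tr <- train[fold_id != f]
      te <- train[fold_id == f]
      ps <- switch(family,
        knn = {
          h <- fit_single_model("knn", tr, k_neighbors = as.integer(cand))
          predict_with_uncertainty(h, te)
        },
        {
          h <- fit_ensemble(cand, tr, seed = derive_seed(seed, 41L + g))
          predict_with_uncertainty(h, te)
        })
      mse(ps)
    }, numeric(1L))
    mean(fold_mse)
  }, numeric(1L))
  best <- grid[[which.min(scores)]]
  attr(best, "cv_mse") <- scores
  best
}

#' Build the published ensemble hyperparameter grid
#'
#' Cartesian grid over subsample fraction, feature fraction, member count
#' and (for kNN) neighbour count, in a canonical ordering for deterministic
#' tie-breaking.
#'
#' @param base_learner `"knn"` or `"dt"`.
#' @param max_samples,max_features Candidate fractions (default
#'   `c(0.05, 0.25, 0.50, 0.75, 1.00)`).
#' @param n_estimators Candidate member counts (default `c(100, 150, 200)`).
#' @param k_neighbors Candidate neighbour counts for kNN (default
#'   `c(1, 3, 5)`).
#' @return A list of [ensemble_config()] objects.
#' @export
ensemble_grid <- function(base_learner = c("knn", "dt"),
                          max_samples = c(0.05, 0.25, 0.50, 0.75, 1.00),
                          max_features = c(0.05, 0.25, 0.50, 0.75, 1.00),
                          n_estimators = c(100L, 150L, 200L),
                          k_neighbors = c(1L, 3L, 5L)) {
  base_learner <- match.arg(base_learner)
  ks <- if (base_learner == "knn") k_neighbors else 3L
  combos <- expand.grid(k = ks, ne = n_estimators, mf = max_features,
                        ms = max_samples, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    ensemble_config(base_learner, n_estimators = combos$ne[i],
                    max_samples = combos$ms[i], max_features = combos$mf[i],
                    k_neighbors = combos$k[i])
  })
}
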
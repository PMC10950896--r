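#' Random train/test split of an activity class
#'
#' Uniform random partition of compound ids, deterministic given the seed.
#' The experiment design uses 10 such splits per class at a 70/30
#' train/test ratio, with the same split shared by every model so that
#' methods are compared on identical data.
#'
#' @param cls An `activity_class`.
#' @param seed Integer seed.
#' @param train_fraction Fraction of compounds assigned to training, in
#'   (0, 1); default 0.7.
#' @return A `split_spec`: list with `train_ids`, `test_ids`, `seed`,
#'   `train_fraction`.
#' @export
split_data <- function(cls, seed, train_fraction = 0.7) {
  stopifnot(inherits(cls, "activity_class"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  n <- n_compounds(cls)
  if (n < 2L) stop("activity class too small to split")
  n_train <- max(1L, min(n - 1L, as.integer(round(train_fraction * n))))
  idx <- with_seed(derive_seed(seed, 3L), sample.int(n, n_train))
  structure(
    list(train_ids = cls$compound_id[sort(idx)],
         test_ids = cls$compound_id[-sort(idx)],
         seed = as.integer(seed), train_fraction = train_fraction),
    class = "split_spec"
  )
}

#' Extract the training / test portion of a class under a split
#' @param cls An `activity_class`.
#' @param split A `split_spec` from [split_data()].
#' @return An `activity_class`.
#' @export
training_portion <- function(cls, split) cls[split$train_ids]

#' @rdname training_portion
#' @export
test_portion <- function(cls, split) cls[split$test_ids]
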
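#' Potency bin scheme
#'
#' Equal-width (by default) left-open/right-closed potency intervals
#' spanning the logarithmic potency range. Test compounds outside the range
#' are clamped into the terminal bins, so every compound maps to exactly
#' one bin.
#'
#' @param range Two-element pIC50 range (default `c(4, 10)`).
#' @param n_bins Number of bins (default 12, i.e. 0.5 log-unit width).
#' @param edges Explicit strictly increasing edge vector overriding
#'   `range`/`n_bins`.
#' @return A `bin_scheme`.
#' @export
bin_scheme <- function(range = c(4, 10), n_bins = 12L, edges = NULL) {
  if (is.null(edges)) {
    edges <- seq(range[1L], range[2L], length.out = n_bins + 1L)
  }
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  structure(list(edges = as.numeric(edges),
                 n_bins = length(edges) - 1L),
            class = "bin_scheme")
}

# Map values to bin indices: edges[j] < x <= edges[j+1]; extremes clamped.
assign_bins <- function(x, scheme) {
  j <- findInterval(x, scheme$edges, left.open = TRUE)
  pmin(pmax(j, 1L), scheme$n_bins)
}

#' Bin-wise coverage and confidence labels
#'
#' Stratifies a prediction set by TRUE pIC50 into potency bins and reports,
#' per bin, the fraction of compounds whose absolute error lies strictly
#' within `x` predicted standard deviations. A bin whose fraction falls
#' below the Gaussian reference `expected_coverage(x)` (68.27% at `x = 1`)
#' is labelled over-confident (the model under-predicts its uncertainty
#' there); above it, under-confident. Empty bins carry count 0 and no
#' label.
#'
#' @param ps A [prediction_set()] with predicted variances.
#' @param scheme A [bin_scheme()].
#' @param x Standard-deviation multiple (default 1.0).
#' @return A data frame of class `binned_confidence`: `bin_lo`, `bin_hi`,
#'   `count`, `fraction_within`, `expected`, `label`.
#' @export
binwise_coverage <- function(ps, scheme = bin_scheme(), x = 1.0) {
  if (!has_uncertainty(ps)) {
    stop("no predicted variances available for this model")
  }
  within <- abs(ps$y_pred - ps$y_true) < x * sqrt(ps$variance)
  bin <- assign_bins(ps$y_true, scheme)
  expected <- expected_coverage(x)
  rows <- lapply(seq_len(scheme$n_bins), function(j) {
    idx <- bin == j
    cnt <- sum(idx)
    frac <- if (cnt > 0L) mean(within[idx]) else NA_real_
    label <- if (cnt == 0L) NA_character_
             else if (frac < expected) "over-confident"
             else if (frac > expected) "under-confident"
             else "calibrated"
    data.frame(bin_lo = scheme$edges[j], bin_hi = scheme$edges[j + 1L],
               count = cnt, fraction_within = frac, expected = expected,
               label = label, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), x = x,
            class = c("binned_confidence", "data.frame"))
}

#' Training-set modification scheme
#'
#' The three potency bins used for training-set modification:
#' `pIC50 <= 5.5`, `5.5 < pIC50 <= 7.5` (central), and `pIC50 > 7.5`.
#'
#' @param mode `"original"` (no change), `"balanced"` (minority sampling to
#'   the smallest bin count) or `"reduced"` (central bin removed).
#' @param seed Integer seed (used by balancing only).
#' @return A `modification_scheme`.
#' @export
modification_scheme <- function(mode = c("original", "balanced", "reduced"),
                                seed = 1L) {
  structure(list(mode = match.arg(mode), edges = c(5.5, 7.5),
                 seed = as.integer(seed)),
            class = "modification_scheme")
}

# 1 = low (<= 5.5), 2 = central (5.5, 7.5], 3 = high (> 7.5)
potency_bin3 <- function(pic50, edges = c(5.5, 7.5)) {
  1L + (pic50 > edges[1L]) + (pic50 > edges[2L])
}

#' Balance a training set across the three potency bins
#'
#' The smallest bin is kept whole and determines how many compounds are
#' drawn uniformly without replacement from each of the other two bins
#' (minority sampling), so every bin ends with exactly the minimum bin
#' count. Deterministic given the scheme's seed.
#'
#' @param train An `activity_class` (training portion only).
#' @param scheme A [modification_scheme()].
#' @return A balanced `activity_class` (subset of the input).
#' @export
balance_training_set <- function(train,
                                 scheme = modification_scheme("balanced")) {
  stopifnot(inherits(train, "activity_class"))
  bins <- potency_bin3(train$pic50, scheme$edges)
  counts <- tabulate(bins, 3L)
  if (any(counts == 0L)) {
    stop("balancing undefined: a potency bin is empty (counts ",
         paste(counts, collapse = "/"), ")")
  }
  m <- min(counts)
  keep <- with_seed(derive_seed(scheme$seed, 51L), {
    unlist(lapply(1:3, function(b) {
      idx <- which(bins == b)
      if (length(idx) == m) idx else sort(sample(idx, m))
    }))
  })
  train[sort(keep)]
}

#' Reduce a training set by removing the central potency bin
#'
#' Drops every training compound with `5.5 < pIC50 <= 7.5`; boundary
#' compounds at 5.5 belong to the low bin and are retained, compounds at
#' 7.5 belong to the central bin and are removed.
#'
#' @param train An `activity_class` (training portion only).
#' @param scheme A [modification_scheme()].
#' @return The reduced `activity_class`; a warning is emitted if nothing
#'   survives.
#' @export
reduce_training_set <- function(train,
                                scheme = modification_scheme("reduced")) {
  stopifnot(inherits(train, "activity_class"))
  keep <- which(potency_bin3(train$pic50, scheme$edges) != 2L)
  if (!length(keep)) warning("reduced training set is empty")
  train[keep]
}

#' Apply a training-set modification
#'
#' Dispatches on the scheme's mode; `"original"` returns the input
#' unchanged. Modification applies to training data only - test sets are
#' never modified.
#'
#' @param train An `activity_class`.
#' @param scheme A [modification_scheme()].
#' @return An `activity_class`.
#' @export
apply_modification <- function(train, scheme) {
  stopifnot(inherits(scheme, "modification_scheme"))
  switch(scheme$mode,
         original = train,
         balanced = balance_training_set(train, scheme),
         reduced = reduce_training_set(train, scheme))
}

#' Write bin-wise confidence rows to CSV
#' @param bc A `binned_confidence` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binned_confidence <- function(bc, path) {
  write.csv(as.data.frame(bc), path, row.names = FALSE)
  invisible(path)
}
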
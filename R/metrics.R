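#' Mean squared error of a prediction set
#' @param ps A [prediction_set()].
#' @return Mean of squared prediction errors.
#' @export
mse <- function(ps) {
  mean((ps$y_pred - ps$y_true)^2)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares taken about the
#' test-set label mean.
#'
#' @param ps A [prediction_set()] with at least two compounds.
#' @return R-squared.
#' @export
r_squared <- function(ps) {
  if (nrow(ps) < 2L) stop("R-squared needs at least two compounds")
  ss_tot <- sum((ps$y_true - mean(ps$y_true))^2)
  if (ss_tot == 0) stop("R-squared undefined: test labels have zero variance")
  1 - sum((ps$y_pred - ps$y_true)^2) / ss_tot
}

#' Gaussian negative log-likelihood
#'
#' `NLL(D) = (1 / (2|D|)) * sum_i [ ln(2 pi) + ln(sigma_i^2) +
#' (yhat_i - y_i)^2 / sigma_i^2 ]` over the `|D|` test compounds, treating
#' each prediction as a Gaussian with the predicted mean and variance. Low
#' values need both small errors and honestly small uncertainties.
#'
#' @param ps A [prediction_set()] with predicted variances.
#' @param var_floor Variances are floored at this value (default 1e-10
#'   pIC50^2) so collapsed ensembles (all members identical) do not yield
#'   infinite log terms; the number of floored compounds is reported in
#'   attribute `"n_floored"`.
#' @return The NLL, with attribute `"n_floored"`.
#' @export
nll <- function(ps, var_floor = 1e-10) {
  if (!has_uncertainty(ps)) {
    stop("no predicted variances available for this model")
  }
  v <- pmax(ps$variance, var_floor)
  out <- mean(log(2 * pi) + log(v) + (ps$y_pred - ps$y_true)^2 / v) / 2
  attr(out, "n_floored") <- sum(ps$variance < var_floor)
  out
}

#' Expected coverage at x standard deviations
#'
#' Fraction of a Gaussian within `x` standard deviations of its mean:
#' `2 * pnorm(x) - 1`. At `x = 1` this is the 68.27% reference used in the
#' bin-wise confidence analysis.
#'
#' @param x Non-negative standard-deviation multiple(s).
#' @return Expected coverage fraction(s) in `[0, 1]`.
#' @examples expected_coverage(1)  # 0.6826895
#' @export
expected_coverage <- function(x) {
  if (any(x < 0)) stop("x must be non-negative")
  2 * pnorm(x) - 1
}

#' Empirical calibration curve
#'
#' For each nominal confidence level `p_j = j / (n_levels + 1)` the curve
#' records the corresponding standard-deviation multiple
#' `x_j = qnorm((1 + p_j) / 2)` and the observed coverage `o_j`: the
#' fraction of compounds whose absolute error is strictly below
#' `x_j * sigma_i`. The curve also stores its endpoint limits: coverage 0
#' at `p = 0` and, at `p = 1`, the fraction of compounds with a positive
#' predicted standard deviation (an infinitely wide band covers any finite
#' error; a zero-width band covers none).
#'
#' @param ps A [prediction_set()] with predicted variances.
#' @param n_levels Number of grid levels (default 99, i.e. p = 0.01..0.99).
#' @return A data frame of class `calibration_curve` with columns `p`, `x`,
#'   `o` and attributes `o0`, `o1`, `n`.
#' @export
calibration_curve <- function(ps, n_levels = 99L) {
  if (!has_uncertainty(ps)) {
    stop("no predicted variances available for this model")
  }
  if (n_levels < 2L) stop("n_levels must be at least 2")
  err <- abs(ps$y_pred - ps$y_true)
  sig <- sqrt(ps$variance)
  p <- seq_len(n_levels) / (n_levels + 1)
  x <- qnorm((1 + p) / 2)
  o <- vapply(x, function(xx) mean(err < xx * sig), numeric(1L))
  structure(data.frame(p = p, x = x, o = o),
            o0 = 0, o1 = mean(sig > 0), n = nrow(ps),
            class = c("calibration_curve", "data.frame"))
}

as_curve <- function(curve, n_levels = 99L) {
  if (inherits(curve, "prediction_set")) curve <- calibration_curve(curve, n_levels)
  if (!inherits(curve, "calibration_curve")) {
    stop("expected a calibration_curve or prediction_set")
  }
  curve
}

# Closed grids for integration over p in [0, 1]: observed curve endpoints
# come from the curve's stored limits.
curve_grids <- function(curve) {
  o1 <- attr(curve, "o1"); if (is.null(o1)) o1 <- curve$o[nrow(curve)]
  o0 <- attr(curve, "o0"); if (is.null(o0)) o0 <- 0
  list(p = c(0, curve$p, 1), o = c(o0, curve$o, o1))
}

# Exact integral of a piecewise-linear function given at nodes (x, y).
trapz <- function(x, y) {
  sum((y[-1L] + y[-length(y)]) / 2 * diff(x))
}

# Exact integral of |piecewise-linear|: segments crossing zero are split at
# the crossing so cancellation inside a segment is handled exactly.
trapz_abs <- function(x, y) {
  total <- 0
  for (i in seq_len(length(x) - 1L)) {
    y1 <- y[i]; y2 <- y[i + 1L]; h <- x[i + 1L] - x[i]
    if (y1 * y2 >= 0) {
      total <- total + h * (abs(y1) + abs(y2)) / 2
    } else {
      t0 <- y1 / (y1 - y2)  # crossing position within the segment
      total <- total + h * (t0 * abs(y1) + (1 - t0) * abs(y2)) / 2
    }
  }
  total
}

#' Miscalibration area
#'
#' Signed area between the observed and expected calibration curves,
#' `A = integral of (o(p) - p) dp` over nominal confidence `p` in `[0, 1]`,
#' evaluated exactly on the piecewise-linear curve closed with its endpoint
#' limits. Negative values mean observed coverage below expected, i.e. an
#' over-confident model (uncertainties too small); positive values an
#' under-confident one. Zero indicates a well-calibrated model, but
#' over- and under-confident regions can cancel - compare with
#' [absolute_miscalibration_area()].
#'
#' @param curve A `calibration_curve`, or a [prediction_set()] (a default
#'   99-level curve is computed).
#' @return The signed area `A`, in `[-0.5, 0.5]`.
#' @export
miscalibration_area <- function(curve) {
  g <- curve_grids(as_curve(curve))
  trapz(g$p, g$o - g$p)
}

#' Absolute miscalibration area
#'
#' `A_abs = integral of |o(p) - p| dp`, the cancellation-free companion of
#' [miscalibration_area()]. Its maximum is 0.5, attained by a degenerate
#' curve with zero observed coverage everywhere (or full coverage
#' everywhere). Note `|A| <= A_abs`, with equality only when `o(p) - p`
#' does not change sign.
#'
#' @inheritParams miscalibration_area
#' @return The absolute area, in `[0, 0.5]`.
#' @export
absolute_miscalibration_area <- function(curve) {
  g <- curve_grids(as_curve(curve))
  trapz_abs(g$p, g$o - g$p)
}

#' Rankings of squared error and predicted variance
#'
#' @param ps A [prediction_set()] with predicted variances.
#' @return List with `v1` (squared errors), `v2` (predicted variances) and
#'   their average-rank vectors `r_v1`, `r_v2`.
#' @export
error_variance_ranking <- function(ps) {
  if (!has_uncertainty(ps)) {
    stop("no predicted variances available for this model")
  }
  v1 <- (ps$y_pred - ps$y_true)^2
  v2 <- ps$variance
  list(v1 = v1, v2 = v2,
       r_v1 = rank(v1, ties.method = "average"),
       r_v2 = rank(v2, ties.method = "average"))
}

#' Spearman rank correlation of squared error vs predicted variance
#'
#' `rho(v1, v2) = cov(r_v1, r_v2) / (sd(r_v1) * sd(r_v2))` over the
#' average-rank vectors of the two inputs. Applied to a prediction set it
#' correlates squared prediction errors with predicted variances:
#' predictions with large claimed uncertainty should also miss by more.
#' Invariant under strictly increasing transforms of either vector.
#'
#' @param x A [prediction_set()], or a numeric vector (then `y` must be the
#'   second vector).
#' @param y Second numeric vector when `x` is a vector.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y = NULL) {
  if (inherits(x, "prediction_set")) {
    rk <- error_variance_ranking(x)
    r1 <- rk$r_v1; r2 <- rk$r_v2
  } else {
    if (is.null(y) || length(y) != length(x)) {
      stop("supply two numeric vectors of equal length")
    }
    r1 <- rank(x, ties.method = "average")
    r2 <- rank(y, ties.method = "average")
  }
  if (length(r1) < 3L) stop("Spearman rho needs at least 3 samples")
  if (sd(r1) == 0 || sd(r2) == 0) {
    stop("Spearman rho undefined: a vector has constant ranks")
  }
  cov(r1, r2) / (sd(r1) * sd(r2))
}

#' Full uncertainty-quantification report for one prediction set
#'
#' One row with the accuracy metrics (MSE, R2) and, when predicted
#' variances are available, the uncertainty metrics (NLL, miscalibration
#' area `A`, absolute miscalibration area `A_abs`, Spearman `rho`).
#' Metrics that need variances are `NA` for single-model controls.
#'
#' @param ps A [prediction_set()].
#' @param class_id,model,split Tags recorded in the row (defaults from the
#'   prediction set's attributes).
#' @param n_levels Calibration-curve grid size (default 99).
#' @return A one-row data frame: `class`, `model`, `split`, `n_test`,
#'   `mse`, `r2`, `nll`, `A`, `A_abs`, `rho`.
#' @export
uq_report <- function(ps, class_id = "", model = NULL, split = NULL,
                      n_levels = 99L) {
  if (is.null(model)) model <- as.character(attr(ps, "model"))
  if (is.null(split)) split <- as.character(attr(ps, "split"))
  has_v <- has_uncertainty(ps)
  curve <- if (has_v) calibration_curve(ps, n_levels)
  data.frame(
    class = class_id, model = model, split = split, n_test = nrow(ps),
    mse = mse(ps), r2 = r_squared(ps),
    nll = if (has_v) as.numeric(nll(ps)) else NA_real_,
    A = if (has_v) miscalibration_area(curve) else NA_real_,
    A_abs = if (has_v) absolute_miscalibration_area(curve) else NA_real_,
    rho = if (has_v) {
      # rho is undefined for constant rank vectors (e.g. a constant-sigma
      # oracle set); report NA rather than fail the whole report row
      tryCatch(spearman_rho(ps), error = function(e) NA_real_)
    } else NA_real_,
    stringsAsFactors = FALSE
  )
}
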
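#' Configuration for a synthetic activity class
#'
#' Defines the generative law used by [generate_activity_class()]. The
#' generator emulates the statistical shape of large curated activity
#' classes: >1000 compounds, sparse 2048-bit fingerprints, a unimodal pIC50
#' distribution peaked at intermediate (micromolar) potency, and enough
#' structure-potency correlation that fingerprint-based regressors attain
#' test R2 in the 0.6-0.7 range.
#'
#' @param n_compounds Number of compounds (>= 10).
#' @param n_bits Fingerprint width (default 2048).
#' @param n_signal_bits Number of potency-determining bits (default 64).
#' @param bit_density Expected fraction of set bits per compound, in (0,1)
#'   (default 0.05).
#' @param potency_range Two-element `c(lo, hi)` on the pIC50 scale; labels
#'   are clipped into this range (default `c(4, 10)`). Must cover the
#'   central potency bin (5.5, 7.5].
#' @param noise_sd Standard deviation of additive Gaussian label noise in
#'   pIC50 units (default 0.6).
#' @param central_mass Minimum fraction of compounds required in the central
#'   potency bin (5.5, 7.5] (default 0.5).
#' @param signal_bit_density Marginal density of the signal bits (default
#'   0.5); within one activity class the potency-determining features are
#'   common, while the remaining bits stay sparse so that the overall
#'   density equals `bit_density`.
#' @param seed Integer master seed; all randomness of the generator derives
#'   from it.
#' @return A `synthetic_class_config`.
#' @export
synthetic_class_config <- function(n_compounds = 2000L, n_bits = 2048L,
                                   n_signal_bits = 64L, bit_density = 0.05,
                                   potency_range = c(4, 10), noise_sd = 0.6,
                                   central_mass = 0.5,
                                   signal_bit_density = 0.5, seed = 1L) {
  stop_if_not_scalar_number(n_compounds, "n_compounds", positive = TRUE)
  stop_if_not_scalar_number(n_bits, "n_bits", positive = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd")
  if (n_compounds < 10) stop("n_compounds must be at least 10")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (bit_density <= 0 || bit_density >= 1) stop("bit_density must be in (0,1)")
  if (signal_bit_density <= 0 || signal_bit_density >= 1) {
    stop("signal_bit_density must be in (0,1)")
  }
  if (n_signal_bits > n_bits) stop("n_signal_bits must not exceed n_bits")
  if (length(potency_range) != 2L || !all(is.finite(potency_range)) ||
      potency_range[1L] >= potency_range[2L]) {
    stop("potency_range must be c(lo, hi) with lo < hi")
  }
  if (potency_range[1L] > 5.5 || potency_range[2L] < 7.5) {
    stop("potency_range must cover the central potency bin (5.5, 7.5]")
  }
  if (central_mass <= 0 || central_mass >= 1) {
    stop("central_mass must be in (0,1)")
  }
  noise_density <- (bit_density * n_bits - signal_bit_density * n_signal_bits) /
    (n_bits - n_signal_bits)
  if (noise_density <= 0 || noise_density >= 1) {
    stop("bit_density incompatible with n_signal_bits at signal_bit_density; ",
         "overall density leaves no room for background bits")
  }
  structure(
    list(n_compounds = as.integer(n_compounds), n_bits = as.integer(n_bits),
         n_signal_bits = as.integer(n_signal_bits), bit_density = bit_density,
         potency_range = as.numeric(potency_range), noise_sd = noise_sd,
         central_mass = central_mass,
         signal_bit_density = signal_bit_density,
         noise_density = noise_density, seed = as.integer(seed)),
    class = "synthetic_class_config"
  )
}

#' Generate a synthetic activity class
#'
#' Compounds carry a latent "decoration level" `u ~ N(0,1)`; each of the
#' `n_signal_bits` signal bits is a threshold feature (`bit j` set iff
#' `u > c_j` for a per-bit threshold `c_j ~ N(0,1)`). The label is linear in
#' the bits: `pic50 = intercept + sum_j w_j b_j + eps`, `eps ~ N(0,
#' noise_sd^2)`, with non-negative weights `w_j`. Because the signal bits are
#' monotone encodings of the same latent, fingerprint similarity is
#' informative about potency - the property of real activity classes that
#' makes nearest-neighbour and tree models work. The remaining bits are iid
#' sparse background. The signal scale is calibrated by bisection on the
#' realized sample so that the central bin (5.5, 7.5] holds at least
#' `central_mass + 0.05` of the compounds; labels are finally clipped into
#' `potency_range`, creating mild boundary mass akin to assay floor/ceiling
#' effects.
#'
#' The fitted signal (bit positions, weights, intercept) is stored in the
#' `"signal"` attribute so the Bayes-optimal predictor
#' `intercept + FP[, bits] %*% weights` can be recomputed exactly.
#'
#' @param config A [synthetic_class_config()].
#' @param class_id Label for the generated class.
#' @return An `activity_class` with a `"signal"` attribute.
#' @examples
#' cls <- generate_activity_class(synthetic_class_config(n_compounds = 200))
#' mean(cls$pic50 > 5.5 & cls$pic50 <= 7.5)
#' @export
generate_activity_class <- function(config, class_id = "synthetic") {
  stopifnot(inherits(config, "synthetic_class_config"))
  n <- config$n_compounds
  with_seed(derive_seed(config$seed, 1L), {
    sig_pos <- sample.int(config$n_bits, config$n_signal_bits)
    u <- rnorm(n)
    thresholds <- rnorm(config$n_signal_bits)
    B <- matrix(0L, n, config$n_signal_bits)
    B[outer(u, thresholds, ">")] <- 1L
    n_noise <- config$n_bits - config$n_signal_bits
    FP <- matrix(0L, n, config$n_bits)
    FP[, sig_pos] <- B
    FP[, -sig_pos] <- matrix(rbinom(n * n_noise, 1L, config$noise_density),
                             n, n_noise)
    w_raw <- abs(rnorm(config$n_signal_bits))
    s_raw <- as.numeric(B %*% w_raw)
    s_centered <- s_raw - mean(s_raw)
    eps <- rnorm(n, 0, config$noise_sd)
    target_mass <- min(config$central_mass + 0.05, 0.99)
    scale <- calibrate_signal_scale(s_centered, eps, target_mass)
    weights <- scale * w_raw
    intercept <- 6.5 - scale * mean(s_raw)
    pic50 <- pmin(pmax(intercept + as.numeric(FP[, sig_pos] %*% weights) + eps,
                       config$potency_range[1L]), config$potency_range[2L])
    cls <- activity_class(class_id,
                          sprintf("CPD_%05d", seq_len(n)), FP, pic50)
    attr(cls, "signal") <- list(bits = sig_pos, weights = weights,
                                intercept = intercept,
                                noise_sd = config$noise_sd)
    cls
  })
}

# Largest signal scale `a` such that the realized fraction of
# `a * s + eps` within (-1, 1] is still >= target_mass. The fraction is a
# non-increasing step function of `a`; bisection keeps the feasible endpoint.
calibrate_signal_scale <- function(s_centered, eps, target_mass) {
  central <- function(a) {
    v <- a * s_centered + eps
    mean(v > -1 & v <= 1)
  }
  if (central(0) < target_mass) {
    stop("noise_sd is too large for the requested central_mass")
  }
  hi <- 1 / max(sd(s_centered), 1e-12)
  grow <- 0L
  while (central(hi) >= target_mass && grow < 60L) {
    hi <- hi * 2
    grow <- grow + 1L
  }
  if (central(hi) >= target_mass) return(hi)
  lo <- 0
  for (i in seq_len(60L)) {
    mid <- (lo + hi) / 2
    if (central(mid) >= target_mass) lo <- mid else hi <- mid
  }
  lo
}

#' Configuration for synthetic prediction/uncertainty pairs
#'
#' Describes a model-free oracle for the metric suite: true labels, point
#' predictions and predicted variances with a known calibration factor. The
#' predictor reports standard deviation `sigma_i` while its actual error is
#' drawn with standard deviation `c * sigma_i`; `c = 1` yields a perfectly
#' calibrated set, `c > 1` an over-confident one (errors larger than
#' claimed), `c < 1` an under-confident one.
#'
#' @param n Number of samples.
#' @param sigma_law Either a single positive number (constant sigma), a
#'   function `function(n) -> positive vector`, or a numeric vector of
#'   length `n`.
#' @param calibration_factor Positive scalar `c`.
#' @param seed Integer master seed.
#' @return A `synthetic_prediction_config`.
#' @export
synthetic_prediction_config <- function(n = 1000L, sigma_law = 0.5,
                                        calibration_factor = 1, seed = 1L) {
  stop_if_not_scalar_number(n, "n", positive = TRUE)
  stop_if_not_scalar_number(calibration_factor, "calibration_factor",
                            positive = TRUE)
  if (is.numeric(sigma_law) && any(sigma_law <= 0)) {
    stop("sigma_law values must be positive")
  }
  structure(
    list(n = as.integer(n), sigma_law = sigma_law,
         calibration_factor = calibration_factor, seed = as.integer(seed)),
    class = "synthetic_prediction_config"
  )
}

#' Generate a prediction set with controlled calibration
#'
#' Labels are drawn from a fixed unimodal potency-like law
#' (`y ~ N(6.5, 1.3^2)`); predictions are `y + e` with
#' `e ~ N(0, (c * sigma_i)^2)` while the reported variance is `sigma_i^2`.
#'
#' @param config A [synthetic_prediction_config()].
#' @return A [prediction_set()] tagged `model = "synthetic"`.
#' @examples
#' ps <- generate_prediction_set(
#'   synthetic_prediction_config(n = 500, sigma_law = 0.5, seed = 7))
#' mean(abs(ps$y_pred - ps$y_true) < sqrt(ps$variance))  # ~ 0.68
#' @export
generate_prediction_set <- function(config) {
  stopifnot(inherits(config, "synthetic_prediction_config"))
  n <- config$n
  with_seed(derive_seed(config$seed, 2L), {
    sigma <- if (is.function(config$sigma_law)) {
      config$sigma_law(n)
    } else if (length(config$sigma_law) == 1L) {
      rep(as.numeric(config$sigma_law), n)
    } else {
      as.numeric(config$sigma_law)
    }
    if (length(sigma) != n || any(!is.finite(sigma)) || any(sigma <= 0)) {
      stop("sigma_law must yield n finite positive values")
    }
    y <- rnorm(n, 6.5, 1.3)
    e <- rnorm(n, 0, config$calibration_factor * sigma)
    prediction_set(compound_id = sprintf("S_%06d", seq_len(n)),
                   y_true = y, y_pred = y + e, variance = sigma^2,
                   model = "synthetic", split = NA_character_)
  })
}

#' Construct a prediction set
#'
#' Per test compound: true pIC50, predicted mean and (optionally) predicted
#' variance. Single-model controls carry `NA` variances; metric functions
#' that need uncertainties refuse such sets explicitly.
#'
#' @param compound_id Character identifiers.
#' @param y_true,y_pred Numeric vectors (pIC50).
#' @param variance Numeric vector of predicted variances (pIC50^2), or `NA`
#'   for models without uncertainty estimates.
#' @param model,split Tags recorded as attributes.
#' @return A data frame of class `prediction_set`.
#' @export
prediction_set <- function(compound_id, y_true, y_pred,
                           variance = NA_real_, model = "", split = "") {
  n <- length(y_true)
  if (length(variance) == 1L) variance <- rep(variance, n)
  if (length(y_pred) != n || length(variance) != n ||
      length(compound_id) != n) {
    stop("prediction_set fields must have equal lengths")
  }
  if (any(!is.na(variance) & variance < 0)) {
    stop("predicted variances must be non-negative")
  }
  structure(
    data.frame(compound_id = as.character(compound_id),
               y_true = as.numeric(y_true), y_pred = as.numeric(y_pred),
               variance = as.numeric(variance), stringsAsFactors = FALSE),
    model = model, split = split,
    class = c("prediction_set", "data.frame")
  )
}

#' Does a prediction set carry predicted variances?
#' @param ps A `prediction_set`.
#' @return `TRUE` if all variances are present.
#' @export
has_uncertainty <- function(ps) {
  !anyNA(ps$variance)
}

#' Write / read prediction sets as CSV
#'
#' Columns: `compound_id,y_true,y_pred,variance,model,split`.
#' @param ps A `prediction_set`.
#' @param path File path.
#' @return `path` invisibly (writer); a `prediction_set` (reader).
#' @export
write_prediction_set <- function(ps, path) {
  df <- as.data.frame(ps)
  df$model <- attr(ps, "model")
  df$split <- attr(ps, "split")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prediction_set
#' @export
read_prediction_set <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  prediction_set(df$compound_id, df$y_true, df$y_pred, df$variance,
                 model = df$model[1L], split = df$split[1L])
}
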
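#' Neural network configuration
#'
#' Two families are provided. `"ffnn"` is a feed-forward regressor trained
#' on MSE with dropout between all hidden layers; the dropout stays active
#' at prediction time and uncertainty comes from Monte Carlo sampling over
#' stochastic forward passes. `"mve"` is a mean-variance estimation
#' network with two output heads (predicted mean and log-variance) trained
#' on the per-sample Gaussian negative log-likelihood with early stopping.
#'
#' The `"paper"` profile uses the full published architectures: large =
#' four hidden layers (1000, 1000, 100, 10), small = two hidden layers of
#' 300 units; learning rate 1e-3, batch size 32; FFNN 600 epochs with 100
#' Monte Carlo prediction trials; MVE up to 4000 epochs with patience 100
#' on the training loss. The `"desk"` profile keeps the small 300-unit
#' architecture but caps training at 50 epochs so full experiments run in
#' minutes on one CPU; desk MVE monitors a 15% validation split with
#' patience 5 and restores the best weights, which prevents the variance
#' head from collapsing once the mean head starts memorising.
#'
#' @param family `"ffnn"` or `"mve"`.
#' @param size `"small"` or `"large"`.
#' @param dropout_rate FFNN dropout rate: 0.10, 0.20 or 0.50.
#' @param profile `"paper"` or `"desk"`.
#' @param hidden_sizes,max_epochs,patience,monitor,valid_fraction,
#'   restore_best,learning_rate,batch_size,n_mc_trials Optional overrides
#'   of the profile defaults.
#' @return A `network_config`.
#' @export
network_config <- function(family = c("ffnn", "mve"),
                           size = c("small", "large"),
                           dropout_rate = 0.10,
                           profile = c("paper", "desk"),
                           hidden_sizes = NULL, max_epochs = NULL,
                           patience = NULL, monitor = NULL,
                           valid_fraction = 0.15, restore_best = NULL,
                           learning_rate = 1e-3, batch_size = 32L,
                           n_mc_trials = 100L) {
  family <- match.arg(family)
  size <- match.arg(size)
  profile <- match.arg(profile)
  if (family == "ffnn" && !dropout_rate %in% c(0.10, 0.20, 0.50)) {
    stop("dropout_rate must be 0.10, 0.20 or 0.50")
  }
  if (is.null(hidden_sizes)) {
    hidden_sizes <- if (profile == "paper" && size == "large") {
      c(1000L, 1000L, 100L, 10L)
    } else {
      c(300L, 300L)
    }
  }
  if (is.null(max_epochs)) {
    max_epochs <- if (profile == "desk") 50L
                  else if (family == "ffnn") 600L else 4000L
  }
  if (is.null(monitor)) {
    monitor <- if (family == "mve" && profile == "desk") "valid" else "train"
  }
  if (is.null(patience)) {
    patience <- if (family == "ffnn") Inf
                else if (profile == "paper") 100L else 5L
  }
  if (is.null(restore_best)) restore_best <- monitor == "valid"
  structure(list(family = family, size = size, profile = profile,
                 hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = if (family == "ffnn") dropout_rate else 0,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = patience,
                 monitor = monitor, valid_fraction = valid_fraction,
                 restore_best = isTRUE(restore_best),
                 n_mc_trials = as.integer(n_mc_trials)),
            class = "network_config")
}

as_input_matrix <- function(cls) {
  x <- cls$fingerprints
  storage.mode(x) <- "double"  # raw 0/1 bits, no scaling
  x
}

#' Fit a feed-forward network with dropout
#'
#' ReLU hidden layers, dropout between all hidden layers, Adam with the
#' configured learning rate and batch size, MSE loss, fixed number of
#' epochs. Deterministic given `seed`.
#'
#' @param config A [network_config()] with `family = "ffnn"`.
#' @param train An `activity_class`.
#' @param seed Integer seed.
#' @return An `ffnn_dropout` handle.
#' @export
fit_ffnn_dropout <- function(config, train, seed = 1L) {
  stopifnot(inherits(config, "network_config"), config$family == "ffnn",
            inherits(train, "activity_class"))
  fit <- mlp_train(as_input_matrix(train), train$pic50,
                   hidden = config$hidden_sizes, n_out = 1L, loss = "mse",
                   dropout = config$dropout_rate,
                   max_epochs = config$max_epochs,
                   batch_size = config$batch_size,
                   lr = config$learning_rate, patience = config$patience,
                   monitor = config$monitor,
                   valid_fraction = config$valid_fraction,
                   restore_best = config$restore_best, seed = seed)
  structure(list(config = config, params = fit$params,
                 epochs = fit$epochs, seed = as.integer(seed),
                 class_id = train$class_id),
            class = "ffnn_dropout")
}

#' Monte Carlo dropout prediction
#'
#' Runs `n_trials` stochastic forward passes with dropout active and
#' reports the per-compound mean and population variance over the passes as
#' the prediction and its uncertainty.
#'
#' @param handle An `ffnn_dropout` handle.
#' @param test An `activity_class`.
#' @param n_trials Number of stochastic passes (default: the configured
#'   `n_mc_trials`, 100).
#' @param seed Integer seed for the dropout masks.
#' @return A [prediction_set()].
#' @export
mc_dropout_predict <- function(handle, test, n_trials = NULL, seed = 1L) {
  stopifnot(inherits(handle, "ffnn_dropout"),
            inherits(test, "activity_class"))
  if (is.null(n_trials)) n_trials <- handle$config$n_mc_trials
  X <- as_input_matrix(test)
  P <- with_seed(derive_seed(seed, 21L), {
    vapply(seq_len(n_trials), function(i) {
      mlp_forward(handle$params, X, dropout = handle$config$dropout_rate)[, 1L]
    }, numeric(nrow(X)))
  })
  P <- matrix(P, nrow = nrow(X))
  prediction_set(test$compound_id, test$pic50, rowMeans(P),
                 pmax(row_population_var(P), 0),
                 model = sprintf("ffnn_%s_d%02d", handle$config$size,
                                 round(100 * handle$config$dropout_rate)),
                 split = handle$seed)
}

#' @rdname predict_with_uncertainty
#' @param seed Seed for the Monte Carlo dropout masks.
#' @export
predict_with_uncertainty.ffnn_dropout <- function(handle, test, seed = 1L,
                                                  ...) {
  mc_dropout_predict(handle, test, seed = seed)
}

#' Fit a mean-variance estimation network
#'
#' Two output heads of size one (predicted mean and log-variance; the
#' exponential link keeps the variance positive), trained on the Gaussian
#' negative log-likelihood. Training halts when the monitored loss has not
#' decreased for `patience` consecutive epochs, up to `max_epochs`.
#'
#' @param config A [network_config()] with `family = "mve"`.
#' @param train An `activity_class`.
#' @param seed Integer seed.
#' @return An `mve_network` handle.
#' @export
fit_mve <- function(config, train, seed = 1L) {
  stopifnot(inherits(config, "network_config"), config$family == "mve",
            inherits(train, "activity_class"))
  fit <- mlp_train(as_input_matrix(train), train$pic50,
                   hidden = config$hidden_sizes, n_out = 2L, loss = "nll",
                   dropout = 0, max_epochs = config$max_epochs,
                   batch_size = config$batch_size,
                   lr = config$learning_rate, patience = config$patience,
                   monitor = config$monitor,
                   valid_fraction = config$valid_fraction,
                   restore_best = config$restore_best, seed = seed)
  structure(list(config = config, params = fit$params,
                 epochs = fit$epochs, seed = as.integer(seed),
                 class_id = train$class_id),
            class = "mve_network")
}

#' Predict mean and variance from an MVE network
#'
#' @param handle An `mve_network` handle.
#' @param test An `activity_class`.
#' @param var_floor Lower bound applied to the predicted variance
#'   (default 1e-6 pIC50^2) so the Gaussian likelihood stays finite.
#' @return A [prediction_set()].
#' @export
mve_predict <- function(handle, test, var_floor = 1e-6) {
  stopifnot(inherits(handle, "mve_network"),
            inherits(test, "activity_class"))
  out <- mlp_forward(handle$params, as_input_matrix(test))
  v <- pmax(exp(pmin(pmax(out[, 2L], -LOGVAR_CLAMP), LOGVAR_CLAMP)),
            var_floor)
  prediction_set(test$compound_id, test$pic50, out[, 1L], v,
                 model = sprintf("mve_%s", handle$config$size),
                 split = handle$seed)
}

#' @rdname predict_with_uncertainty
#' @export
predict_with_uncertainty.mve_network <- function(handle, test, ...) {
  mve_predict(handle, test, ...)
}
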
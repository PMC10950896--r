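# Dense multilayer perceptron with ReLU activations, inverted dropout,
# Adam optimisation and either MSE or per-sample Gaussian NLL loss.
# Implemented on BLAS matrix products; networks of the sizes used here
# (hundreds of units, thousands of compounds) train in seconds to minutes
# on one CPU.

LOG_2PI <- log(2 * pi)
LOGVAR_CLAMP <- 12  # log-variance head clamped to +/- this before exp()

mlp_init <- function(n_in, hidden, n_out, seed) {
  with_seed(seed, {
    dims <- c(n_in, hidden, n_out)
    W <- vector("list", length(dims) - 1L)
    b <- vector("list", length(dims) - 1L)
    for (l in seq_along(W)) {
      # He initialisation for ReLU layers
      W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1L], 0, sqrt(2 / dims[l])),
                       dims[l], dims[l + 1L])
      b[[l]] <- rep(0, dims[l + 1L])
    }
    list(W = W, b = b)
  })
}

adam_init <- function(params) {
  zero <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zero, v = zero, t = 0L)
}

# Forward pass. Dropout (inverted scaling) is applied to the activations of
# hidden layers 1..H-1, i.e. between all hidden layers, never on the input
# or output. Returns the output matrix; with cache = TRUE also the
# per-layer inputs and dropout masks needed for backprop.
mlp_forward <- function(params, X, dropout = 0, cache = FALSE) {
  H <- length(params$W) - 1L
  A <- if (cache) vector("list", H + 1L)
  masks <- if (cache) vector("list", H)
  Z <- X
  for (l in seq_len(H)) {
    if (cache) A[[l]] <- Z
    Z <- pmax(sweep(Z %*% params$W[[l]], 2L, params$b[[l]], "+"), 0)
    if (dropout > 0 && l < H) {
      m <- matrix(rbinom(length(Z), 1L, 1 - dropout) / (1 - dropout),
                  nrow(Z))
      Z <- Z * m
      if (cache) masks[[l]] <- m
    }
  }
  if (cache) A[[H + 1L]] <- Z
  out <- sweep(Z %*% params$W[[H + 1L]], 2L, params$b[[H + 1L]], "+")
  if (cache) list(out = out, A = A, masks = masks) else out
}

# Loss value and gradient w.r.t. the network output for one mini-batch.
# "mse": one output unit. "nll": two output units (mean, log-variance);
# per-sample 0.5 * (log 2pi + log sigma^2 + (y - mu)^2 / sigma^2).
mlp_loss_grad <- function(out, y, loss) {
  B <- length(y)
  if (loss == "mse") {
    err <- out[, 1L] - y
    list(loss = sum(err^2), dout = matrix(2 * err / B, B, 1L))
  } else {
    mu <- out[, 1L]
    s <- pmin(pmax(out[, 2L], -LOGVAR_CLAMP), LOGVAR_CLAMP)
    r <- y - mu
    iv <- exp(-s)
    list(loss = sum(0.5 * (LOG_2PI + s + r^2 * iv)),
         dout = cbind(-r * iv / B, 0.5 * (1 - r^2 * iv) / B))
  }
}

# One epoch of mini-batch Adam. Returns updated params/state and the mean
# per-sample training loss. Mutates nothing; caller reassigns.
mlp_epoch <- function(params, state, X, y, loss, dropout, batch_size, lr) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- nrow(X)
  H <- length(params$W) - 1L
  idx <- sample.int(n)
  total <- 0
  for (s0 in seq(1L, n, by = batch_size)) {
    ii <- idx[s0:min(s0 + batch_size - 1L, n)]
    fw <- mlp_forward(params, X[ii, , drop = FALSE], dropout, cache = TRUE)
    lg <- mlp_loss_grad(fw$out, y[ii], loss)
    if (!is.finite(lg$loss)) {
      stop(sprintf("non-finite training loss in batch starting at %d ",
                   s0), "(exploding gradients); lower the learning rate")
    }
    total <- total + lg$loss
    dZ <- lg$dout
    state$t <- state$t + 1L
    corr1 <- 1 - b1^state$t
    corr2 <- 1 - b2^state$t
    for (l in (H + 1L):1L) {
      gW <- crossprod(fw$A[[l]], dZ)
      gb <- colSums(dZ)
      if (l > 1L) {
        dA <- tcrossprod(dZ, params$W[[l]])
        if (!is.null(fw$masks[[l - 1L]])) dA <- dA * fw$masks[[l - 1L]]
        dZ <- dA * (fw$A[[l]] > 0)
      }
      state$m$W[[l]] <- b1 * state$m$W[[l]] + (1 - b1) * gW
      state$v$W[[l]] <- b2 * state$v$W[[l]] + (1 - b2) * gW * gW
      state$m$b[[l]] <- b1 * state$m$b[[l]] + (1 - b1) * gb
      state$v$b[[l]] <- b2 * state$v$b[[l]] + (1 - b2) * gb * gb
      params$W[[l]] <- params$W[[l]] -
        lr * (state$m$W[[l]] / corr1) / (sqrt(state$v$W[[l]] / corr2) + eps)
      params$b[[l]] <- params$b[[l]] -
        lr * (state$m$b[[l]] / corr1) / (sqrt(state$v$b[[l]] / corr2) + eps)
    }
  }
  list(params = params, state = state, loss = total / n)
}

# Early-stopping bookkeeping as a pure function: given the monitored loss
# trace so far and a patience, return TRUE when the last `patience` epochs
# brought no improvement over the running best.
stop_early <- function(loss_trace, patience, tol = 1e-8) {
  if (!is.finite(patience) && patience > 0) return(FALSE)
  k <- length(loss_trace)
  if (k <= patience) return(FALSE)
  best_before <- min(loss_trace[seq_len(k - patience)])
  all(loss_trace[(k - patience + 1L):k] > best_before - tol)
}

# Full training loop with optional validation-split monitoring and
# best-weight restore. Returns params, the loss trace and the epoch count.
mlp_train <- function(X, y, hidden, n_out, loss, dropout = 0,
                      max_epochs = 100L, batch_size = 32L, lr = 1e-3,
                      patience = Inf, monitor = c("train", "valid"),
                      valid_fraction = 0.15, restore_best = FALSE,
                      seed = 1L) {
  monitor <- match.arg(monitor)
  params <- mlp_init(ncol(X), hidden, n_out, derive_seed(seed, 11L))
  state <- adam_init(params)
  vi <- NULL
  if (monitor == "valid") {
    vi <- with_seed(derive_seed(seed, 12L),
                    sample.int(nrow(X), max(1L, round(valid_fraction * nrow(X)))))
    Xv <- X[vi, , drop = FALSE]; yv <- y[vi]
    X <- X[-vi, , drop = FALSE]; y <- y[-vi]
  }
  trace <- numeric(0)
  best_loss <- Inf
  best_params <- params
  with_seed(derive_seed(seed, 13L), {
    for (ep in seq_len(max_epochs)) {
      r <- mlp_epoch(params, state, X, y, loss, dropout, batch_size, lr)
      params <- r$params; state <- r$state
      monitored <- if (monitor == "train") r$loss else {
        fw <- mlp_forward(params, Xv)
        mlp_loss_grad(fw, yv, loss)$loss / length(yv)
      }
      trace <- c(trace, monitored)
      if (monitored < best_loss - 1e-8) {
        best_loss <- monitored
        if (restore_best) best_params <- params
      }
      if (stop_early(trace, patience)) break
    }
  })
  list(params = if (restore_best) best_params else params,
       trace = trace, epochs = length(trace))
}
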
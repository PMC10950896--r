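# Network tests use deliberately small fixtures (256-bit fingerprints,
# 64-128 unit hidden layers) so the whole file runs in well under a minute.

net_fixture <- function(n = 400, seed = 5) small_class(n = n, seed = seed)

test_that("MC dropout produces the configured number of stochastic passes", {
  cls <- net_fixture(n = 150)
  sp <- split_data(cls, 1)
  cfg <- network_config("ffnn", "small", 0.2, "desk",
                        hidden_sizes = c(32, 32), max_epochs = 5)
  expect_equal(cfg$n_mc_trials, 100L)
  h <- fit_ffnn_dropout(cfg, training_portion(cls, sp), seed = 3)
  te <- test_portion(cls, sp)
  # default trial count equals the configured 100
  a <- mc_dropout_predict(h, te, seed = 9)
  b <- mc_dropout_predict(h, te, n_trials = 100, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$variance > 0))
})

test_that("without dropout all stochastic passes coincide", {
  cls <- net_fixture(n = 120)
  cfg <- network_config("ffnn", "small", 0.1, "desk",
                        hidden_sizes = c(16, 16), max_epochs = 3)
  h <- fit_ffnn_dropout(cfg, cls, seed = 1)
  h$config$dropout_rate <- 0
  ps <- mc_dropout_predict(h, cls[1:20], n_trials = 25, seed = 2)
  expect_true(all(ps$variance == 0))
})

test_that("a scaled-down FFNN beats a label-shuffle control", {
  cls <- net_fixture(n = 260, seed = 12)
  sp <- split_data(cls, 4)
  tr <- training_portion(cls, sp); te <- test_portion(cls, sp)
  cfg <- network_config("ffnn", "small", 0.2, "desk",
                        hidden_sizes = c(128, 128), max_epochs = 50)
  ps <- mc_dropout_predict(fit_ffnn_dropout(cfg, tr, seed = 2), te, seed = 3)
  shuffled <- tr
  set.seed(99)
  shuffled$pic50 <- sample(tr$pic50)  # destroys the bit-label association
  ps0 <- mc_dropout_predict(fit_ffnn_dropout(cfg, shuffled, seed = 2), te,
                            seed = 3)
  expect_gt(r_squared(ps), 0)
  expect_gt(r_squared(ps), r_squared(ps0))
})

test_that("network training is deterministic given the seed", {
  cls <- net_fixture(n = 120)
  cfg <- network_config("ffnn", "small", 0.5, "desk",
                        hidden_sizes = c(24, 24), max_epochs = 4)
  h1 <- fit_ffnn_dropout(cfg, cls, seed = 11)
  h2 <- fit_ffnn_dropout(cfg, cls, seed = 11)
  expect_identical(h1$params, h2$params)
  m1 <- fit_mve(network_config("mve", "small", profile = "desk",
                               hidden_sizes = c(24, 24), max_epochs = 4,
                               monitor = "train", patience = Inf,
                               restore_best = FALSE), cls, seed = 11)
  m2 <- fit_mve(network_config("mve", "small", profile = "desk",
                               hidden_sizes = c(24, 24), max_epochs = 4,
                               monitor = "train", patience = Inf,
                               restore_best = FALSE), cls, seed = 11)
  expect_identical(m1$params, m2$params)
})

test_that("the MVE variance head is strictly positive", {
  cls <- net_fixture(n = 150)
  cfg <- network_config("mve", "small", profile = "desk",
                        hidden_sizes = c(32, 32), max_epochs = 10)
  h <- fit_mve(cfg, cls, seed = 6)
  set.seed(20)
  random_cls <- activity_class("rand", sprintf("r%d", 1:50),
                               matrix(rbinom(50 * 256, 1, 0.1), 50, 256),
                               runif(50, 4, 10))
  ps <- mve_predict(h, random_cls)
  expect_true(all(ps$variance > 0))
})

test_that("early stopping halts patience epochs after the loss plateaus", {
  # pure stopping rule: improvement for 20 epochs, flat afterwards
  trace <- c(seq(2, 1, length.out = 20), rep(1.0, 200))
  halted_at <- NA
  for (k in seq_along(trace)) {
    if (potencyUQ:::stop_early(trace[1:k], patience = 100L)) {
      halted_at <- k
      break
    }
  }
  expect_equal(halted_at, 120L)
  # and never stops while the loss still improves
  improving <- seq(2, 0.5, length.out = 300)
  expect_false(potencyUQ:::stop_early(improving, patience = 100L))
})

test_that("MVE training respects patience and the epoch cap", {
  cls <- net_fixture(n = 200, seed = 8)
  cfg <- network_config("mve", "small", profile = "desk",
                        hidden_sizes = c(16, 16), max_epochs = 40,
                        monitor = "valid", patience = 3)
  h <- fit_mve(cfg, cls, seed = 2)
  expect_lte(h$epochs, 40L)
  # paper-profile configuration records its published limits
  paper <- network_config("mve", "large", profile = "paper")
  expect_equal(paper$hidden_sizes, c(1000L, 1000L, 100L, 10L))
  expect_equal(paper$max_epochs, 4000L)
  expect_equal(paper$patience, 100L)
  expect_identical(paper$monitor, "train")
  ffnn_paper <- network_config("ffnn", "small", 0.5, "paper")
  expect_equal(ffnn_paper$hidden_sizes, c(300L, 300L))
  expect_equal(ffnn_paper$max_epochs, 600L)
  expect_error(network_config("ffnn", dropout_rate = 0.3), "dropout_rate")
})
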
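make_ps <- function(y, yhat, v) {
  prediction_set(sprintf("c%d", seq_along(y)), y, yhat, v)
}

test_that("MSE and R-squared follow their definitions", {
  y <- c(5, 6, 7, 8, 6.5, 7.5, 4.5)
  yhat <- c(5.2, 5.9, 7.4, 7.7, 6.6, 7.1, 4.9)
  ps <- make_ps(y, yhat, 1)
  expect_equal(mse(ps), mean((yhat - y)^2), tolerance = 1e-15)
  expect_equal(r_squared(ps),
               1 - sum((yhat - y)^2) / sum((y - mean(y))^2),
               tolerance = 1e-15)
  expect_equal(mse(make_ps(y, y, 1)), 0)
  expect_equal(r_squared(make_ps(y, y, 1)), 1)
  # constant predictor at the label mean scores exactly 0
  expect_equal(r_squared(make_ps(y, rep(mean(y), 7), 1)), 0)
  expect_error(r_squared(make_ps(rep(5, 3), c(5, 5, 5), 1)), "zero variance")
})

test_that("the Gaussian NLL evaluates its closed form", {
  expect_equal(as.numeric(nll(make_ps(6, 6, 1))), 0.5 * log(2 * pi),
               tolerance = 1e-12)
  # one sample with |error| = sigma
  s2 <- 0.49
  expect_equal(as.numeric(nll(make_ps(6, 6 + sqrt(s2), s2))),
               0.5 * (log(2 * pi) + log(s2) + 1), tolerance = 1e-12)
  # brute-force per-sample loop oracle
  set.seed(31)
  y <- rnorm(50, 6.5, 1.2); yhat <- y + rnorm(50, 0, 0.5)
  v <- runif(50, 0.05, 1)
  acc <- 0
  for (i in 1:50) acc <- acc + log(2 * pi) + log(v[i]) + (yhat[i] - y[i])^2 / v[i]
  expect_equal(as.numeric(nll(make_ps(y, yhat, v))), acc / (2 * 50),
               tolerance = 1e-12)
  # variance flooring is counted
  res <- nll(make_ps(c(6, 7), c(6.1, 7.1), c(0, 0.5)))
  expect_equal(attr(res, "n_floored"), 1L)
  expect_true(is.finite(res))
})

test_that("NLL is minimised when the variance matches the squared error", {
  y <- 6; yhat <- 6.8
  opt <- (yhat - y)^2
  base <- as.numeric(nll(make_ps(y, yhat, opt)))
  for (f in c(0.5, 0.9, 1.1, 2)) {
    expect_gt(as.numeric(nll(make_ps(y, yhat, f * opt))), base)
  }
})

test_that("expected coverage matches the normal distribution", {
  expect_equal(round(expected_coverage(1), 4), 0.6827)
  expect_equal(expected_coverage(0), 0)
  expect_equal(expected_coverage(1.959964), 0.95, tolerance = 1e-6)
  expect_error(expected_coverage(-0.1), "non-negative")
})

test_that("calibration curves hit their degenerate limits", {
  set.seed(5)
  y <- rnorm(200, 6.5, 1); yhat <- y + rnorm(200, 0, 0.5)
  wide <- calibration_curve(make_ps(y, yhat, 1e18), n_levels = 19)
  expect_true(all(wide$o == 1))
  narrow <- calibration_curve(make_ps(y, yhat, 1e-30), n_levels = 19)
  expect_true(all(narrow$o == 0))
  # grid layout and monotonicity
  cc <- calibration_curve(calibrated_ps(5000, seed = 2), n_levels = 99)
  expect_equal(cc$p, (1:99) / 100)
  expect_equal(cc$x, qnorm((1 + cc$p) / 2))
  expect_true(all(diff(cc$o) >= 0))
  expect_error(calibration_curve(calibrated_ps(100), n_levels = 1), "at least 2")
})

test_that("miscalibration areas integrate the curve with its sign convention", {
  # perfectly calibrated curve: both areas vanish
  p <- (1:99) / 100
  perfect <- structure(data.frame(p = p, x = qnorm((1 + p) / 2), o = p),
                       o0 = 0, o1 = 1,
                       class = c("calibration_curve", "data.frame"))
  expect_equal(miscalibration_area(perfect), 0)
  expect_equal(absolute_miscalibration_area(perfect), 0)
  # zero observed coverage: A_abs attains its maximum 0.5, A = -0.5
  degenerate <- make_ps(c(5, 6, 7), c(5.5, 6.5, 7.5), 0)
  expect_equal(absolute_miscalibration_area(degenerate), 0.5)
  expect_equal(miscalibration_area(degenerate), -0.5)
  # cancellation: o - p = +d on the lower half, -d on the upper half
  d <- 0.05
  o <- p + ifelse(p < 0.5, d, -d)
  o <- pmin(pmax(o, 0), 1)
  mixed <- structure(data.frame(p = p, x = qnorm((1 + p) / 2), o = o),
                     o0 = 0, o1 = 1,
                     class = c("calibration_curve", "data.frame"))
  A <- miscalibration_area(mixed)
  A_abs <- absolute_miscalibration_area(mixed)
  expect_lt(abs(A), A_abs)
  expect_lt(abs(A), 0.01)
  expect_gt(A_abs, 0.045)
  expect_lt(A_abs, 0.055)
})

test_that("|A| <= A_abs <= 0.5 with equality only without sign change", {
  set.seed(17)
  for (i in 1:20) {
    ps <- calibrated_ps(500, c = runif(1, 0.3, 3), seed = i)
    cc <- calibration_curve(ps, n_levels = 29)
    A <- miscalibration_area(cc)
    A_abs <- absolute_miscalibration_area(cc)
    expect_lte(abs(A), A_abs + 1e-12)
    expect_lte(A_abs, 0.5 + 1e-12)
    dsign <- sign(cc$o - cc$p)
    if (all(dsign >= 0) || all(dsign <= 0)) {
      expect_equal(abs(A), A_abs, tolerance = 1e-12)
    }
  }
})

test_that("Spearman rho matches rank algebra, ties and the no-tie closed form", {
  v1 <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rho(v1, v1), 1)
  # brute-force average-rank oracle with one tie pair
  v2 <- c(2, 2, 5, 1, 8, 3)
  r1 <- rank(v1); r2 <- rank(v2)
  oracle <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
  expect_equal(spearman_rho(v1, v2), oracle, tolerance = 1e-12)
  # the installed correlation routine agrees (independent implementation)
  expect_equal(spearman_rho(v1, v2), cor(v1, v2, method = "spearman"),
               tolerance = 1e-12)
  # textbook closed form when no ties exist
  set.seed(9)
  a <- rnorm(25); b <- rnorm(25)
  dd <- rank(a) - rank(b)
  expect_equal(spearman_rho(a, b),
               1 - 6 * sum(dd^2) / (25 * (25^2 - 1)), tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("all metrics are invariant to compound ordering", {
  ps <- generate_prediction_set(synthetic_prediction_config(
    n = 400, sigma_law = function(n) runif(n, 0.2, 1.2),
    calibration_factor = 1.5, seed = 21))
  perm <- sample(nrow(ps))
  ps2 <- prediction_set(ps$compound_id[perm], ps$y_true[perm],
                        ps$y_pred[perm], ps$variance[perm])
  expect_equal(mse(ps2), mse(ps), tolerance = 1e-12)
  expect_equal(r_squared(ps2), r_squared(ps), tolerance = 1e-12)
  expect_equal(as.numeric(nll(ps2)), as.numeric(nll(ps)), tolerance = 1e-12)
  expect_equal(miscalibration_area(ps2), miscalibration_area(ps),
               tolerance = 1e-12)
  expect_equal(spearman_rho(ps2), spearman_rho(ps), tolerance = 1e-12)
})

test_that("uq_report collects every metric and respects missing variances", {
  ps <- generate_prediction_set(synthetic_prediction_config(
    n = 200, sigma_law = function(n) runif(n, 0.2, 1), seed = 4))
  row <- uq_report(ps, class_id = "x", model = "m", split = "1")
  expect_equal(row$n_test, 200L)
  expect_false(anyNA(row[c("mse", "r2", "nll", "A", "A_abs", "rho")]))
  bare <- prediction_set(c("a", "b", "c"), c(5, 6, 7), c(5, 6.5, 7))
  row2 <- uq_report(bare, class_id = "x", model = "ctrl", split = "1")
  expect_true(all(is.na(row2[c("nll", "A", "A_abs", "rho")])))
  expect_false(anyNA(row2[c("mse", "r2")]))
})
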
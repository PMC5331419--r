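test_that("R2 and RMSE behave at their fixed points", {
  y <- c(5.2, 6.1, 5.8, 6.6, 6.0)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  expect_error(r_squared(rep(2, 4), 1:4), class = "arqsar_constant_response_error")
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_error(rmse(numeric(), numeric()), class = "arqsar_argument_error")
})

test_that("hat-shortcut LOO equals the explicit refit oracle", {
  inst <- random_instance(12, 2, seed = 14)
  expect_equal(q2_loo(inst$x, inst$y), q2_loo_refit_oracle(inst$x, inst$y),
               tolerance = 1e-10)
  # noise-free linear data predicts perfectly out of sample
  x <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  y_clean <- 2 + x[, 1] - 3 * x[, 2]
  expect_equal(q2_loo(x, y_clean), 1, tolerance = 1e-10)
  expect_error(q2_loo(x[1:4, ], y_clean[1:4]), class = "arqsar_precondition_error")
})

test_that("LOO collapses when the signal is broken by permutation", {
  inst <- random_instance(20, 3, noise_sd = 0.1, seed = 20)
  set.seed(1)
  q_broken <- q2_loo(inst$x, sample(inst$y))
  expect_lt(q_broken, 0.2)
  expect_gt(q2_loo(inst$x, inst$y), 0.8)
})

test_that("LMO is seed-reproducible and approaches LOO as folds shrink", {
  inst <- random_instance(20, 2, noise_sd = 0.1, seed = 33)
  a <- q2_lmo(inst$x, inst$y, 0.3, iterations = 100, seed = 7)
  b <- q2_lmo(inst$x, inst$y, 0.3, iterations = 100, seed = 7)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_identical(attr(a, "iterations"), attr(b, "iterations"))

  # leave-1-out folds over many iterations converge toward Q2(LOO); the
  # response is kept well away from its mean so single-row denominators
  # stay bounded
  set.seed(44)
  xb <- cbind(g = rep(c(-1, 1), each = 10), z = rnorm(20, sd = 0.3))
  yb <- 6.5 + 1.5 * xb[, "g"] + 0.2 * xb[, "z"] + rnorm(20, sd = 0.05)
  near_loo <- q2_lmo(xb, yb, 1 / 20, iterations = 600, seed = 3)
  expect_equal(as.numeric(near_loo), q2_loo(xb, yb), tolerance = 0.05)

  # noise-free data scores 1 in every iteration
  y_clean <- 1 + inst$x[, 1]
  clean <- q2_lmo(inst$x, y_clean, 0.3, iterations = 25, seed = 1)
  expect_equal(unname(attr(clean, "iterations")), rep(1, 25), tolerance = 1e-10)

  expect_error(q2_lmo(inst$x, inst$y, 0.9, iterations = 5),
               class = "arqsar_argument_error")
})

test_that("external predictivity statistics match hand arithmetic", {
  y_ext <- c(5.5, 6.5, 6.0); yhat <- y_ext
  expect_equal(q2_f1(y_ext, yhat, 6.2), 1)
  expect_equal(q2_f2(y_ext, yhat), 1)
  expect_equal(q2_f3(y_ext, yhat, c(5, 6, 7)), 1)

  # F2 = 1 - 2/2 = 0 for predictions at the external mean's accuracy
  expect_equal(q2_f2(c(0, 2), c(1, 1)), 0)

  # shifting y and yhat together leaves every Q2 unchanged
  y2 <- c(5.1, 6.3, 5.6, 6.8); p2 <- c(5.3, 6.1, 5.8, 6.5); tr <- c(5.4, 6.2, 6.9, 5.1)
  for (delta in c(-2, 3.5)) {
    expect_equal(q2_f1(y2 + delta, p2 + delta, mean(tr) + delta), q2_f1(y2, p2, mean(tr)))
    expect_equal(q2_f2(y2 + delta, p2 + delta), q2_f2(y2, p2))
    expect_equal(q2_f3(y2 + delta, p2 + delta, tr + delta), q2_f3(y2, p2, tr))
  }
  expect_error(q2_f2(c(1, 1), c(0, 2)), class = "arqsar_constant_response_error")
})

test_that("concordance correlation is bounded by Pearson and exact at its poles", {
  expect_equal(ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  for (seed in 1:5) {
    set.seed(seed)
    y <- rnorm(15); yh <- 0.6 * y + rnorm(15, sd = 0.5) + 0.3
    expect_lte(abs(ccc(y, yh)), abs(cor(y, yh)) + 1e-12)
  }
  # matching first and second moments collapse CCC onto Pearson r
  set.seed(2)
  y <- rnorm(40)
  yh <- 0.5 * y + sqrt(1 - 0.25) * rnorm(40)
  yh <- (yh - mean(yh)) / sd(yh) * sd(y) + mean(y)
  expect_equal(ccc(y, yh), cor(y, yh), tolerance = 1e-12)
  expect_error(ccc(rep(1, 3), rep(2, 3)), class = "arqsar_constant_response_error")
})

test_that("Y-scrambling separates real signal from chance correlation", {
  set.seed(77)
  n <- 25
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("d", 1:4)))
  y <- 6 + drop(x %*% c(0.8, -0.6, 0.7, -0.9)) + rnorm(n, sd = 0.2)
  scr <- y_scramble(x, y, iterations = 100, seed = 5)
  fit <- fit_ols(x, y)
  expect_gt(r_squared(y, fit$fitted) - scr$mean_r2, 0.3)
  expect_length(scr$r2, 100L)

  # single iteration with a fixed seed is fully deterministic
  one_a <- y_scramble(x, y, iterations = 1, seed = 9)
  one_b <- y_scramble(x, y, iterations = 1, seed = 9)
  expect_identical(one_a$r2, one_b$r2)

  # pure-noise response: scrambled and unscrambled R2 are indistinguishable
  set.seed(8)
  y_noise <- rnorm(n)
  scr_n <- y_scramble(x, y_noise, iterations = 60, seed = 2)
  r2_noise <- r_squared(y_noise, fit_ols(x, y_noise)$fitted)
  pct <- mean(scr_n$r2 <= r2_noise)
  expect_gt(pct, 0.01)
  expect_lt(pct, 0.99)
  expect_lt(abs(r2_noise - mean(scr_n$r2)), 0.25)
})

test_that("Q2(LOO) never exceeds R2 of the same OLS fit", {
  for (seed in 1:8) {
    inst <- random_instance(16 + seed, 3, noise_sd = 0.5, seed = seed)
    fit <- fit_ols(inst$x, inst$y)
    expect_lte(q2_loo(inst$x, inst$y), r_squared(inst$y, fit$fitted))
  }
})

test_that("the metrics report carries internal and external batteries", {
  set.seed(55)
  n <- 24; x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("d", 1:3)))
  y <- 6 + drop(x %*% c(0.7, -0.5, 0.6)) + rnorm(n, sd = 0.2)
  x_ext <- matrix(rnorm(18), 6, 3, dimnames = list(NULL, paste0("d", 1:3)))
  y_ext <- 6 + drop(x_ext %*% c(0.7, -0.5, 0.6)) + rnorm(6, sd = 0.2)
  rep <- validation_metrics(x, y, x_ext, y_ext, lmo_iterations = 50,
                            scramble_iterations = 30, seed = 4)
  expect_s3_class(rep, "metrics_report")
  for (f in c("r2", "rmse_train", "q2_loo", "q2_lmo", "q2_f1", "q2_f2",
              "q2_f3", "ccc", "rmse_prediction"))
    expect_true(is.finite(rep[[f]]), info = f)
  expect_identical(rep$lmo_config$iterations, 50)
  expect_output(print(rep), "Q2F1")
})
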
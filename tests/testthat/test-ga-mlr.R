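test_that("fit_ols matches the normal-equations oracle and is exact on clean data", {
  inst <- random_instance(20, 3, seed = 5)
  fit <- fit_ols(inst$x, inst$y)
  expect_equal(unname(coef(fit$model)), unname(ols_oracle(inst$x, inst$y)),
               tolerance = 1e-10)
  expect_equal(fit$sse, sum(fit$residuals^2))
  expect_length(fit$residuals, 20L)

  # exact linear response -> zero SSE, exact coefficients
  x <- matrix(seq_len(8), 8, 1, dimnames = list(NULL, "d1"))
  fit0 <- fit_ols(x, 2 + 3 * x[, 1])
  expect_equal(fit0$sse, 0, tolerance = 1e-20)
  expect_equal(unname(coef(fit0$model)), c(2, 3))
})

test_that("fit_ols rejects singular and undersized designs", {
  inst <- random_instance(10, 2, seed = 6)
  dup <- cbind(inst$x, d3 = inst$x[, 1])
  expect_error(fit_ols(dup, inst$y), class = "arqsar_singular_fit_error")
  expect_error(fit_ols(inst$x[1:3, ], inst$y[1:3]),
               class = "arqsar_precondition_error")
})

test_that("Friedman LOF matches hand arithmetic and its monotonicity", {
  expect_equal(friedman_lof(0, c = 3, d = 0.5, p = 2, n = 10), 0)
  expect_equal(friedman_lof(2, c = 5, d = 0.5, p = 4, n = 29), 2 / (22 / 29)^2)
  expect_equal(friedman_lof(1, c = 2, d = 0.5, p = 1, n = 10), 1 / 0.75^2)
  expect_error(friedman_lof(1, c = 8, d = 0.5, p = 4, n = 10),
               class = "arqsar_degenerate_penalty_error")

  # strictly increasing in SSE, and in p at fixed SSE
  lofs_sse <- vapply(c(0.5, 1, 2, 4), friedman_lof, numeric(1),
                     c = 4, d = 0.5, p = 3, n = 25)
  expect_true(all(diff(lofs_sse) > 0))
  lofs_p <- vapply(1:5, function(p)
    friedman_lof(1, c = p + 1, d = 0.5, p = p, n = 25), numeric(1))
  expect_true(all(diff(lofs_p) > 0))
})

test_that("the GA matches exhaustive enumeration on small descriptor spaces", {
  for (seed in c(2, 9, 17)) {
    inst <- random_instance(18, 11, noise_sd = 0.5, seed = seed)
    cfg <- ga_config(population_size = 40, max_generations = 120,
                     model_size = 3, stagnation_patience = 40, seed = seed)
    res <- run_ga(descriptor_table(inst$x), inst$y, cfg)
    # brute-force oracle over all C(11, 3) subsets
    combos <- utils::combn(ncol(inst$x), 3)
    lofs <- apply(combos, 2, function(idx) {
      f <- fit_ols(inst$x[, idx, drop = FALSE], inst$y)
      friedman_lof(f$sse, f$c, 0.5, f$p_terms, f$n)
    })
    expect_equal(sort(res$models[[1]]$indices),
                 sort(combos[, which.min(lofs)]))
    expect_equal(res$models[[1]]$lof, min(lofs), tolerance = 1e-12)
  }
})

test_that("GA degenerate configurations behave as specified", {
  inst <- random_instance(15, 6, seed = 3)
  # zero generations: a ranked random initial population, seed-reproducible
  cfg0 <- ga_config(population_size = 10, max_generations = 0, model_size = 2,
                    seed = 42)
  r1 <- run_ga(descriptor_table(inst$x), inst$y, cfg0)
  r2 <- run_ga(descriptor_table(inst$x), inst$y, cfg0)
  expect_identical(lapply(r1$models, `[[`, "indices"),
                   lapply(r2$models, `[[`, "indices"))
  expect_equal(r1$generations, 0L)
  lofs <- vapply(r1$models, `[[`, numeric(1), "lof")
  expect_true(!is.unsorted(lofs))

  # one available descriptor: the single possible model
  x1 <- inst$x[, 1, drop = FALSE]
  res1 <- run_ga(descriptor_table(x1), inst$y,
                 ga_config(population_size = 4, max_generations = 3,
                           model_size = 1, seed = 1))
  f <- fit_ols(x1, inst$y)
  expect_equal(res1$models[[1]]$lof,
               friedman_lof(f$sse, f$c, 0.5, f$p_terms, f$n))

  expect_error(run_ga(descriptor_table(inst$x), inst$y,
                      ga_config(model_size = 7)),
               class = "arqsar_argument_error")
})

test_that("best LOF is non-increasing and the trajectory is seed-deterministic", {
  inst <- random_instance(25, 15, seed = 8)
  cfg <- ga_config(population_size = 30, max_generations = 80, model_size = 3,
                   stagnation_patience = 80, seed = 99)
  res <- run_ga(descriptor_table(inst$x), inst$y, cfg)
  expect_true(all(diff(res$best_lof_history) <= 0))
  res2 <- run_ga(descriptor_table(inst$x), inst$y, cfg)
  expect_identical(res$best_lof_history, res2$best_lof_history)
})

test_that("the GA recovers a planted subset among decoys", {
  set.seed(123)
  n <- 30; m <- 54
  x <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, paste0("d", 1:m)))
  true_idx <- c(5L, 19L, 33L, 47L)
  y <- 6 + drop(x[, true_idx] %*% c(0.9, -0.7, 0.8, -1.0)) + rnorm(n, sd = 0.1)
  res <- run_ga(descriptor_table(x), y,
                ga_config(population_size = 60, max_generations = 400,
                          model_size = 4, stagnation_patience = 100, seed = 21))
  expect_identical(sort(res$models[[1]]$indices), true_idx)
})

test_that("the fitted model object supports the standard verbs", {
  set.seed(31)
  n <- 26; m <- 15
  x <- matrix(rnorm(n * m), n, m,
              dimnames = list(sprintf("c%02d", 1:n), paste0("d", 1:m)))
  y <- 5.5 + x[, 4] - 0.8 * x[, 11] + rnorm(n, sd = 0.15)
  fit <- qsar_gamlr(x, y, model_size = 2,
                    config = ga_config(population_size = 30, max_generations = 100,
                                       stagnation_patience = 40, seed = 2))
  expect_s3_class(fit, "qsar_gamlr")
  expect_identical(sort(fit$model$descriptor_names), c("d11", "d4"))
  expect_equal(unname(predict(fit)), fit$fit$fitted)
  expect_equal(predict(fit, x), setNames(fit$fit$fitted, rownames(x)),
               tolerance = 1e-12)
  expect_equal(unname(residuals(fit)), unname(y - fitted(fit)),
               tolerance = 1e-12)
  expect_equal(length(coef(fit)), 3L)
  expect_output(print(fit), "GA-MLR QSAR model")

  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(n, 3L))

  s <- summary(fit, lmo_iterations = 50, scramble_iterations = 20, seed = 1)
  expect_output(print(s), "Validation metrics")
  expect_gt(s$metrics$r2, 0.8)

  pdf(NULL)
  on.exit(dev.off())
  rep <- plot(fit)
  expect_s3_class(rep, "leverage_report")
})
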
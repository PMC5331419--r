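test_that("leverage cutoff follows 3(p+1)/n", {
  expect_equal(round(leverage_cutoff(4, 29), 3), 0.517)
  expect_equal(leverage_cutoff(2, 12), 0.75)
  expect_equal(leverage_cutoff(1, 6), 1)
  expect_error(leverage_cutoff(0, 10), class = "arqsar_argument_error")
  expect_error(leverage_cutoff(4, 5), class = "arqsar_argument_error")
})

test_that("training leverages are the hat diagonal with trace p+1", {
  for (seed in 1:6) {
    inst <- random_instance(15 + seed, 3, seed = seed)
    h <- leverages(inst$x)
    expect_equal(sum(h), 4, tolerance = 1e-8)
    expect_true(all(h >= 1 / nrow(inst$x) - 1e-12))
    expect_true(all(h <= 1 + 1e-12))
  }
  # two distinct points, one descriptor: both interpolated, h = 1
  x2 <- matrix(c(0, 1), 2, 1, dimnames = list(NULL, "d"))
  expect_equal(unname(leverages(x2)), c(1, 1), tolerance = 1e-12)
})

test_that("leverage is invariant under affine recoding of descriptors", {
  inst <- random_instance(18, 3, seed = 40)
  q <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, colnames(inst$x)))
  h0 <- leverages(inst$x)
  recoded <- sweep(inst$x, 2, c(10, 0.01, 3), "*")
  recoded <- sweep(recoded, 2, c(-5, 2, 100), "+")
  colnames(recoded) <- colnames(inst$x)
  expect_equal(unname(leverages(recoded)), unname(h0), tolerance = 1e-8)
})

test_that("moving a query away from the centroid never re-enters the domain", {
  inst <- random_instance(20, 4, seed = 12)
  centroid <- colMeans(inst$x)
  dir <- rnorm(4)
  hs <- vapply(c(0.5, 1, 2, 4, 8, 16), function(s)
    leverages(inst$x, matrix(centroid + s * dir, 1,
                             dimnames = list(NULL, colnames(inst$x)))),
    numeric(1))
  expect_true(all(diff(hs) > 0))
  expect_gt(hs[6], leverage_cutoff(4, 20))
})

test_that("standardized residuals use the training sd and flag beyond 2.5", {
  # alternating equal-magnitude residuals: z = +/- sqrt((n-1)/n)
  n <- 8
  y <- rep(c(1, -1), n / 2) * 0.4
  z <- standardized_residuals(y, rep(0, n))
  expect_equal(abs(z), rep(sqrt((n - 1) / n), n), tolerance = 1e-12,
               ignore_attr = TRUE)

  y2 <- c(0, 0.1, -0.1, 0.2, -0.2)
  z2 <- standardized_residuals(y2, rep(0, 5))
  expect_equal(unname(z2[1]), 0)

  # a residual at 3 training sds is flagged
  train_res <- rnorm(20, sd = 0.2)
  z3 <- standardized_residuals(3 * sd(train_res), 0, scale_residuals = train_res)
  expect_true(attr(z3, "flagged"))
  expect_error(standardized_residuals(c(1, 1), c(1, 1)),
               class = "arqsar_zero_variance_error")
})

test_that("Williams points separate structural and response outliers", {
  set.seed(60)
  n <- 25
  x <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(sprintf("c%02d", 1:n), paste0("d", 1:3)))
  y <- 6 + drop(x %*% c(0.8, -0.6, 0.5)) + rnorm(n, sd = 0.15)
  fit <- fit_ols(x, y)

  # benign data: everything inside, residuals within 2.5 sigma
  wp <- williams_points(fit$model, x, y)
  expect_true(all(wp$points$inside_ad))
  expect_true(all(abs(wp$points$std_residual) <= 2.5))
  expect_equal(wp$h_star, leverage_cutoff(3, n))

  # descriptor outlier far from the centroid: leverage flag only
  x_out <- matrix(colMeans(x) + 10 * apply(x, 2, sd), 1,
                  dimnames = list("ext_far", colnames(x)))
  y_out <- drop(predict(fit$model, x_out))  # perfectly predicted
  wp2 <- williams_points(fit$model, x, y, x_ext = x_out, y_ext = y_out)
  ext <- wp2$points[wp2$points$set == "external", ]
  expect_false(ext$inside_ad)
  expect_false(ext$residual_flag)

  # activity outlier at the centroid: residual flag only
  x_mid <- matrix(colMeans(x), 1, dimnames = list("ext_mid", colnames(x)))
  y_bad <- drop(predict(fit$model, x_mid)) + 10 * sd(fit$residuals)
  wp3 <- williams_points(fit$model, x, y, x_ext = x_mid, y_ext = y_bad)
  ext3 <- wp3$points[wp3$points$set == "external", ]
  expect_true(ext3$inside_ad)
  expect_true(ext3$residual_flag)
})

test_that("Insubria points score unlabelled screening rows against training h*", {
  set.seed(61)
  n <- 20
  x <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(sprintf("t%02d", 1:n), c("d1", "d2")))
  y <- 5 + x[, 1] - x[, 2] + rnorm(n, sd = 0.1)
  model <- fit_ols(x, y)$model

  # a screening row identical to a training row inherits its hat value
  x_screen <- x[c(3, 7), , drop = FALSE]
  rownames(x_screen) <- c("s1", "s2")
  ip <- insubria_points(model, x, x_screen)
  expect_equal(ip$h, unname(leverages(x)[c(3, 7)]), tolerance = 1e-12)
  expect_true(all(ip$inside_ad))
  expect_equal(ip$predicted_pIC50, unname(predict(model, x_screen)))

  # an extrapolated row is outside
  far <- matrix(colMeans(x) + 12 * apply(x, 2, sd), 1,
                dimnames = list("s_far", colnames(x)))
  ip2 <- insubria_points(model, x, far)
  expect_false(ip2$inside_ad)

  # empty screening set: empty table, no error
  ip0 <- insubria_points(model, x, x[0, , drop = FALSE])
  expect_equal(nrow(ip0), 0L)
  expect_equal(attr(ip0, "h_star"), leverage_cutoff(2, n))
})

test_that("misaligned query columns are rejected", {
  inst <- random_instance(10, 2, seed = 1)
  bad <- inst$x[, 2:1]
  expect_error(leverages(inst$x, bad), class = "arqsar_shape_error")
  expect_error(leverages(inst$x, inst$x[, 1, drop = FALSE]),
               class = "arqsar_shape_error")
})
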
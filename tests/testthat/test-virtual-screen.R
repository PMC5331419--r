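eq4 <- function() dht_antagonists()$model

test_that("frozen-model prediction is the published affine map", {
  x <- matrix(c(0, 0, 0, 0,
                1, 1, 1, 1), 2, 4, byrow = TRUE,
              dimnames = list(c("zero", "one"),
                              c("IC5", "GATS5e", "DISPp", "HATS3u")))
  pred <- predict(eq4(), x)
  expect_equal(unname(pred["zero"]), 27.13)                       # intercept
  expect_equal(unname(pred["one"]), -2.89 + 1.01 - 3.17 - 12.99 + 27.13)

  # extra columns are ignored; matching is by exact name
  x_extra <- cbind(x, noise = c(9, 9))
  expect_equal(predict(eq4(), x_extra), pred)

  expect_error(predict(eq4(), x[, c("IC5", "GATS5e", "HATS3u")]),
               class = "arqsar_missing_descriptor_error")
  x_bad <- x; x_bad[1, 1] <- NA
  expect_error(predict(eq4(), x_bad), class = "arqsar_missing_value_error")
})

test_that("prediction is affine along descriptor interpolations", {
  set.seed(90)
  m <- eq4()
  x1 <- rnorm(4); x2 <- rnorm(4)
  for (a in c(-0.5, 0.25, 0.8, 2)) {
    mix <- matrix(a * x1 + (1 - a) * x2, 1,
                  dimnames = list(NULL, m$descriptor_names))
    p1 <- predict(m, matrix(x1, 1, dimnames = list(NULL, m$descriptor_names)))
    p2 <- predict(m, matrix(x2, 1, dimnames = list(NULL, m$descriptor_names)))
    expect_equal(unname(predict(m, mix)), a * p1 + (1 - a) * p2,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("screening attaches AD flags and a deterministic ranking", {
  set.seed(92)  # a draw whose training rows all sit inside the leverage domain
  n <- 24
  x <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(sprintf("t%02d", 1:n), paste0("d", 1:3)))
  y <- 6 + drop(x %*% c(0.7, -0.5, 0.9)) + rnorm(n, sd = 0.15)
  model <- fit_ols(x, y)$model

  # screening the training set itself: all inside, predictions = fitted values
  res <- screen_compounds(model, x, x)
  expect_s3_class(res, "screen_result")
  expect_true(all(res$ad_flag == "Y"))
  expect_equal(res$predicted_pIC50[match(rownames(x), res$compound_id)],
               unname(predict(model, x)))
  expect_identical(sort(res$rank), 1:n)
  expect_true(!is.unsorted(-res$predicted_pIC50))

  # a synthetic 110-row screen with 26 constructed leverage outliers
  x_in <- matrix(rnorm(84 * 3, sd = 0.8), 84, 3,
                 dimnames = list(sprintf("in%03d", 1:84), colnames(x)))
  x_out <- generate_screen_outliers(x, 26)
  rownames(x_out) <- sprintf("out%02d", 1:26)
  res110 <- screen_compounds(model, x, rbind(x_in, x_out))
  expect_equal(nrow(res110), 110L)
  expect_equal(sum(res110$ad_flag == "Y"), 84L)
  expect_true(all(res110$ad_flag[match(rownames(x_out), res110$compound_id)] == "N"))

  # equal predictions rank by ascending compound id
  x_tie <- x[c(1, 1), , drop = FALSE]
  rownames(x_tie) <- c("zz", "aa")
  res_tie <- screen_compounds(model, x, x_tie)
  expect_identical(res_tie$compound_id, c("aa", "zz"))

  # threshold filters the report after ranking
  thr <- stats::median(res$predicted_pIC50)
  res_thr <- screen_compounds(model, x, x, threshold = thr)
  expect_true(all(res_thr$predicted_pIC50 >= thr))
})

test_that("top hits partition the reference screening table as published", {
  fx <- dht_antagonists()
  res <- as_screen_result(fx$screen)
  hits <- top_hits(res, k = 3)

  expect_identical(hits$best_overall$compound_id, "CID_70126881")
  expect_equal(hits$best_overall$predicted_pIC50, 7.90)
  expect_identical(hits$best_inside_ad$compound_id, "CID_70128824")
  expect_equal(hits$best_inside_ad$predicted_pIC50, 7.37)

  # ranking extremes among the highlighted hits
  pos <- match(c("CID_70126881", "CID_70127147", "CID_70128824"),
               res$compound_id[order(res$rank)])
  expect_true(all(diff(pos) > 0))
  expect_equal(nrow(hits$inside) + nrow(hits$outside), 110L)

  # k larger than the table returns everything
  all_hits <- top_hits(res, k = 500)
  expect_equal(nrow(all_hits$top), 110L)

  # all compounds outside the AD: inside partition reported empty, no error
  out_only <- as_screen_result(data.frame(
    compound_id = c("a", "b"), predicted_pIC50 = c(7, 6), ad_flag = "N"))
  h2 <- top_hits(out_only)
  expect_null(h2$best_inside_ad)
  expect_equal(nrow(h2$inside), 0L)

  expect_error(top_hits(res[0, ]), class = "arqsar_argument_error")
})
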